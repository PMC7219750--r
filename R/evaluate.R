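# Predictive-accuracy measures, the stratified holdout protocol, the
# bootstrapped logistic benchmark, and the qualitative-compliance report.

#' Stratified train/holdout split
#'
#' Within each stratum of `stratify_by` (survey year by default),
#' `round(train_frac * n)` records go to the training set after a seeded
#' shuffle (R's round-half-to-even at the .5 boundary), the rest to the
#' holdout. Empty strata are skipped with a message.
#'
#' @param survey a `qihb_survey`.
#' @param train_frac training fraction (default 0.70).
#' @param stratify_by stratification column (default `"year"`).
#' @param seed integer seed.
#' @return list with `train` and `holdout` surveys and the index vectors
#'   `train_idx`, `holdout_idx`.
#' @export
split_train_holdout <- function(survey, train_frac = 0.7,
                                stratify_by = "year", seed = 1) {
  if (anyNA(survey[[stratify_by]])) {
    abort_qihb("stratification variable has missing values",
               "qihb_data_error")
  }
  set.seed(seed)
  train_idx <- integer(0)
  for (s in sort(unique(survey[[stratify_by]]))) {
    idx <- which(survey[[stratify_by]] == s)
    if (!length(idx)) { message("empty stratum ", s, " skipped"); next }
    k <- round(train_frac * length(idx))
    train_idx <- c(train_idx, sample(idx)[seq_len(k)])
  }
  train_idx <- sort(train_idx)
  holdout_idx <- setdiff(seq_len(nrow(survey)), train_idx)
  list(train = survey[train_idx, , drop = FALSE],
       holdout = survey[holdout_idx, , drop = FALSE],
       train_idx = train_idx, holdout_idx = holdout_idx)
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a randomly selected
#' positive case scores higher than a randomly selected negative case, with
#' ties counting one half.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1) with at least one of each class.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  if (length(scores) != length(labels) || anyNA(scores) || anyNA(labels)) {
    abort_qihb("scores and labels must align and be complete",
               "qihb_invalid_input")
  }
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    abort_qihb("AUC undefined with a single-class label vector",
               "qihb_undefined_auc")
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Per-record disease probabilities for the first n_draws posterior draws
# (all draws with a message if fewer are available). Returns n x draws.
posterior_theta <- function(fit, survey, spec = fit$spec, n_draws = NULL,
                            mask_refs = NULL) {
  X <- design_matrix(survey, spec)
  B <- fit$draws
  if (!is.null(n_draws)) {
    if (n_draws > nrow(B)) {
      message("only ", nrow(B), " posterior draws available; using all")
      n_draws <- nrow(B)
    }
    B <- B[seq_len(n_draws), , drop = FALSE]
  }
  if (!is.null(mask_refs)) B[, mask_refs] <- 0
  stats::plogis(tcrossprod(X, B))
}

#' Predicted prevalent cases with uncertainty
#'
#' For each posterior draw (up to `n_draws`, in stored order) the expected
#' prevalent count is the sum of individual disease probabilities over the
#' supplied (typically holdout) survey. Reports the mean and the 5th/95th
#' percentiles as the 90% interval, and whether it covers the actual count.
#'
#' @param fit a `qihb_posterior` (MCMC or bootstrap pseudo-posterior).
#' @param survey survey to predict on.
#' @param spec model spec (defaults to the fit's).
#' @param n_draws posterior draws to use (default 1000).
#' @return list of class `qihb_calibration`: `disease`, `actual`, `mean`,
#'   `lo`, `hi`, `covered`, `n_draws`.
#' @export
predicted_prevalent_cases <- function(fit, survey, spec = fit$spec,
                                      n_draws = 1000) {
  theta <- posterior_theta(fit, survey, spec, n_draws)
  counts <- colSums(theta)
  d <- spec$disease
  actual <- if (d %in% names(survey)) sum(survey[[d]]) else NA_real_
  lo <- unname(stats::quantile(counts, 0.05))
  hi <- unname(stats::quantile(counts, 0.95))
  structure(list(disease = d, actual = actual, mean = mean(counts),
                 lo = lo, hi = hi,
                 covered = if (is.na(actual)) NA else
                   actual >= lo && actual <= hi,
                 n_draws = length(counts)),
            class = "qihb_calibration")
}

#' @export
print.qihb_calibration <- function(x, ...) {
  cat(sprintf(
    "%s prevalent cases: predicted %.1f (90%% interval %.1f-%.1f), actual %s, covered: %s\n",
    x$disease, x$mean, x$lo, x$hi,
    ifelse(is.na(x$actual), "?", format(x$actual)),
    format(x$covered)))
  invisible(x)
}

#' Bootstrapped maximum-likelihood logistic benchmark
#'
#' Unpenalized logistic fits on `n_boot` resampled-with-replacement copies
#' of the survey. Replicates exhibiting separation (non-convergence or
#' fitted probabilities numerically 0/1) are dropped with a message; the
#' coefficient sets are returned in the same container as MCMC draws so the
#' calibration and AUC machinery applies unchanged.
#'
#' @param survey a `qihb_survey` with the spec's outcome column.
#' @param spec a [model_spec()].
#' @param n_boot bootstrap replicates (default 100).
#' @param seed integer seed.
#' @return a `qihb_posterior` with flavor `"mle_bootstrap"`; element
#'   `n_separated` counts dropped replicates.
#' @export
fit_logistic_mle_bootstrap <- function(survey, spec, n_boot = 100,
                                       seed = 1) {
  d <- spec$disease
  keep <- stats::complete.cases(survey[c(REQUIRED_COVARIATES, d)])
  survey <- survey[keep, , drop = FALSE]
  y <- as.numeric(survey[[d]])
  if (all(y == 0) || all(y == 1)) {
    abort_qihb("outcome needs both classes for MLE", "qihb_data_error")
  }
  X <- design_matrix(survey, spec)
  n <- nrow(X)
  set.seed(seed)
  sets <- list()
  dropped <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    sep <- FALSE
    fit <- withCallingHandlers(
      stats::glm.fit(X[idx, , drop = FALSE], y[idx],
                     family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities|did not converge",
                  conditionMessage(w))) sep <<- TRUE
        invokeRestart("muffleWarning")
      })
    if (sep || !fit$converged) { dropped <- dropped + 1L; next }
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0  # rank deficiency: unobserved level in the resample
    sets[[length(sets) + 1]] <- cf
  }
  if (dropped > 0) message(dropped, " separated replicate(s) dropped")
  if (!length(sets)) abort_qihb("all bootstrap replicates separated",
                                "qihb_numerical_error")
  draws <- do.call(rbind, sets)
  colnames(draws) <- colnames(X)
  structure(list(draws = draws, chain = rep(1L, nrow(draws)),
                 sigma2 = NULL, accept = NULL, rhat = NULL, spec = spec,
                 flavor = "mle_bootstrap", constraints = NULL,
                 mcmc = NULL, n_used = n, n_dropped = sum(!keep),
                 n_separated = dropped),
            class = "qihb_posterior")
}

# Human-readable label for a pattern, matching the rows of the published
# compliance grid.
pattern_label <- function(p) {
  fac <- c(phys = "Physical Activity", smoke = "Smoking",
           secsmoke = "Second-Hand Smoking", bmi = "BMI",
           demog = "Demographics")[p$factor]
  if (p$kind == "sign") return(unname(fac))
  if (p$factor == "demog") {
    return(paste(if (p$gender == "M") "Male" else "Female", "with Age"))
  }
  if (p$factor == "smoke" && p$dimension == "age") {
    return(paste(if (p$gender == "M") "Male" else "Female",
                 "Smoking with Age"))
  }
  if (p$dimension == "level") return(paste(fac, "with Level"))
  paste(fac, "with Age")
}

#' Qualitative-compliance report
#'
#' Evaluates each qualitative pattern on the point estimates (posterior
#' means, or MLE coefficients) of one or more fitted models, with
#' non-strict inequalities. Patterns whose shape dimension does not exist
#' in a model's structure (the age-varying rows for Diabetes) are excluded
#' from that model's grid.
#'
#' @param fits named list of fits (`qihb_posterior` or named coefficient
#'   vectors carrying a `spec` attribute); names are the model flavors.
#' @param patterns list of patterns; defaults to [default_patterns()] per
#'   fit's disease.
#' @return data frame of class `qihb_compliance`: `flavor`, `disease`,
#'   `label`, `kind`, `pass`.
#' @export
compliance_report <- function(fits, patterns = NULL) {
  if (is.null(names(fits))) {
    abort_qihb("`fits` must be a named list", "qihb_invalid_input")
  }
  rows <- list()
  for (flavor in names(fits)) {
    fit <- fits[[flavor]]
    spec <- if (inherits(fit, "qihb_posterior")) fit$spec else
      attr(fit, "spec")
    if (is.null(spec)) {
      abort_qihb("each fit must carry a model spec", "qihb_spec_mismatch")
    }
    est <- point_estimate(fit)
    pats <- patterns %||% default_patterns(spec$disease)
    for (p in pats) {
      applies <- tryCatch({
        cs <- compile_constraints(list(p), spec)
        TRUE
      }, qihb_spec_mismatch = function(e) FALSE)
      if (!applies) next
      rows[[length(rows) + 1]] <- data.frame(
        flavor = flavor, disease = spec$disease,
        label = pattern_label(p), kind = p$kind,
        pass = check_constraints(est, cs), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("qihb_compliance", "data.frame"))
}

#' Render a compliance report as a markdown grid
#'
#' @param report a [compliance_report()] result.
#' @return character vector of markdown lines (check marks / crosses).
#' @export
format_compliance <- function(report) {
  cols <- unique(paste(report$flavor, report$disease))
  labels <- unique(report$label)
  header <- paste0("| Pattern | ", paste(cols, collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", length(cols) + 1), collapse = "|"),
                "|")
  body <- vapply(labels, function(lb) {
    cells <- vapply(cols, function(cl) {
      hit <- report[report$label == lb & paste(report$flavor,
                                               report$disease) == cl, ]
      if (nrow(hit) == 0) "NA" else if (all(hit$pass)) "✓" else
        "×"
    }, character(1))
    paste0("| ", lb, " | ", paste(cells, collapse = " | "), " |")
  }, character(1))
  c(header, sep, body)
}
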