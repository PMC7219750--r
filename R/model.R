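# Disease-model term structure, design matrix, priors and RR conversions.

BLOCK_ORDER <- c("demog", "bmi", "phys", "smoke", "alc", "veg", "fruit",
                 "secsmoke", "trust", "edu", "inc", "meth", "region")

# Shared block-variance groups: one inverse-gamma variance per coefficient
# block; the scalar slopes (secsmoke, edu, inc, meth) share a single group.
VAR_GROUPS <- c(demog = 1L, bmi = 2L, phys = 3L, smoke = 4L, alc = 5L,
                veg = 6L, fruit = 7L, trust = 8L, region = 9L,
                secsmoke = 10L, edu = 10L, inc = 10L, meth = 10L)

#' Model specification
#'
#' Term structure of one disease's logistic model. The age-gender cells
#' (`demog[a,g]`) act as the per-cell intercepts; every other categorical
#' block drops its first level (coefficient fixed at 0): activity level 1
#' (Inactive), alcohol 1, vegetable 1, fruit 1, trust 1 and region 1. The
#' two diseases differ structurally: the IHD activity block varies by age
#' (`phys[a,m]`, 21 free coefficients) and its smoking block by age and
#' gender (`smoke[a,g]`, 14), whereas Diabetes uses `phys[m]` (3) and
#' `smoke[g]` (2).
#'
#' @param disease `"IHD"` or `"Diabetes"`.
#' @return list with elements `disease`, `coefs` (data frame: `ref`,
#'   `block`, `age`, `gender`, `level`) and `p` (free-coefficient count:
#'   90 for IHD, 60 for Diabetes); class `qihb_model_spec`.
#' @export
model_spec <- function(disease = c("IHD", "Diabetes")) {
  disease <- match.arg(disease)
  rows <- list()
  add <- function(ref, block, age = NA_integer_, gender = NA_character_,
                  level = NA_integer_) {
    rows[[length(rows) + 1]] <<- data.frame(
      ref = ref, block = block, age = as.integer(age), gender = gender,
      level = as.integer(level), stringsAsFactors = FALSE)
  }
  for (g in c("M", "F")) for (a in 1:7) {
    add(sprintf("demog[%d,%s]", a, g), "demog", a, g)
  }
  for (a in 1:7) add(sprintf("bmi[%d]", a), "bmi", a)
  if (disease == "IHD") {
    for (m in 2:4) for (a in 1:7) {
      add(sprintf("phys[%d,%d]", a, m), "phys", a, level = m)
    }
    for (g in c("M", "F")) for (a in 1:7) {
      add(sprintf("smoke[%d,%s]", a, g), "smoke", a, g)
    }
  } else {
    for (m in 2:4) add(sprintf("phys[%d]", m), "phys", level = m)
    for (g in c("M", "F")) add(sprintf("smoke[%s]", g), "smoke", gender = g)
  }
  for (g in c("M", "F")) for (cc in 2:5) {
    add(sprintf("alc[%s,%d]", g, cc), "alc", gender = g, level = cc)
  }
  for (v in 2:5) add(sprintf("veg[%d]", v), "veg", level = v)
  for (f in 2:5) add(sprintf("fruit[%d]", f), "fruit", level = f)
  add("secsmoke", "secsmoke")
  for (t in 2:4) add(sprintf("trust[%d]", t), "trust", level = t)
  add("edu", "edu"); add("inc", "inc"); add("meth", "meth")
  for (r in 2:12) add(sprintf("region[%d]", r), "region", level = r)
  coefs <- do.call(rbind, rows)
  rownames(coefs) <- NULL
  structure(list(disease = disease, coefs = coefs, p = nrow(coefs)),
            class = "qihb_model_spec")
}

#' @export
print.qihb_model_spec <- function(x, ...) {
  cat(sprintf("<qihb_model_spec> %s: %d free coefficients\n", x$disease,
              x$p))
  print(table(factor(x$coefs$block, levels = BLOCK_ORDER)))
  invisible(x)
}

REQUIRED_COVARIATES <- c("age_bucket", "gender", "activity_level", "smoke",
                         "secsmoke", "alcohol", "veg", "fruit", "education",
                         "income", "bmi_excess", "trust", "region", "method")

#' Design matrix for a model spec
#'
#' One column per free coefficient, in spec order. Errors if any record is
#' missing a required covariate (use [fit_model()], which drops incomplete
#' records with a message, for fitting).
#'
#' @param survey a `qihb_survey` (or data frame with the survey fields).
#' @param spec a [model_spec()].
#' @return numeric matrix `n x p` with `colnames` the coefficient refs.
#' @export
design_matrix <- function(survey, spec) {
  if (!all(stats::complete.cases(survey[REQUIRED_COVARIATES]))) {
    abort_qihb("records with missing model covariates; drop or impute first",
               "qihb_missing_data")
  }
  n <- nrow(survey)
  refs <- spec$coefs$ref
  M <- matrix(0, n, length(refs), dimnames = list(NULL, refs))
  ii <- seq_len(n)
  a <- survey$age_bucket
  g <- as.character(survey$gender)
  M[cbind(ii, match(sprintf("demog[%d,%s]", a, g), refs))] <- 1
  M[cbind(ii, match(sprintf("bmi[%d]", a), refs))] <- survey$bmi_excess
  m <- survey$activity_level
  sel <- which(m >= 2)
  prefs <- if (spec$disease == "IHD") {
    sprintf("phys[%d,%d]", a[sel], m[sel])
  } else sprintf("phys[%d]", m[sel])
  M[cbind(sel, match(prefs, refs))] <- 1
  sm <- which(survey$smoke == 1)
  srefs <- if (spec$disease == "IHD") {
    sprintf("smoke[%d,%s]", a[sm], g[sm])
  } else sprintf("smoke[%s]", g[sm])
  M[cbind(sm, match(srefs, refs))] <- 1
  sel <- which(survey$alcohol >= 2)
  M[cbind(sel, match(sprintf("alc[%s,%d]", g[sel], survey$alcohol[sel]),
                     refs))] <- 1
  for (blk in c("veg", "fruit", "trust", "region")) {
    sel <- which(survey[[blk]] >= 2)
    M[cbind(sel, match(sprintf("%s[%d]", blk, survey[[blk]][sel]), refs))] <- 1
  }
  M[, "secsmoke"] <- survey$secsmoke
  M[, "edu"] <- survey$education
  M[, "inc"] <- survey$income
  M[, "meth"] <- survey$method
  M
}

#' Linear predictor for one record
#'
#' Sum of the applicable coefficients and slope-times-covariate products;
#' reference levels contribute 0.
#'
#' @param record single-row survey data frame.
#' @param params complete named coefficient vector.
#' @param spec a [model_spec()].
#' @return the logit of the record's disease probability.
#' @export
linear_predictor <- function(record, params, spec) {
  if (nrow(record) != 1) {
    abort_qihb("`record` must be a single row", "qihb_invalid_input")
  }
  drop(lp_vector(record, params, spec))
}

#' Inverse-logit disease probability
#'
#' Numerically stable `1 / (1 + exp(-x))`.
#'
#' @param logit numeric vector.
#' @return probabilities in `[0, 1]`.
#' @export
disease_probability <- function(logit) {
  if (anyNA(logit)) abort_qihb("logit must not be NA", "qihb_invalid_input")
  stats::plogis(logit)
}

#' Coefficient / relative-risk conversions
#'
#' Model coefficients live on the natural-log relative-risk scale (the log
#' relative risk and the log odds ratio are approximately equal for
#' low-probability events), so `exp()` of a coefficient is the implied
#' relative risk versus the reference level and `log()` of a relative risk
#' is the implied coefficient.
#'
#' @param beta log-scale coefficient(s).
#' @return `coefficient_to_rr()`: relative risk; `rr_to_coefficient()`:
#'   log relative risk.
#' @examples
#' coefficient_to_rr(-0.48)  # ~0.62: 62% of the reference risk
#' rr_to_coefficient(1.48)   # ~0.39
#' @export
coefficient_to_rr <- function(beta) exp(beta)

#' @param rr positive relative risk(s).
#' @rdname coefficient_to_rr
#' @export
rr_to_coefficient <- function(rr) {
  if (any(!is.finite(rr)) || any(rr <= 0)) {
    abort_qihb("`rr` must be positive", "qihb_invalid_input")
  }
  log(rr)
}

#' Normal prior from a relative-risk estimate
#'
#' Prior mean and standard deviation on the coefficient scale implied by a
#' mean and 95% interval of a relative risk: `mean = ln(rr_mean)`,
#' `sd = (ln(rr_high) - ln(rr_low)) / (2 * 1.959964)`. A degenerate
#' interval (`sd = 0`) is flagged as a fixed coefficient.
#'
#' @param rr_mean,rr_low,rr_high relative-risk mean and 95% bounds,
#'   `0 < rr_low <= rr_mean <= rr_high`.
#' @return list with `mean`, `sd` and `fixed` (`TRUE` when `sd == 0`).
#' @export
numerical_prior_from_rr <- function(rr_mean, rr_low, rr_high) {
  if (!(rr_low > 0 && rr_low <= rr_mean && rr_mean <= rr_high)) {
    abort_qihb("need 0 < rr_low <= rr_mean <= rr_high", "qihb_invalid_input")
  }
  sd <- (log(rr_high) - log(rr_low)) / (2 * 1.959964)
  list(mean = log(rr_mean), sd = sd, fixed = sd == 0)
}

# ---- prior specifications ---------------------------------------------------

new_prior_spec <- function(flavor, spec, mean, sd, var_group,
                           constraints = NULL, ig_shape = 5, ig_scale = 50) {
  structure(list(flavor = flavor, disease = spec$disease, mean = mean,
                 sd = sd, var_group = var_group, ig_shape = ig_shape,
                 ig_scale = ig_scale, constraints = constraints),
            class = "qihb_prior_spec")
}

#' Prior specifications for the three model flavors
#'
#' All flavors use independent normal priors on the coefficients.
#' `prior_noninformative()` fixes every prior standard deviation at a wide
#' constant and imposes no constraints. `prior_qualitative()` centers every
#' coefficient at 0, shares an Inverse-Gamma(5, 50) hyper-prior variance
#' per coefficient block (the scalar slopes share one), and attaches the
#' compiled inequality constraints, which act as truncation of the prior
#' support. `prior_numerical()` keeps the hierarchical structure but fixes
#' the mean and standard deviation of the coefficients matched by the
#' relative-risk table (physical activity, smoking, second-hand smoke and
#' BMI) at the values implied by [numerical_prior_from_rr()]; entries with
#' degenerate intervals pin the coefficient at its prior mean.
#'
#' @param spec a [model_spec()].
#' @param sd prior standard deviation for the non-informative flavor.
#' @return a `qihb_prior_spec`.
#' @export
prior_noninformative <- function(spec, sd = 10) {
  p <- spec$p
  new_prior_spec("noninformative", spec, rep(0, p), rep(sd, p),
                 rep(0L, p))
}

#' @param constraints a [compile_constraints()] result for `spec`.
#' @rdname prior_noninformative
#' @export
prior_qualitative <- function(spec, constraints) {
  if (!identical(attr(constraints, "spec")$disease, spec$disease)) {
    abort_qihb("constraints compiled for a different disease",
               "qihb_spec_mismatch")
  }
  p <- spec$p
  vg <- unname(VAR_GROUPS[spec$coefs$block])
  new_prior_spec("qualitative", spec, rep(0, p), rep(NA_real_, p), vg,
                 constraints = constraints)
}

#' @param rr a `qihb_rr_table` supplying the numerical prior information.
#' @rdname prior_noninformative
#' @export
prior_numerical <- function(spec, rr) {
  p <- spec$p
  vg <- unname(VAR_GROUPS[spec$coefs$block])
  mean <- rep(0, p)
  sd <- rep(NA_real_, p)
  rr <- rr[rr$disease == spec$disease, , drop = FALSE]
  for (k in seq_len(p)) {
    row <- spec$coefs[k, ]
    if (!row$block %in% c("phys", "smoke", "secsmoke", "bmi")) next
    hit <- rr_lookup(rr, row$block, row$level, row$age, row$gender)
    if (is.null(hit)) next
    pr <- numerical_prior_from_rr(hit$rr_mean, hit$rr_low, hit$rr_high)
    mean[k] <- pr$mean
    sd[k] <- pr$sd
    vg[k] <- 0L
  }
  new_prior_spec("numerical", spec, mean, sd, vg)
}

# Most specific RR entry for a coefficient: exact level/age/gender first,
# falling back to the "ALL" wildcard per dimension.
rr_lookup <- function(rr, block, level, age, gender) {
  sl <- rr[rr$factor == block, , drop = FALSE]
  if (nrow(sl) == 0) return(NULL)
  score <- function(col, want) {
    if (is.na(want)) ifelse(sl[[col]] == "ALL", 0, -Inf)
    else ifelse(sl[[col]] == as.character(want), 1,
                ifelse(sl[[col]] == "ALL", 0, -Inf))
  }
  s <- score("level", level) + score("age_bucket", age) +
    score("gender", gender)
  if (all(!is.finite(s))) return(NULL)
  as.list(sl[which.max(s), c("rr_mean", "rr_low", "rr_high")])
}

#' Parameter set CSV I/O
#'
#' Two-column CSV `coef_ref,value`.
#'
#' @param params named coefficient vector.
#' @param path file path.
#' @export
write_params <- function(params, path) {
  utils::write.csv(data.frame(coef_ref = names(params),
                              value = as.numeric(params)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @param spec optional [model_spec()] to validate completeness against.
#' @rdname write_params
#' @export
read_params <- function(path, spec = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  params <- stats::setNames(df$value, df$coef_ref)
  if (!is.null(spec)) {
    if (!setequal(names(params), spec$coefs$ref)) {
      abort_qihb("parameter file does not match the model spec",
                 "qihb_spec_mismatch")
    }
    params <- params[spec$coefs$ref]
    attr(params, "spec") <- spec
    class(params) <- "qihb_params"
  }
  params
}
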