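# MCMC fitting: Metropolis-within-Gibbs with truncated priors, plus
# convergence diagnostics.

#' MCMC configuration
#'
#' @param chains number of chains (default 3).
#' @param iterations retained iterations per chain after burn-in
#'   (default 5000).
#' @param burn_in discarded initial iterations per chain (default 1000).
#' @param proposal_scale initial random-walk proposal standard deviation,
#'   one value or one per coefficient block.
#' @param seed integer seed.
#' @param adapt adapt proposal scales during burn-in only (target
#'   acceptance around 0.3), frozen afterwards so detailed balance holds
#'   over the retained draws.
#' @return a `qihb_mcmc_config`.
#' @export
mcmc_config <- function(chains = 3, iterations = 5000, burn_in = 1000,
                        proposal_scale = 0.1, seed = 1, adapt = TRUE) {
  if (chains < 1 || iterations < 1 || burn_in < 0) {
    abort_qihb("need chains >= 1, iterations >= 1, burn_in >= 0",
               "qihb_config_error")
  }
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in),
                 proposal_scale = proposal_scale,
                 seed = as.integer(seed), adapt = isTRUE(adapt)),
            class = "qihb_mcmc_config")
}

# Low-level sampler on an explicit design matrix. Exposed internally so the
# 1-D truncation tests can target it directly.
mcmc_logistic <- function(X, y, blocks, prior_mean, prior_sd, var_group,
                          cons, mcmc, n_groups = max(c(0L, var_group)),
                          beta_init = NULL, ig_shape = 5, ig_scale = 50) {
  p <- ncol(X)
  nb <- length(blocks)
  scale <- rep(mcmc$proposal_scale, length.out = nb)
  beta_init <- beta_init %||% rep(0, p)
  cons_by_block <- lapply(blocks, function(cols) {
    if (nrow(cons$idx) == 0) return(integer(0))
    which(cons$idx[, 1] %in% cols | cons$idx[, 2] %in% cols)
  })
  draws <- vector("list", mcmc$chains)
  sig <- vector("list", mcmc$chains)
  accept <- matrix(NA_real_, mcmc$chains, nb,
                   dimnames = list(NULL, names(blocks)))
  set.seed(mcmc$seed)
  for (ch in seq_len(mcmc$chains)) {
    res <- mcmc_chain_cpp(X, y, unname(blocks), beta_init, prior_mean,
                          prior_sd, as.integer(var_group),
                          as.integer(n_groups), ig_shape, ig_scale,
                          cbind(cons$idx, deparse.level = 0),
                          cbind(cons$sign, deparse.level = 0),
                          cons_by_block, mcmc$iterations, mcmc$burn_in,
                          scale, mcmc$adapt)
    colnames(res$draws) <- colnames(X)
    draws[[ch]] <- res$draws
    sig[[ch]] <- res$sigma2
    accept[ch, ] <- res$accept
  }
  list(draws = do.call(rbind, draws),
       chain = rep(seq_len(mcmc$chains), each = mcmc$iterations),
       sigma2 = do.call(rbind, sig), accept = accept)
}

#' Fit a disease probability model by MCMC
#'
#' Metropolis-within-Gibbs: each coefficient block receives a joint
#' random-walk proposal accepted with the Metropolis ratio of the
#' Bernoulli-logit likelihood times the (possibly truncated) normal prior;
#' proposals that violate any compiled inequality have zero prior density
#' and are rejected, so every retained draw is feasible. Shared block
#' variances are refreshed each sweep by conjugate inverse-gamma draws.
#' Chains start at the all-zero vector (feasible by construction of the
#' constraint sets).
#'
#' Records with any missing model covariate are excluded from the
#' likelihood with a message reporting the count.
#'
#' @param survey a `qihb_survey` containing the outcome column for the
#'   spec's disease.
#' @param spec a [model_spec()].
#' @param priors a prior specification ([prior_qualitative()],
#'   [prior_numerical()] or [prior_noninformative()]).
#' @param constraints optional `qihb_constraints`; defaults to the one
#'   attached to a qualitative prior.
#' @param mcmc a [mcmc_config()].
#' @return `qihb_posterior`: list with `draws` (retained draws x
#'   coefficients), `chain`, `sigma2`, `accept` (per chain x block),
#'   `rhat` (split-R-hat per coefficient when `chains >= 2`), `spec`,
#'   `flavor`, `constraints`, `mcmc`, `n_used`, `n_dropped`.
#' @export
fit_model <- function(survey, spec, priors, constraints = NULL,
                      mcmc = mcmc_config()) {
  if (is.null(constraints) && identical(priors$flavor, "qualitative")) {
    constraints <- priors$constraints
  }
  if (!is.null(constraints) && priors$flavor != "qualitative") {
    message("constraints ignored for flavor '", priors$flavor, "'")
    constraints <- NULL
  }
  if (!identical(priors$disease, spec$disease)) {
    abort_qihb("priors built for a different disease", "qihb_spec_mismatch")
  }
  d <- spec$disease
  if (!d %in% names(survey)) {
    abort_qihb(sprintf("survey has no outcome column '%s'", d),
               "qihb_data_error")
  }
  keep <- stats::complete.cases(survey[c(REQUIRED_COVARIATES, d)])
  if (!any(keep)) abort_qihb("no complete records", "qihb_data_error")
  if (any(!keep)) {
    message(sum(!keep), " record(s) with missing covariates excluded")
    survey <- survey[keep, , drop = FALSE]
  }
  y <- as.numeric(survey[[d]])
  if (all(y == 0) || all(y == 1)) {
    warning("degenerate outcome column (single class); fitting anyway")
  }

  cons <- if (is.null(constraints)) {
    list(idx = matrix(0L, 0, 2), sign = matrix(0, 0, 2))
  } else {
    cm <- constraints_matrix(constraints, spec)
    zero <- stats::setNames(rep(0, spec$p), spec$coefs$ref)
    if (!check_constraints(zero, constraints)) {
      abort_qihb("constraint set infeasible at the zero vector",
                 "qihb_constraint_error")
    }
    cm
  }

  X <- design_matrix(survey, spec)
  blocks <- split(seq_len(spec$p),
                  factor(spec$coefs$block, levels = BLOCK_ORDER))
  # Proposal granularity: blocks whose coefficients appear in any
  # inequality are updated one coefficient at a time (a joint random-walk
  # on an order-constrained block is rejected almost surely), other blocks
  # jointly.
  constrained_cols <- unique(as.vector(cons$idx))
  units <- list()
  for (b in names(blocks)) {
    cols <- blocks[[b]]
    if (any(cols %in% constrained_cols)) {
      for (j in cols) units[[spec$coefs$ref[j]]] <- j
    } else if (length(cols)) {
      units[[b]] <- cols
    }
  }
  blocks <- units
  # pinned coefficients (fixed prior sd 0) are excluded from sampling
  pinned <- priors$var_group == 0 & !is.na(priors$sd) & priors$sd == 0
  if (any(pinned)) {
    blocks <- lapply(blocks, function(cols) cols[!pinned[cols]])
  }
  beta_init <- rep(0, spec$p)
  beta_init[pinned] <- priors$mean[pinned]

  res <- mcmc_logistic(X, y, blocks, priors$mean,
                       ifelse(is.na(priors$sd), 1, priors$sd),
                       priors$var_group, cons, mcmc,
                       n_groups = max(c(0L, priors$var_group)),
                       beta_init = beta_init, ig_shape = priors$ig_shape,
                       ig_scale = priors$ig_scale)
  rhat <- if (mcmc$chains >= 2) {
    gelman_rubin(res$draws, res$chain)
  } else NULL
  structure(list(draws = res$draws, chain = res$chain, sigma2 = res$sigma2,
                 accept = res$accept, rhat = rhat, spec = spec,
                 flavor = priors$flavor, constraints = constraints,
                 mcmc = mcmc, n_used = nrow(survey),
                 n_dropped = sum(!keep)),
            class = "qihb_posterior")
}

#' @export
print.qihb_posterior <- function(x, ...) {
  cat(sprintf("<qihb_posterior> %s (%s): %d draws x %d coefficients, %d chain(s)\n",
              x$spec$disease, x$flavor, nrow(x$draws), ncol(x$draws),
              length(unique(x$chain))))
  if (!is.null(x$rhat)) {
    bad <- sum(x$rhat > 1.1, na.rm = TRUE)
    cat(sprintf("max split-Rhat %.3f (%d coefficient(s) above 1.1)\n",
                max(x$rhat, na.rm = TRUE), bad))
  }
  invisible(x)
}

#' Posterior point estimate
#'
#' @param fit a `qihb_posterior` (posterior mean of the draws) or a named
#'   coefficient vector (returned unchanged).
#' @return named numeric vector.
#' @export
point_estimate <- function(fit) {
  if (inherits(fit, "qihb_posterior")) colMeans(fit$draws)
  else if (is.numeric(fit) && !is.null(names(fit))) fit
  else abort_qihb("cannot extract a point estimate", "qihb_invalid_input")
}

#' Split Gelman-Rubin diagnostic
#'
#' Standard split-R-hat: each chain is halved, and the ratio of pooled to
#' within-sequence variance is computed per coefficient. Constant
#' coefficients report 1 (zero-variance guard). Coefficients with values
#' above 1.1 have not converged by the package's working threshold.
#'
#' @param x a `qihb_posterior`, or a draws matrix.
#' @param chain chain index per row (required when `x` is a matrix).
#' @return named vector of R-hat values.
#' @export
gelman_rubin <- function(x, chain = NULL) {
  if (inherits(x, "qihb_posterior")) {
    chain <- x$chain
    x <- x$draws
  }
  if (is.null(chain)) abort_qihb("chain ids required", "qihb_invalid_input")
  chains <- unique(chain)
  if (length(chains) < 2) {
    abort_qihb("diagnostic unavailable with a single chain",
               "qihb_diagnostic_error")
  }
  if (min(table(chain)) < 10) {
    abort_qihb("need >= 10 draws per chain", "qihb_invalid_input")
  }
  halves <- list()
  for (ch in chains) {
    idx <- which(chain == ch)
    h <- length(idx) %/% 2
    halves[[length(halves) + 1]] <- idx[seq_len(h)]
    halves[[length(halves) + 1]] <- idx[(h + 1):(2 * h)]
  }
  n2 <- min(lengths(halves))
  halves <- lapply(halves, function(i) i[seq_len(n2)])
  m <- length(halves)
  apply(x, 2, function(v) {
    seqs <- vapply(halves, function(i) v[i], numeric(n2))
    W <- mean(apply(seqs, 2, stats::var))
    if (!is.finite(W) || W == 0) return(1)
    B <- n2 * stats::var(colMeans(seqs))
    sqrt(((n2 - 1) / n2 * W + B / n2) / W)
  })
}

#' Posterior draws CSV I/O
#'
#' Long-format CSV (`draw`, `chain`, `coef_ref`, `value`) plus a YAML run
#' manifest alongside (same path with extension `.manifest.yaml`).
#'
#' @param fit a `qihb_posterior`.
#' @param path CSV output path.
#' @export
write_posterior <- function(fit, path) {
  p <- ncol(fit$draws)
  nd <- nrow(fit$draws)
  utils::write.csv(data.frame(
    draw = rep(seq_len(nd), times = p),
    chain = rep(fit$chain, times = p),
    coef_ref = rep(colnames(fit$draws), each = nd),
    value = as.vector(fit$draws)), path, row.names = FALSE)
  manifest <- list(disease = fit$spec$disease, flavor = fit$flavor,
                   mcmc = unclass(fit$mcmc),
                   n_used = fit$n_used, n_dropped = fit$n_dropped,
                   accept = as.list(round(colMeans(fit$accept), 4)),
                   rhat_max = if (!is.null(fit$rhat))
                     max(fit$rhat, na.rm = TRUE) else NA)
  yaml::write_yaml(manifest, sub("\\.csv$", ".manifest.yaml", path))
  invisible(path)
}

#' @param spec the [model_spec()] the draws belong to.
#' @rdname write_posterior
#' @export
read_posterior <- function(path, spec) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  refs <- spec$coefs$ref
  if (!setequal(unique(df$coef_ref), refs)) {
    abort_qihb("posterior file does not match the model spec",
               "qihb_spec_mismatch")
  }
  nd <- max(df$draw)
  draws <- matrix(NA_real_, nd, length(refs), dimnames = list(NULL, refs))
  for (ref in refs) {
    sub <- df[df$coef_ref == ref, ]
    draws[sub$draw, ref] <- sub$value
  }
  chain <- df$chain[match(seq_len(nd), df$draw)]
  structure(list(draws = draws, chain = chain, sigma2 = NULL,
                 accept = NULL, rhat = NULL, spec = spec,
                 flavor = "loaded", constraints = NULL, mcmc = NULL,
                 n_used = NA, n_dropped = NA),
            class = "qihb_posterior")
}
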