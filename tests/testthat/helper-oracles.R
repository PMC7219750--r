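# Independent oracles used by the tests; deliberately naive implementations
# kept separate from the package code paths they check.

# Exhaustive pairwise AUC with half-credit ties.
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Per-record, per-draw reference implementation of the scenario simulator.
naive_simulate <- function(survey, scn, fits, dpp, n_draws,
                           mask_fruit = TRUE) {
  scn_survey <- apply_scenario(survey, scn)
  out <- list()
  for (d in names(fits)) {
    fit <- fits[[d]]
    spec <- fit$spec
    B <- fit$draws[seq_len(n_draws), , drop = FALSE]
    if (d == "Diabetes" && mask_fruit) {
      B[, grep("^fruit\\[", colnames(B))] <- 0
    }
    pd <- pp <- numeric(n_draws)
    for (k in seq_len(n_draws)) {
      par <- B[k, ]
      d0 <- d1 <- p0 <- p1 <- 0
      for (i in seq_len(nrow(survey))) {
        th0 <- disease_probability(
          linear_predictor(survey[i, , drop = FALSE], par, spec))
        th1 <- disease_probability(
          linear_predictor(scn_survey[i, , drop = FALSE], par, spec))
        w <- dpp$dpp[dpp$disease == d &
                       dpp$age_bucket == survey$age_bucket[i] &
                       dpp$gender == survey$gender[i]]
        d0 <- d0 + th0 * w
        d1 <- d1 + th1 * w
        p0 <- p0 + th0
        p1 <- p1 + th1
      }
      pd[k] <- 100 * (d1 - d0) / d0
      pp[k] <- 100 * (p1 - p0) / p0
    }
    out[[d]] <- list(daly = pd, prev = pp)
  }
  out
}

# Wrap an explicit draws matrix as a posterior container.
fake_posterior <- function(draws, spec) {
  structure(list(draws = draws, chain = rep(1L, nrow(draws)),
                 sigma2 = NULL, accept = NULL, rhat = NULL, spec = spec,
                 flavor = "fixed", constraints = NULL, mcmc = NULL,
                 n_used = NA, n_dropped = NA),
            class = "qihb_posterior")
}

# All retained draws satisfy the constraint set?
all_draws_feasible <- function(fit, constraints) {
  all(apply(fit$draws, 1, function(dr) check_constraints(dr, constraints)))
}
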