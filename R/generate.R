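# Seeded synthetic-survey generator with latent-Gaussian copula dependence
# between fruit and vegetable consumption and between smoking and
# second-hand-smoke exposure. All other covariates are drawn independently
# from configurable marginals.

#' Generator configuration
#'
#' Marginal distributions and dependence targets for the synthetic survey.
#' The behavior defaults reproduce the base-case marginal distribution of
#' behaviors in the 2016 survey wave (18/45/10/27% activity levels, 44%
#' smokers, 26% exposed to second-hand smoke, and the five-level fruit and
#' vegetable consumption frequencies), with the fruit-vegetable level
#' correlation targeted at 0.49 and the smoking/second-hand-smoke
#' correlation at 0.14. Demographic and socioeconomic marginals are
#' package defaults chosen to be plausible for a national adult survey.
#'
#' @param activity,veg,fruit,alcohol,age,trust,region probability vectors
#'   over the respective category codes (must each sum to 1 within 1e-9).
#' @param smoke,secsmoke probability of the exposed (=1) state.
#' @param fruit_veg_cor,smoke_secsmoke_cor target sample correlations
#'   induced via the latent-Gaussian copula.
#' @param latent_fruit_veg,latent_smoke_secsmoke optional overrides for the
#'   latent correlation parameters; when `NULL` they are calibrated by
#'   bisection so the discretized sample correlations approach the targets.
#' @param female probability of gender `"F"`.
#' @param education_years named probability vector; names are years of
#'   education.
#' @param income_meanlog,income_sdlog log-normal parameters of the raw
#'   income index before standardization.
#' @param bmi_mean,bmi_sd normal parameters for BMI (kg/m^2) before the
#'   hinge transform.
#' @param years named probability vector over survey years.
#' @param activity_missing probability that `activity_level` is missing
#'   (missing at random).
#' @return a `qihb_generator_config` list.
#' @export
generator_config <- function(activity = c(0.18, 0.45, 0.10, 0.27),
                             smoke = 0.44,
                             secsmoke = 0.26,
                             veg = c(1, 3, 16, 19, 62) / 101,
                             fruit = c(2, 6, 23, 17, 53) / 101,
                             alcohol = c(0.85, 0.08, 0.04, 0.02, 0.01),
                             fruit_veg_cor = 0.49,
                             smoke_secsmoke_cor = 0.14,
                             latent_fruit_veg = NULL,
                             latent_smoke_secsmoke = NULL,
                             age = c(0.21, 0.19, 0.17, 0.15, 0.12, 0.09, 0.07),
                             female = 0.5,
                             education_years = c("0" = 0.12, "5" = 0.35,
                                                 "8" = 0.18, "11" = 0.20,
                                                 "15" = 0.15),
                             income_meanlog = 0,
                             income_sdlog = 0.6,
                             bmi_mean = 26.5,
                             bmi_sd = 4.5,
                             trust = c(0.15, 0.30, 0.25, 0.30),
                             region = c(0.19, 0.10, 0.08, 0.07, 0.09, 0.07,
                                        0.06, 0.08, 0.06, 0.07, 0.07, 0.06),
                             years = c("2016" = 1),
                             activity_missing = 0) {
  cfg <- list(activity = activity, smoke = smoke, secsmoke = secsmoke,
              veg = veg, fruit = fruit, alcohol = alcohol,
              fruit_veg_cor = fruit_veg_cor,
              smoke_secsmoke_cor = smoke_secsmoke_cor,
              latent_fruit_veg = latent_fruit_veg,
              latent_smoke_secsmoke = latent_smoke_secsmoke,
              age = age, female = female,
              education_years = education_years,
              income_meanlog = income_meanlog, income_sdlog = income_sdlog,
              bmi_mean = bmi_mean, bmi_sd = bmi_sd,
              trust = trust, region = region, years = years,
              activity_missing = activity_missing)
  validate_generator_config(cfg)
  structure(cfg, class = "qihb_generator_config")
}

validate_generator_config <- function(cfg) {
  lens <- c(activity = 4, veg = 5, fruit = 5, alcohol = 5, age = 7,
            trust = 4, region = 12)
  for (nm in names(lens)) {
    p <- cfg[[nm]]
    if (length(p) != lens[[nm]] || any(p < 0) ||
        abs(sum(p) - 1) > 1e-9) {
      abort_qihb(sprintf(
        "marginal `%s` must be %d non-negative probabilities summing to 1",
        nm, lens[[nm]]), "qihb_config_error")
    }
  }
  for (nm in c("smoke", "secsmoke", "female", "activity_missing")) {
    p <- cfg[[nm]]
    if (!is.numeric(p) || length(p) != 1 || p < 0 || p > 1) {
      abort_qihb(sprintf("`%s` must be a probability", nm),
                 "qihb_config_error")
    }
  }
  for (nm in c("education_years", "years")) {
    p <- cfg[[nm]]
    if (is.null(names(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      abort_qihb(sprintf("`%s` must be a named probability vector", nm),
                 "qihb_config_error")
    }
  }
  invisible(TRUE)
}

# ---- copula calibration -----------------------------------------------------

# Sample correlation of the two discretized variables at latent correlation
# rho, on a fixed set of common random numbers (so the map rho -> correlation
# is deterministic and monotone for the bisection).
discretized_cor <- function(rho, cuts1, cuts2, z1, z2) {
  w2 <- rho * z1 + sqrt(1 - rho^2) * z2
  x1 <- findInterval(z1, cuts1) + 1L
  x2 <- findInterval(w2, cuts2) + 1L
  if (stats::sd(x1) == 0 || stats::sd(x2) == 0) return(0)
  stats::cor(x1, x2)
}

# Bisection for the latent correlation that induces the target sample
# correlation after discretization by the marginal quantiles. Uses n = 1e5
# latent draws under a fixed internal seed, without touching the caller's
# RNG stream.
calibrate_latent_rho <- function(target, marg1, marg2, n = 1e5,
                                 internal_seed = 903001, tol = 1e-3) {
  if (abs(target) < 1e-12) return(0)
  key <- paste0("rho:", paste(signif(c(target, marg1, marg2), 10),
                              collapse = ","))
  cache_get_or(key, function() {
    z <- with_preserved_seed({
      set.seed(internal_seed)
      list(z1 = stats::rnorm(n), z2 = stats::rnorm(n))
    })
    cuts1 <- stats::qnorm(cumsum(marg1)[-length(marg1)])
    cuts2 <- stats::qnorm(cumsum(marg2)[-length(marg2)])
    lo <- -0.999; hi <- 0.999
    for (i in 1:40) {
      mid <- (lo + hi) / 2
      v <- discretized_cor(mid, cuts1, cuts2, z$z1, z$z2)
      if (abs(v - target) < tol) return(mid)
      if (v < target) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  })
}

# Draw a pair of categorical variables through the latent-Gaussian copula.
draw_copula_pair <- function(n, rho, marg1, marg2) {
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  cuts1 <- stats::qnorm(cumsum(marg1)[-length(marg1)])
  cuts2 <- stats::qnorm(cumsum(marg2)[-length(marg2)])
  list(x1 = findInterval(z1, cuts1) + 1L,
       x2 = findInterval(z2, cuts2) + 1L)
}

#' Generate a synthetic survey
#'
#' Draws `n` respondent records from the configured marginals. Fruit and
#' vegetable consumption levels, and smoking and second-hand-smoke
#' indicators, are drawn jointly through a two-block latent-Gaussian copula
#' whose latent correlations are calibrated by bisection against the
#' configured sample-correlation targets; all other covariates are
#' independent. Reproducible given `seed`.
#'
#' @param n number of records (>= 1).
#' @param config a [generator_config()].
#' @param seed integer seed.
#' @return a `qihb_survey` without outcome columns (see
#'   [generate_outcomes()]).
#' @examples
#' s <- generate_survey(500, seed = 1)
#' mean(s$smoke)
#' @export
generate_survey <- function(n, config = generator_config(), seed = 1) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    abort_qihb("`n` must be a positive count", "qihb_config_error")
  }
  validate_generator_config(config)
  n <- as.integer(n)

  rho_fv <- config$latent_fruit_veg %||%
    calibrate_latent_rho(config$fruit_veg_cor, config$fruit, config$veg)
  rho_ss <- config$latent_smoke_secsmoke %||%
    calibrate_latent_rho(config$smoke_secsmoke_cor,
                         c(1 - config$smoke, config$smoke),
                         c(1 - config$secsmoke, config$secsmoke))

  set.seed(seed)
  age <- sample.int(7L, n, replace = TRUE, prob = config$age)
  gender <- ifelse(stats::runif(n) < config$female, "F", "M")
  activity <- sample.int(4L, n, replace = TRUE, prob = config$activity)
  if (config$activity_missing > 0) {
    activity[stats::runif(n) < config$activity_missing] <- NA_integer_
  }
  fv <- draw_copula_pair(n, rho_fv, config$fruit, config$veg)
  ss <- draw_copula_pair(n, rho_ss,
                         c(1 - config$smoke, config$smoke),
                         c(1 - config$secsmoke, config$secsmoke))
  alcohol <- sample.int(5L, n, replace = TRUE, prob = config$alcohol)
  education <- as.numeric(sample(names(config$education_years), n,
                                 replace = TRUE,
                                 prob = config$education_years))
  raw_inc <- stats::rlnorm(n, config$income_meanlog, config$income_sdlog)
  m <- exp(config$income_meanlog + config$income_sdlog^2 / 2)
  s <- sqrt((exp(config$income_sdlog^2) - 1)) * m
  income <- (raw_inc - m) / s
  bmi <- pmax(12.1, stats::rnorm(n, config$bmi_mean, config$bmi_sd))
  trust <- sample.int(4L, n, replace = TRUE, prob = config$trust)
  region <- sample.int(12L, n, replace = TRUE, prob = config$region)
  year <- as.integer(sample(names(config$years), n, replace = TRUE,
                            prob = config$years))

  df <- data.frame(age_bucket = age, gender = gender,
                   activity_level = activity,
                   smoke = ss$x1 - 1L, secsmoke = ss$x2 - 1L,
                   alcohol = alcohol, veg = fv$x2, fruit = fv$x1,
                   education = education, income = income,
                   bmi_excess = bmi_transform(bmi),
                   trust = trust, region = region,
                   method = as.integer(year >= 2014), year = year,
                   stringsAsFactors = FALSE)
  as_survey(df, provenance = "synthetic", seed = seed)
}

# ---- ground-truth parameters ------------------------------------------------

#' Feasible ground-truth parameters
#'
#' Draws a parameter set that satisfies every inequality in a compiled
#' constraint set, for use as the known truth in parameter-recovery
#' experiments. Construction: independent normal draws per free coefficient;
#' coefficients under a sign constraint take the signed absolute value;
#' coefficients linked by order constraints are reassigned along the
#' constraint graph so every ordering holds (values sorted by graph depth).
#' The demographic age-gender cells, which act as per-cell intercepts, are
#' shifted by `baseline` after ordering so that synthetic outcome
#' prevalences are realistic for chronic-disease self-reports (around 10%
#' at the default) rather than 50%.
#'
#' @param constraints a [compile_constraints()] result (carries its model
#'   spec).
#' @param scale standard deviation of the raw coefficient draws (> 0).
#' @param seed integer seed.
#' @param baseline shift added to the demographic cells (order constraints
#'   are invariant to it).
#' @return named numeric vector of coefficients with attribute `spec`,
#'   class `qihb_params`.
#' @export
make_true_params <- function(constraints, scale = 0.5, seed = 1,
                             baseline = -2.2) {
  if (!is.numeric(scale) || scale <= 0) {
    abort_qihb("`scale` must be > 0", "qihb_config_error")
  }
  spec <- attr(constraints, "spec")
  if (is.null(spec)) {
    abort_qihb("constraints carry no model spec", "qihb_spec_mismatch")
  }
  refs <- spec$coefs$ref
  set.seed(seed)
  theta <- stats::setNames(stats::rnorm(length(refs), 0, scale), refs)
  # slopes on wide-ranging continuous covariates (BMI excess, years of
  # education, income index) act per unit, so their plausible magnitude is
  # an order smaller than categorical contrasts
  slope <- spec$coefs$block %in% c("bmi", "edu", "inc")
  theta[slope] <- theta[slope] / 10

  # sign projection
  sgn <- constraint_signs(constraints, refs)
  pos <- !is.na(sgn) & sgn > 0
  neg <- !is.na(sgn) & sgn < 0
  theta[pos] <- abs(theta[pos])
  theta[neg] <- -abs(theta[neg])

  # order projection: within each weakly-connected component of the order
  # graph, assign the component's values sorted by longest-path depth
  # (larger values to nodes that must dominate).
  ord <- constraints[constraints$type == "order", , drop = FALSE]
  if (nrow(ord)) {
    # canonical edges hi -> lo meaning theta[hi] >= theta[lo]
    hi <- ifelse(ord$op == "a_ge_b", ord$ref_a, ord$ref_b)
    lo <- ifelse(ord$op == "a_ge_b", ord$ref_b, ord$ref_a)
    nodes <- unique(c(hi, lo))
    depth <- stats::setNames(rep(0L, length(nodes)), nodes)
    for (pass in seq_len(length(nodes))) {
      changed <- FALSE
      for (e in seq_along(hi)) {
        if (depth[lo[e]] < depth[hi[e]] + 1L) {
          depth[lo[e]] <- depth[hi[e]] + 1L
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    comp <- stats::setNames(seq_along(nodes), nodes)
    for (pass in seq_len(length(nodes))) {
      changed <- FALSE
      for (e in seq_along(hi)) {
        m <- min(comp[hi[e]], comp[lo[e]])
        if (comp[hi[e]] != m || comp[lo[e]] != m) {
          comp[hi[e]] <- m; comp[lo[e]] <- m
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    for (cid in unique(comp)) {
      members <- nodes[comp == cid]
      o <- order(depth[members], members)   # deterministic tie-break
      theta[members[o]] <- sort(theta[members], decreasing = TRUE)
    }
  }

  demog <- refs[spec$coefs$block == "demog"]
  theta[demog] <- theta[demog] + baseline

  stopifnot(check_constraints(theta, constraints))
  structure(theta, spec = spec, class = "qihb_params")
}

#' Bundle per-disease ground-truth parameters
#'
#' @param ... named `qihb_params` (names are diseases), or a single named
#'   list.
#' @return list of parameter sets, class `qihb_true_model`.
#' @export
true_model <- function(...) {
  parts <- list(...)
  if (length(parts) == 1 && is.list(parts[[1]]) &&
      !inherits(parts[[1]], "qihb_params")) {
    parts <- parts[[1]]
  }
  if (is.null(names(parts)) || !all(names(parts) %in% DISEASES)) {
    abort_qihb("true_model components must be named by disease",
               "qihb_config_error")
  }
  structure(parts, class = "qihb_true_model")
}

#' Generate Bernoulli disease outcomes
#'
#' Adds one binary outcome column per disease in `tm`, drawn
#' `Bernoulli(theta)` with `theta` the inverse-logit of each record's linear
#' predictor under the ground-truth parameters. Records missing a covariate
#' required by a model raise a missing-data error.
#'
#' Use a `seed` different from the one that generated the survey: reusing
#' it would replay the covariate RNG stream for the outcome draws and
#' induce spurious dependence between the disease probabilities and the
#' realized outcomes.
#'
#' @param survey a `qihb_survey`.
#' @param tm a [true_model()] (or single `qihb_params`, taken as its spec's
#'   disease).
#' @param seed integer seed.
#' @return the survey with outcome columns appended.
#' @export
generate_outcomes <- function(survey, tm, seed = 1) {
  if (inherits(tm, "qihb_params")) {
    tm <- true_model(stats::setNames(list(tm), attr(tm, "spec")$disease))
  }
  set.seed(seed)
  for (d in names(tm)) {
    params <- tm[[d]]
    spec <- attr(params, "spec")
    eta <- lp_vector(survey, params, spec)
    theta <- stats::plogis(eta)
    survey[[d]] <- stats::rbinom(nrow(survey), 1L, theta)
  }
  survey
}

# Linear predictor for all records; tolerates infinite coefficients by
# zeroing their contribution where the covariate is 0 (reference levels
# contribute nothing even against an infinite coefficient).
lp_vector <- function(survey, params, spec) {
  X <- design_matrix(survey, spec)
  beta <- as.numeric(params[colnames(X)])
  if (anyNA(beta)) {
    abort_qihb("parameter set incomplete for model spec",
               "qihb_spec_mismatch")
  }
  inf <- which(!is.finite(beta))
  if (!length(inf)) return(drop(X %*% beta))
  bfin <- beta
  bfin[inf] <- 0
  eta <- drop(X %*% bfin)
  for (j in inf) {
    contrib <- X[, j] * beta[j]
    contrib[X[, j] == 0] <- 0
    eta <- eta + contrib
  }
  eta
}
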