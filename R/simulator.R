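# Counterfactual behavior scenarios and the DALY simulator.

#' Read a DALY-per-prevalent-case table
#'
#' CSV with columns `disease, age_bucket, gender, dpp` (years of healthy
#' life lost per existing case). Must be positive and complete over the
#' 7 age buckets x 2 genders per disease.
#'
#' @param path file path.
#' @return data frame of class `qihb_dpp_table`.
#' @export
read_dpp_table <- function(path) {
  as_dpp_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @param data data frame with the DPP columns.
#' @rdname read_dpp_table
#' @export
as_dpp_table <- function(data) {
  need <- c("disease", "age_bucket", "gender", "dpp")
  if (!all(need %in% names(data))) {
    abort_qihb("DPP table needs columns disease, age_bucket, gender, dpp",
               "qihb_data_error")
  }
  if (any(data$dpp <= 0)) {
    abort_qihb("DPP values must be positive", "qihb_data_error")
  }
  for (d in unique(data$disease)) {
    sl <- data[data$disease == d, ]
    if (nrow(unique(sl[c("age_bucket", "gender")])) != 14) {
      abort_qihb(sprintf("DPP table incomplete for %s (need 7 ages x 2 genders)",
                         d), "qihb_data_error")
    }
  }
  structure(data, class = c("qihb_dpp_table", "data.frame"))
}

# DPP value per record for one disease.
dpp_for_records <- function(dpp, disease, survey) {
  sl <- dpp[dpp$disease == disease, ]
  key <- paste(sl$age_bucket, sl$gender)
  want <- paste(survey$age_bucket, survey$gender)
  hit <- match(want, key)
  if (anyNA(hit)) {
    abort_qihb(sprintf("DPP cell missing for %s: %s", disease,
                       paste(unique(want[is.na(hit)]), collapse = ", ")),
               "qihb_data_error")
  }
  sl$dpp[hit]
}

#' Behavior-change scenario
#'
#' A named set of level maps applied record-wise. Each transform maps a
#' behavior's current level to a counterfactual level; individuals already
#' at the most desirable level stay unchanged, and the activity transform
#' leaves records with unknown activity level untouched.
#'
#' @param name scenario label.
#' @param transforms named list: behavior column -> integer map. For
#'   5-level behaviors the map has 5 entries indexed by current level; for
#'   the binary behaviors (`smoke`, `secsmoke`) it has 2 entries indexed by
#'   current value + 1.
#' @return list of class `qihb_scenario`.
#' @export
scenario <- function(name, transforms) {
  sizes <- c(activity_level = 4, smoke = 2, secsmoke = 2, alcohol = 5,
             veg = 5, fruit = 5)
  if (is.null(names(transforms)) ||
      !all(names(transforms) %in% names(sizes))) {
    abort_qihb(paste("unknown behavior in scenario; allowed:",
                     paste(names(sizes), collapse = ", ")),
               "qihb_scenario_error")
  }
  for (b in names(transforms)) {
    mp <- transforms[[b]]
    k <- sizes[[b]]
    lo <- if (b %in% c("smoke", "secsmoke")) 0 else 1
    if (length(mp) != k || any(mp < lo) || any(mp > lo + k - 1)) {
      abort_qihb(sprintf("transform for '%s' must map its %d levels to valid levels",
                         b, k), "qihb_scenario_error")
    }
  }
  structure(list(name = name, transforms = transforms),
            class = "qihb_scenario")
}

#' Packaged scenarios
#'
#' The three policy scenarios: every individual with known activity level
#' moves up one activity level; all smoking and second-hand-smoke exposure
#' is eliminated; everyone moves up one fruit and one vegetable consumption
#' level. Individuals already at the most desirable level stay put.
#'
#' @return a `qihb_scenario`.
#' @export
scenario_increase_activity <- function() {
  scenario("Increase Physical Activity",
           list(activity_level = c(2L, 3L, 4L, 4L)))
}

#' @rdname scenario_increase_activity
#' @export
scenario_eliminate_smoking <- function() {
  scenario("Eliminate Smoking & Secondhand Smoking",
           list(smoke = c(0L, 0L), secsmoke = c(0L, 0L)))
}

#' @rdname scenario_increase_activity
#' @export
scenario_increase_fruit_veg <- function() {
  scenario("Increase Fruit & Vegetable Consumption",
           list(fruit = c(2L, 3L, 4L, 5L, 5L),
                veg = c(2L, 3L, 4L, 5L, 5L)))
}

#' @rdname scenario_increase_activity
#' @export
scenario_identity <- function() {
  scenario("Identity", list(activity_level = 1:4))
}

#' Default scenario list
#'
#' @return named list of the three packaged scenarios.
#' @export
default_scenarios <- function() {
  sc <- list(scenario_increase_activity(), scenario_eliminate_smoking(),
             scenario_increase_fruit_veg())
  stats::setNames(sc, vapply(sc, `[[`, character(1), "name"))
}

#' Read scenario definitions from YAML
#'
#' Each document entry: `name` plus `transforms` (behavior -> level map).
#'
#' @param path YAML file.
#' @return named list of `qihb_scenario`.
#' @export
read_scenarios <- function(path) {
  raw <- yaml::read_yaml(path)
  sc <- lapply(raw, function(s) {
    scenario(s$name, lapply(s$transforms, as.integer))
  })
  stats::setNames(sc, vapply(sc, `[[`, character(1), "name"))
}

#' Apply a scenario to a survey
#'
#' @param survey a `qihb_survey`.
#' @param scn a [scenario()].
#' @return the counterfactual survey; all non-behavior covariates (and any
#'   outcome columns) are unchanged.
#' @export
apply_scenario <- function(survey, scn) {
  if (!inherits(scn, "qihb_scenario")) {
    abort_qihb("`scn` must be a qihb_scenario", "qihb_scenario_error")
  }
  for (b in names(scn$transforms)) {
    mp <- scn$transforms[[b]]
    x <- survey[[b]]
    off <- if (b %in% c("smoke", "secsmoke")) 1L else 0L
    known <- !is.na(x)
    x[known] <- mp[x[known] + off]
    survey[[b]] <- x
  }
  survey
}

#' Expected DALYs for one individual
#'
#' Disease probability times DALY-per-prevalent-case.
#'
#' @param theta disease probability in `[0, 1]`.
#' @param dpp DALY per prevalent case (> 0), years.
#' @return expected DALYs, years.
#' @export
expected_daly <- function(theta, dpp) {
  if (any(theta < 0) || any(theta > 1)) {
    abort_qihb("`theta` must lie in [0, 1]", "qihb_invalid_input")
  }
  if (any(dpp <= 0)) abort_qihb("`dpp` must be positive",
                                "qihb_invalid_input")
  theta * dpp
}

#' Percent change versus a base total
#'
#' `100 * (scenario_total - base_total) / base_total`; serves both DALY and
#' prevalence totals.
#'
#' @param scenario_total,base_total population totals; `base_total > 0`.
#' @return percent change.
#' @export
percent_change <- function(scenario_total, base_total) {
  if (any(base_total <= 0)) {
    abort_qihb("undefined percent change: base total must be positive",
               "qihb_undefined_change")
  }
  100 * (scenario_total - base_total) / base_total
}

#' Simulate a behavior-change scenario
#'
#' For each posterior draw (consumed in stored order, up to `n_draws`):
#' recompute every record's disease probability under the base case and the
#' counterfactual covariates, convert to expected DALYs through the
#' DPP table, total over the population and take percent changes. The
#' per-draw percent changes are summarized by their mean and 5th/95th
#' percentiles (90% uncertainty interval). For Diabetes the fruit
#' consumption coefficients are zeroed before prediction by default
#' (`mask_fruit_diabetes`), a scenario-evaluation rule only — fitting and
#' evaluation are unaffected.
#'
#' @param survey_base base-case survey.
#' @param scn a [scenario()].
#' @param fits named list of `qihb_posterior` per disease.
#' @param dpp a `qihb_dpp_table`.
#' @param n_draws posterior draws to use (default 1000; all available with
#'   a message if fewer).
#' @param mask_fruit_diabetes zero the Diabetes fruit coefficients
#'   (default `TRUE`).
#' @param seed unused: draws are consumed in stored order, which makes the
#'   computation reproducible without reseeding; retained for signature
#'   stability.
#' @return data frame of class `qihb_scenario_result`: one row per disease
#'   and measure (`DALY`, `prevalence`) with `mean`, `p5`, `p95` percent
#'   change; per-draw trajectories in `attr(, "draws")`.
#' @export
simulate_scenario <- function(survey_base, scn, fits, dpp, n_draws = 1000,
                              mask_fruit_diabetes = TRUE, seed = NULL) {
  if (is.null(names(fits)) || !all(names(fits) %in% DISEASES)) {
    abort_qihb("`fits` must be a list named by disease",
               "qihb_invalid_input")
  }
  survey_scn <- apply_scenario(survey_base, scn)
  rows <- list()
  traj <- list()
  for (d in names(fits)) {
    fit <- fits[[d]]
    spec <- fit$spec
    mask <- NULL
    if (d == "Diabetes" && mask_fruit_diabetes) {
      mask <- spec$coefs$ref[spec$coefs$block == "fruit"]
    }
    th0 <- posterior_theta(fit, survey_base, spec, n_draws, mask)
    th1 <- posterior_theta(fit, survey_scn, spec, n_draws, mask)
    w <- dpp_for_records(dpp, d, survey_base)
    pct_daly <- percent_change(colSums(th1 * w), colSums(th0 * w))
    pct_prev <- percent_change(colSums(th1), colSums(th0))
    for (meas in c("DALY", "prevalence")) {
      v <- if (meas == "DALY") pct_daly else pct_prev
      rows[[length(rows) + 1]] <- data.frame(
        scenario = scn$name, disease = d, measure = meas,
        mean = mean(v), p5 = unname(stats::quantile(v, 0.05)),
        p95 = unname(stats::quantile(v, 0.95)), stringsAsFactors = FALSE)
      traj[[paste(d, meas)]] <- v
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("qihb_scenario_result", "data.frame"),
            draws = traj)
}

#' Render scenario results as a markdown table
#'
#' Mean percent reduction with the 90% interval in parentheses (a positive
#' reduction is a negative percent change).
#'
#' @param results one or more `qihb_scenario_result`s (rbind-ed).
#' @return character vector of markdown lines.
#' @export
format_scenario_results <- function(results) {
  fmt <- function(m, lo, hi) sprintf("%.1f (%.1f %.1f)", -m, -hi, -lo)
  lines <- c("| Scenario | Disease | Measure | % reduction (90% UI) |",
             "|---|---|---|---|")
  for (i in seq_len(nrow(results))) {
    r <- results[i, ]
    lines <- c(lines, sprintf("| %s | %s | %s | %s |", r$scenario,
                              r$disease, r$measure,
                              fmt(r$mean, r$p5, r$p95)))
  }
  lines
}
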