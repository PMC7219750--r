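test_that("scenario transforms move levels one step and respect the ceiling", {
  s <- generate_survey(200, generator_config(activity_missing = 0.15),
                       seed = 41)
  up <- apply_scenario(s, scenario_increase_activity())
  known <- !is.na(s$activity_level)
  expect_true(all(up$activity_level[known] ==
                    pmin(s$activity_level[known] + 1L, 4L)))
  expect_identical(is.na(up$activity_level), is.na(s$activity_level))
  expect_identical(up$smoke, s$smoke)

  elim <- apply_scenario(s, scenario_eliminate_smoking())
  expect_true(all(elim$smoke == 0) && all(elim$secsmoke == 0))

  fv <- apply_scenario(s, scenario_increase_fruit_veg())
  expect_true(all(fv$fruit == pmin(s$fruit + 1L, 5L)))
  expect_true(all(fv$veg == pmin(s$veg + 1L, 5L)))

  expect_error(scenario("bad", list(coffee = 1:3)),
               class = "qihb_scenario_error")
  expect_error(scenario("bad", list(fruit = c(2, 3, 4, 5, 9))),
               class = "qihb_scenario_error")
})

test_that("expected DALYs and percent change follow their defining formulas", {
  expect_equal(expected_daly(0, 0.5), 0)
  expect_equal(expected_daly(0.1, 0.5), 0.05)
  expect_equal(expected_daly(1, 0.83), 0.83)
  expect_error(expected_daly(1.2, 0.5), class = "qihb_invalid_input")
  expect_error(expected_daly(0.5, 0), class = "qihb_invalid_input")
  expect_equal(percent_change(90, 100), -10)
  expect_equal(percent_change(100, 100), 0)
  expect_error(percent_change(5, 0), class = "qihb_undefined_change")
})

test_that("a five-record worked fixture matches a hand summation", {
  theta_base <- c(0.10, 0.20, 0.05, 0.40, 0.25)
  theta_scn <- c(0.08, 0.15, 0.05, 0.30, 0.20)
  dpp <- c(0.83, 0.24, 0.38, 0.60, 0.72)
  base_total <- sum(expected_daly(theta_base, dpp))
  scn_total <- sum(expected_daly(theta_scn, dpp))
  hand_base <- 0.10 * 0.83 + 0.20 * 0.24 + 0.05 * 0.38 + 0.40 * 0.60 +
    0.25 * 0.72
  hand_scn <- 0.08 * 0.83 + 0.15 * 0.24 + 0.05 * 0.38 + 0.30 * 0.60 +
    0.20 * 0.72
  expect_equal(base_total, hand_base)
  expect_equal(percent_change(scn_total, base_total),
               100 * (hand_scn - hand_base) / hand_base)
})

test_that("the simulator matches the naive per-record reference to 1e-12", {
  s <- fx_survey_small()[1:40, ]
  dpp <- dpp_table_synthetic()
  fits <- list(IHD = fx_fit_small("IHD"),
               Diabetes = fx_fit_small("Diabetes"))
  fits <- lapply(fits, function(f) {
    f$draws <- f$draws[1:8, , drop = FALSE]
    f$chain <- f$chain[1:8]
    f
  })
  scn <- scenario_increase_fruit_veg()
  got <- simulate_scenario(s, scn, fits, dpp, n_draws = 8)
  ref <- naive_simulate(s, scn, fits, dpp, n_draws = 8)
  for (d in names(fits)) {
    gd <- attr(got, "draws")
    expect_equal(gd[[paste(d, "DALY")]], ref[[d]]$daly, tolerance = 1e-12)
    expect_equal(gd[[paste(d, "prevalence")]], ref[[d]]$prev,
                 tolerance = 1e-12)
    row <- got[got$disease == d & got$measure == "DALY", ]
    expect_equal(row$mean, mean(ref[[d]]$daly), tolerance = 1e-12)
  }
})

test_that("identity scenarios change nothing and single draws collapse the interval", {
  s <- fx_survey_small()[1:100, ]
  dpp <- dpp_table_synthetic()
  fit <- fx_fit_small("IHD")
  res <- simulate_scenario(s, scenario_identity(), list(IHD = fit), dpp,
                           n_draws = 50)
  expect_true(all(res$mean == 0 & res$p5 == 0 & res$p95 == 0))
  single <- fit
  single$draws <- fit$draws[1, , drop = FALSE]
  r1 <- simulate_scenario(s, scenario_increase_activity(),
                          list(IHD = single), dpp, n_draws = 1)
  expect_equal(r1$mean, r1$p5)
  expect_equal(r1$mean, r1$p95)
})

test_that("scaling every DPP cell cancels out of the percent change", {
  s <- fx_survey_small()[1:150, ]
  dpp <- dpp_table_synthetic()
  dpp_scaled <- dpp
  dpp_scaled$dpp <- dpp$dpp * 7.3
  fits <- list(IHD = fx_fit_small("IHD"))
  scn <- scenario_eliminate_smoking()
  a <- simulate_scenario(s, scn, fits, dpp, n_draws = 100)
  b <- simulate_scenario(s, scn, fits, as_dpp_table(dpp_scaled),
                         n_draws = 100)
  expect_equal(a$mean, b$mean, tolerance = 1e-12)
  expect_equal(a$p5, b$p5, tolerance = 1e-12)
})

test_that("with constant DPP the prevalence and DALY changes coincide", {
  s <- fx_survey_small()[1:150, ]
  const <- expand.grid(disease = c("IHD", "Diabetes"), age_bucket = 1:7,
                       gender = c("M", "F"), stringsAsFactors = FALSE)
  const$dpp <- 0.5
  res <- simulate_scenario(s, scenario_increase_activity(),
                           list(IHD = fx_fit_small("IHD")),
                           as_dpp_table(const), n_draws = 60)
  expect_equal(res$mean[res$measure == "DALY"],
               res$mean[res$measure == "prevalence"], tolerance = 1e-12)
})

test_that("a two-point posterior reports the average of its per-draw changes", {
  s <- fx_survey_small()[1:60, ]
  dpp <- dpp_table_synthetic()
  fit <- fx_fit_small("Diabetes")
  two <- fit
  two$draws <- fit$draws[c(10, 900), , drop = FALSE]
  res <- simulate_scenario(s, scenario_eliminate_smoking(),
                           list(Diabetes = two), dpp, n_draws = 2)
  tr <- attr(res, "draws")[["Diabetes DALY"]]
  expect_length(tr, 2)
  expect_equal(res$mean[res$measure == "DALY"], mean(tr))
})

test_that("the Diabetes fruit mask switches the fruit effect off for scenarios only", {
  spec <- fx_spec("Diabetes")
  est <- setNames(rep(0, spec$p), spec$coefs$ref)
  est[c("fruit[2]", "fruit[3]", "fruit[4]", "fruit[5]")] <-
    c(-0.1, -0.2, -0.3, -0.4)
  fit <- fake_posterior(rbind(est, est), spec)
  s <- fx_survey_small()[1:100, ]
  fruit_only <- scenario("fruit up", list(fruit = c(2L, 3L, 4L, 5L, 5L)))
  dpp <- dpp_table_synthetic()
  masked <- simulate_scenario(s, fruit_only, list(Diabetes = fit), dpp,
                              n_draws = 2)
  unmasked <- simulate_scenario(s, fruit_only, list(Diabetes = fit), dpp,
                                n_draws = 2, mask_fruit_diabetes = FALSE)
  expect_true(all(masked$mean == 0))
  expect_true(all(unmasked$mean < 0))
})

test_that("missing DPP cells are reported as a table-completeness error", {
  s <- fx_survey_small()[1:50, ]
  dpp <- dpp_table_synthetic()
  expect_error(as_dpp_table(dpp[-1, ]), class = "qihb_data_error")
  holes <- dpp[dpp$disease != "IHD", ]
  expect_error(
    simulate_scenario(s, scenario_identity(),
                      list(IHD = fx_fit_small("IHD")),
                      structure(holes, class = class(dpp)), n_draws = 2),
    class = "qihb_data_error")
})

test_that("scenario YAML definitions load into working scenarios", {
  sc <- read_scenarios(qihb_example("scenarios.yaml"))
  expect_length(sc, 3)
  expect_true("Increase Physical Activity" %in% names(sc))
  expect_identical(sc[["Increase Physical Activity"]]$transforms,
                   scenario_increase_activity()$transforms)
})
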