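slice_df <- function(rr_means, factor = "smoke", disease = "IHD") {
  as_rr_table(data.frame(factor = factor, level = "ALL",
                         age_bucket = as.character(seq_along(rr_means)),
                         gender = "ALL", disease = disease,
                         rr_mean = rr_means, rr_low = rr_means * 0.9,
                         rr_high = rr_means * 1.1,
                         stringsAsFactors = FALSE))
}

test_that("sign extraction follows the all-above-1 / all-below-1 rule", {
  expect_equal(extract_sign_pattern(slice_df(c(3.4, 2.0, 1.2)))$direction,
               "positive")
  expect_equal(extract_sign_pattern(
    slice_df(c(0.86, 0.74, 0.62), factor = "phys"))$direction, "negative")
  expect_null(extract_sign_pattern(slice_df(c(0.9, 1.1))))
  empty <- slice_df(c(1.2, 1.3))[0, ]
  expect_error(extract_sign_pattern(empty), class = "qihb_invalid_input")
})

test_that("shape extraction requires a monotone trend with a strict step", {
  dec <- slice_df(c(3.5, 3.0, 2.2, 1.6, 1.3, 1.2, 1.15))
  p <- extract_shape_pattern(dec, "age", gender = "F")
  expect_equal(p$direction, "decrease")
  expect_equal(p$gender, "F")
  expect_null(extract_shape_pattern(slice_df(c(2, 2, 2)), "age"))
  expect_null(extract_shape_pattern(slice_df(c(1, 2, 1)), "age"))
  expect_equal(extract_shape_pattern(slice_df(c(1, 1, 2)), "age")$direction,
               "increase")
  expect_error(extract_shape_pattern(slice_df(1.5), "age"),
               class = "qihb_invalid_input")
})

test_that("patterns extracted from the packaged RR table reproduce the canonical set", {
  rr <- rr_table_synthetic()
  canon <- function(pl) {
    df <- do.call(rbind, lapply(pl, function(p) {
      as.data.frame(unclass(p), stringsAsFactors = FALSE)
    }))
    df <- df[do.call(order, df), ]
    rownames(df) <- NULL
    df
  }
  for (d in c("IHD", "Diabetes")) {
    expect_equal(canon(extract_patterns(rr, d)),
                 canon(default_patterns(d)))
  }
})

test_that("IHD constraint compilation enumerates the full inequality set", {
  cons <- fx_cons("IHD")
  expect_equal(nrow(cons), 105)
  expect_equal(sum(cons$type == "sign"), 43)
  expect_equal(sum(cons$type == "order"), 62)
  # block-level tallies: signs 21 phys + 14 smoke + 1 secsmoke + 7 bmi;
  # orders 12 demog + 14 phys-level + 18 phys-age + 12 smoke-age + 6 bmi-age
  expect_equal(sum(cons$type == "sign" & grepl("^phys", cons$ref_a)), 21)
  expect_equal(sum(cons$type == "sign" & grepl("^smoke", cons$ref_a)), 14)
  expect_equal(sum(cons$type == "order" & grepl("^demog", cons$ref_a)), 12)
  expect_equal(sum(cons$type == "order" & grepl("^phys", cons$ref_a)), 32)
  expect_equal(sum(cons$type == "order" & grepl("^smoke", cons$ref_a)), 12)
  expect_equal(sum(cons$type == "order" & grepl("^bmi", cons$ref_a)), 6)
})

test_that("Diabetes compilation has no age-varying rows and the expected signs", {
  cons <- fx_cons("Diabetes")
  expect_equal(nrow(cons), 33)
  expect_true(all(c("phys[2]", "phys[3]", "phys[4]") %in%
                    cons$ref_a[cons$op == "le0"]))
  expect_true(all(c("smoke[M]", "smoke[F]") %in%
                    cons$ref_a[cons$op == "ge0"]))
  expect_false(any(grepl("^smoke", cons$ref_a) & cons$type == "order"))
})

test_that("compilation is idempotent, order-independent, and feasible at zero", {
  spec <- fx_spec("IHD")
  pats <- default_patterns("IHD")
  a <- compile_constraints(pats, spec)
  set.seed(1)
  b <- compile_constraints(sample(pats), spec)
  expect_identical(as.data.frame(a), as.data.frame(b))
  zero <- setNames(rep(0, spec$p), spec$coefs$ref)
  expect_true(check_constraints(zero, a))
  expect_equal(nrow(compile_constraints(list(), spec)), 0)
})

test_that("the smoking-age direction override flips only that shape", {
  spec <- fx_spec("IHD")
  pats <- default_patterns("IHD")
  flipped <- compile_constraints(pats, spec,
                                 constraint_direction_override = TRUE)
  base <- fx_cons("IHD")
  smoke_ord <- function(cs) cs[cs$type == "order" &
                                 grepl("^smoke", cs$ref_a), "op"]
  expect_true(all(smoke_ord(base) == "a_le_b"))
  expect_true(all(smoke_ord(flipped) == "a_ge_b"))
  other <- function(cs) cs[!(cs$type == "order" &
                               grepl("^smoke", cs$ref_a)), ]
  expect_identical(as.data.frame(other(base)),
                   as.data.frame(other(flipped)))
})

test_that("patterns naming unknown factors or absent dimensions are rejected", {
  spec <- fx_spec("Diabetes")
  expect_error(compile_constraints(
    list(qualitative_pattern("Diabetes", "yoga", "sign", "negative")),
    spec), class = "qihb_spec_mismatch")
  expect_error(compile_constraints(
    list(qualitative_pattern("Diabetes", "smoke", "shape", "decrease",
                             dimension = "age", gender = "M")),
    spec), class = "qihb_spec_mismatch")
})

test_that("constraint checking resolves references and flags violations", {
  cons <- fx_cons("IHD")
  spec <- fx_spec("IHD")
  theta <- setNames(rep(0, spec$p), spec$coefs$ref)
  theta["smoke[2,M]"] <- -0.1
  expect_false(check_constraints(theta, cons))
  expect_error(check_constraints(theta[-1], cons),
               class = "qihb_spec_mismatch")
})

test_that("RR tables validate their interval ordering and patterns survive YAML", {
  expect_error(as_rr_table(data.frame(
    factor = "smoke", level = "ALL", age_bucket = "ALL", gender = "ALL",
    disease = "IHD", rr_mean = 1.2, rr_low = 1.5, rr_high = 2)),
    class = "qihb_data_error")
  pats <- default_patterns("IHD")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_patterns(pats, path)
  back <- read_patterns(path)
  expect_equal(lapply(back, unclass), lapply(pats, unclass))
})
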