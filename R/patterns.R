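# Qualitative pattern extraction from relative-risk tables and compilation
# into linear inequality constraints on named model coefficients.

#' Read a relative-risk table
#'
#' CSV with columns `factor, level, age_bucket, gender, disease, rr_mean,
#' rr_low, rr_high`; `level`, `age_bucket` and `gender` admit the wildcard
#' `"ALL"`. Validates `0 < rr_low <= rr_mean <= rr_high`.
#'
#' @param path file path.
#' @return data frame of class `qihb_rr_table`.
#' @export
read_rr_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(level = "character",
                                       age_bucket = "character",
                                       gender = "character"))
  as_rr_table(df)
}

#' @param data data frame with the RR-table columns.
#' @rdname read_rr_table
#' @export
as_rr_table <- function(data) {
  need <- c("factor", "level", "age_bucket", "gender", "disease",
            "rr_mean", "rr_low", "rr_high")
  if (!all(need %in% names(data))) {
    abort_qihb("RR table must have columns factor, level, age_bucket, gender, disease, rr_mean, rr_low, rr_high",
               "qihb_data_error")
  }
  for (col in c("level", "age_bucket", "gender")) {
    data[[col]] <- as.character(data[[col]])
  }
  with(data, {
    if (any(rr_low <= 0) || any(rr_low > rr_mean) || any(rr_mean > rr_high)) {
      abort_qihb("RR table requires 0 < rr_low <= rr_mean <= rr_high",
                 "qihb_data_error")
    }
  })
  structure(data, class = c("qihb_rr_table", "data.frame"))
}

#' Qualitative pattern
#'
#' A sign expectation (effect direction versus the reference level) or a
#' shape expectation (monotone trend across exposure levels or age buckets)
#' on one risk factor's coefficients for one disease.
#'
#' @param disease `"IHD"` or `"Diabetes"`.
#' @param factor coefficient block name (`"phys"`, `"smoke"`, `"secsmoke"`,
#'   `"bmi"`, `"demog"`).
#' @param kind `"sign"` or `"shape"`.
#' @param direction `"positive"`/`"negative"` for sign patterns,
#'   `"increase"`/`"decrease"` for shape patterns.
#' @param dimension for shape patterns, `"level"` or `"age"`.
#' @param gender scope: `"M"`, `"F"` or `"ALL"`.
#' @return list of class `qihb_pattern`.
#' @export
qualitative_pattern <- function(disease, factor, kind, direction,
                                dimension = NA_character_, gender = "ALL") {
  kind <- match.arg(kind, c("sign", "shape"))
  if (kind == "sign" && !direction %in% c("positive", "negative")) {
    abort_qihb("sign patterns carry direction positive/negative",
               "qihb_invalid_input")
  }
  if (kind == "shape") {
    if (!direction %in% c("increase", "decrease")) {
      abort_qihb("shape patterns carry direction increase/decrease",
                 "qihb_invalid_input")
    }
    if (!dimension %in% c("level", "age")) {
      abort_qihb("shape patterns need dimension 'level' or 'age'",
                 "qihb_invalid_input")
    }
  }
  structure(list(disease = disease, factor = factor, kind = kind,
                 direction = direction, dimension = dimension,
                 gender = gender),
            class = "qihb_pattern")
}

#' @export
print.qihb_pattern <- function(x, ...) {
  cat(sprintf("<pattern> %s %s: %s %s%s%s\n", x$disease, x$factor, x$kind,
              x$direction,
              if (!is.na(x$dimension)) paste0(" over ", x$dimension) else "",
              if (x$gender != "ALL") paste0(" [", x$gender, "]") else ""))
  invisible(x)
}

#' Extract a sign pattern from an RR-table slice
#'
#' All mean relative risks above 1 imply a positive effect versus the
#' reference level; all below 1 a negative effect; mixed means give no
#' pattern.
#'
#' @param slice non-empty RR-table rows for a single factor and disease.
#' @return a `qihb_pattern` or `NULL` (mixed signs).
#' @export
extract_sign_pattern <- function(slice) {
  if (is.null(slice) || nrow(slice) == 0) {
    abort_qihb("empty RR slice", "qihb_invalid_input")
  }
  if (length(unique(slice$factor)) != 1 ||
      length(unique(slice$disease)) != 1) {
    abort_qihb("sign extraction needs a single factor and disease",
               "qihb_invalid_input")
  }
  if (all(slice$rr_mean > 1)) {
    qualitative_pattern(slice$disease[1], slice$factor[1], "sign", "positive")
  } else if (all(slice$rr_mean < 1)) {
    qualitative_pattern(slice$disease[1], slice$factor[1], "sign", "negative")
  } else {
    NULL
  }
}

#' Extract a shape pattern from an ordered RR-table slice
#'
#' The slice must already be ordered along the shape dimension (exposure
#' level or age bucket). A non-decreasing mean RR sequence with at least one
#' strict increase gives `"increase"`; the mirror gives `"decrease"`;
#' anything else (constant or non-monotone) gives no pattern.
#'
#' @param slice RR-table rows, ordered, with >= 2 entries.
#' @param dimension `"level"` or `"age"`.
#' @param gender gender scope recorded on the emitted pattern.
#' @return a `qihb_pattern` or `NULL`.
#' @export
extract_shape_pattern <- function(slice, dimension = "level",
                                  gender = "ALL") {
  if (is.null(slice) || nrow(slice) < 2) {
    abort_qihb("shape extraction needs >= 2 ordered entries",
               "qihb_invalid_input")
  }
  d <- diff(slice$rr_mean)
  dir <- if (all(d >= 0) && any(d > 0)) "increase"
         else if (all(d <= 0) && any(d < 0)) "decrease"
         else return(NULL)
  qualitative_pattern(slice$disease[1], slice$factor[1], "shape", dir,
                      dimension = dimension, gender = gender)
}

#' Extract all qualitative patterns for a disease
#'
#' Applies [extract_sign_pattern()] per factor and [extract_shape_pattern()]
#' over exposure levels (per age/gender slice; a pattern is emitted only
#' when every slice agrees) and over age buckets (separately per gender
#' present in the table; emitted only when every level's age profile
#' agrees).
#'
#' @param rr a `qihb_rr_table`.
#' @param disease disease to extract for.
#' @return list of `qihb_pattern`.
#' @export
extract_patterns <- function(rr, disease) {
  rr <- rr[rr$disease == disease, , drop = FALSE]
  out <- list()
  for (fac in unique(rr$factor)) {
    sl <- rr[rr$factor == fac, , drop = FALSE]
    p <- extract_sign_pattern(sl)
    if (!is.null(p)) out[[length(out) + 1]] <- p

    # shape over exposure level
    lev <- suppressWarnings(as.numeric(sl$level))
    if (sum(!is.na(unique(lev))) >= 2) {
      dirs <- character(0)
      ok <- TRUE
      for (a in unique(sl$age_bucket)) for (g in unique(sl$gender)) {
        sub <- sl[sl$age_bucket == a & sl$gender == g &
                    !is.na(suppressWarnings(as.numeric(sl$level))), ,
                  drop = FALSE]
        if (nrow(sub) < 2) next
        sub <- sub[order(as.numeric(sub$level)), , drop = FALSE]
        p <- extract_shape_pattern(sub, "level")
        if (is.null(p)) { ok <- FALSE; break }
        dirs <- c(dirs, p$direction)
      }
      if (ok && length(dirs) && length(unique(dirs)) == 1) {
        out[[length(out) + 1]] <-
          qualitative_pattern(disease, fac, "shape", dirs[1],
                              dimension = "level")
      }
    }

    # shape over age, per gender scope
    for (g in unique(sl$gender)) {
      slg <- sl[sl$gender == g, , drop = FALSE]
      ages <- suppressWarnings(as.numeric(slg$age_bucket))
      if (sum(!is.na(unique(ages))) < 2) next
      dirs <- character(0)
      ok <- TRUE
      for (lv in unique(slg$level)) {
        sub <- slg[slg$level == lv &
                     !is.na(suppressWarnings(as.numeric(slg$age_bucket))), ,
                   drop = FALSE]
        if (nrow(sub) < 2) next
        sub <- sub[order(as.numeric(sub$age_bucket)), , drop = FALSE]
        p <- extract_shape_pattern(sub, "age", gender = g)
        if (is.null(p)) { ok <- FALSE; break }
        dirs <- c(dirs, p$direction)
      }
      if (ok && length(dirs) && length(unique(dirs)) == 1) {
        out[[length(out) + 1]] <-
          qualitative_pattern(disease, fac, "shape", dirs[1],
                              dimension = "age", gender = g)
      }
    }
  }
  out
}

#' Canonical pattern set
#'
#' The full qualitative pattern list for a disease as used by the
#' qualitative-informative prior: negative physical-activity and positive
#' smoking, second-hand-smoke and BMI signs; risk increasing with age for
#' both genders; effects decreasing with activity level; and (for IHD only)
#' physical-activity, smoking (per gender) and BMI effects decreasing with
#' age.
#'
#' @param disease `"IHD"` or `"Diabetes"`.
#' @return list of `qihb_pattern`.
#' @export
default_patterns <- function(disease = c("IHD", "Diabetes")) {
  disease <- match.arg(disease)
  qp <- function(...) qualitative_pattern(disease, ...)
  out <- list(
    qp("phys", "sign", "negative"),
    qp("smoke", "sign", "positive"),
    qp("secsmoke", "sign", "positive"),
    qp("bmi", "sign", "positive"),
    qp("demog", "shape", "increase", dimension = "age", gender = "M"),
    qp("demog", "shape", "increase", dimension = "age", gender = "F"),
    qp("phys", "shape", "decrease", dimension = "level"),
    qp("bmi", "shape", "decrease", dimension = "age"))
  if (disease == "IHD") {
    out <- c(out, list(
      qp("phys", "shape", "decrease", dimension = "age"),
      qp("smoke", "shape", "decrease", dimension = "age", gender = "M"),
      qp("smoke", "shape", "decrease", dimension = "age", gender = "F")))
  }
  out
}

#' Compile patterns into inequality constraints
#'
#' Sign patterns constrain every free coefficient of the factor's block to
#' the stated half-line. Shape patterns over exposure levels chain
#' consecutive non-reference levels (the first non-reference level versus
#' the reference at 0 is covered by the sign constraint); shape patterns
#' over age chain consecutive age buckets within each secondary index
#' (gender or activity level). All inequalities are non-strict, so the
#' all-zero vector is always feasible.
#'
#' @param patterns list of [qualitative_pattern()].
#' @param spec a [model_spec()].
#' @param constraint_direction_override if `TRUE`, compile the smoking-age
#'   shape with the opposite direction (the displayed-inequality reading
#'   rather than the tabulated pattern).
#' @return data frame of class `qihb_constraints` with columns `type`
#'   (`sign`/`order`), `ref_a`, `ref_b`, `op` (`ge0`, `le0`, `a_ge_b`,
#'   `a_le_b`); attribute `spec`.
#' @export
compile_constraints <- function(patterns, spec,
                                constraint_direction_override = FALSE) {
  rows <- list()
  add <- function(type, ref_a, ref_b, op) {
    if (length(ref_a)) {
      rows[[length(rows) + 1]] <<- data.frame(
        type = type, ref_a = ref_a, ref_b = ref_b, op = op,
        stringsAsFactors = FALSE)
    }
  }
  coefs <- spec$coefs
  for (p in patterns) {
    if (!is.null(p$disease) && p$disease != spec$disease) {
      abort_qihb(sprintf("pattern for %s compiled against %s spec",
                         p$disease, spec$disease), "qihb_spec_mismatch")
    }
    blk <- coefs[coefs$block == p$factor, , drop = FALSE]
    if (nrow(blk) == 0) {
      abort_qihb(sprintf("pattern factor '%s' absent from model spec",
                         p$factor), "qihb_spec_mismatch")
    }
    if (p$kind == "sign") {
      op <- if (p$direction == "positive") "ge0" else "le0"
      add("sign", blk$ref, NA_character_, op)
    } else if (p$dimension == "level") {
      op <- if (p$direction == "increase") "a_ge_b" else "a_le_b"
      if (all(is.na(blk$age))) {
        b2 <- blk[order(blk$level), , drop = FALSE]
        k <- nrow(b2)
        if (k >= 2) add("order", b2$ref[-1], b2$ref[-k], op)
      } else {
        for (a in sort(unique(blk$age))) {
          b2 <- blk[blk$age == a, , drop = FALSE]
          b2 <- b2[order(b2$level), , drop = FALSE]
          k <- nrow(b2)
          if (k >= 2) add("order", b2$ref[-1], b2$ref[-k], op)
        }
      }
    } else {  # shape over age
      if (all(is.na(blk$age))) {
        abort_qihb(sprintf(
          "age-shape pattern on '%s' but the %s block has no age dimension",
          p$factor, spec$disease), "qihb_spec_mismatch")
      }
      dir <- p$direction
      if (constraint_direction_override && p$factor == "smoke") {
        dir <- if (dir == "decrease") "increase" else "decrease"
      }
      op <- if (dir == "increase") "a_ge_b" else "a_le_b"
      if (p$gender %in% c("M", "F")) {
        blk <- blk[!is.na(blk$gender) & blk$gender == p$gender, ,
                   drop = FALSE]
      }
      split_on <- if (all(is.na(blk$level))) blk$gender else blk$level
      split_on[is.na(split_on)] <- "."
      for (sec in unique(split_on)) {
        b2 <- blk[split_on == sec, , drop = FALSE]
        b2 <- b2[order(b2$age), , drop = FALSE]
        k <- nrow(b2)
        if (k >= 2) add("order", b2$ref[-1], b2$ref[-k], op)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(type = character(0), ref_a = character(0),
               ref_b = character(0), op = character(0),
               stringsAsFactors = FALSE)
  out <- unique(out)
  out <- out[order(out$type, out$ref_a, out$ref_b, out$op), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("qihb_constraints", "data.frame"), spec = spec)
}

# Per-coefficient sign implied by the sign constraints (+1 / -1 / NA).
constraint_signs <- function(constraints, refs) {
  sgn <- stats::setNames(rep(NA_real_, length(refs)), refs)
  sg <- constraints[constraints$type == "sign", , drop = FALSE]
  if (nrow(sg)) {
    sgn[sg$ref_a[sg$op == "ge0"]] <- 1
    sgn[sg$ref_a[sg$op == "le0"]] <- -1
  }
  sgn
}

# Numeric form: each row r encodes si*theta[i] + sj*theta[j] >= 0.
constraints_matrix <- function(constraints, spec) {
  refs <- spec$coefs$ref
  n <- nrow(constraints)
  if (n == 0) {
    return(list(idx = matrix(0L, 0, 2), sign = matrix(0, 0, 2)))
  }
  i <- match(constraints$ref_a, refs)
  j <- match(constraints$ref_b, refs)
  if (anyNA(i) || anyNA(j[constraints$type == "order"])) {
    abort_qihb("constraint references a coefficient absent from the spec",
               "qihb_spec_mismatch")
  }
  j[is.na(j)] <- 0L
  si <- ifelse(constraints$op %in% c("ge0", "a_ge_b"), 1, -1)
  sj <- ifelse(constraints$type == "order",
               ifelse(constraints$op == "a_ge_b", -1, 1), 0)
  list(idx = cbind(as.integer(i), as.integer(j)), sign = cbind(si, sj))
}

#' Check a parameter set against a constraint set
#'
#' @param params complete named coefficient vector (or `qihb_params`).
#' @param constraints a `qihb_constraints`.
#' @return `TRUE` iff every inequality holds (non-strict, zero tolerance).
#' @export
check_constraints <- function(params, constraints) {
  if (nrow(constraints) == 0) return(TRUE)
  vals_a <- params[constraints$ref_a]
  if (anyNA(names(vals_a)) || anyNA(vals_a)) {
    abort_qihb("parameter set does not resolve all constrained coefficients",
               "qihb_spec_mismatch")
  }
  ord <- constraints$type == "order"
  vals_b <- rep(0, nrow(constraints))
  if (any(ord)) {
    vb <- params[constraints$ref_b[ord]]
    if (anyNA(vb)) {
      abort_qihb("parameter set does not resolve all constrained coefficients",
                 "qihb_spec_mismatch")
    }
    vals_b[ord] <- vb
  }
  lhs <- ifelse(constraints$op %in% c("ge0", "a_ge_b"), 1, -1) * vals_a +
    ifelse(ord, ifelse(constraints$op == "a_ge_b", -1, 1), 0) * vals_b
  all(lhs >= 0)
}

#' Serialize patterns or constraints to YAML
#'
#' @param x list of patterns, or a `qihb_constraints`.
#' @param path output file.
#' @export
write_patterns <- function(x, path) {
  if (inherits(x, "qihb_constraints")) {
    yaml::write_yaml(list(disease = attr(x, "spec")$disease,
                          constraints = unname(split(as.data.frame(x),
                                                     seq_len(nrow(x))))),
                     path)
  } else {
    yaml::write_yaml(lapply(x, unclass), path)
  }
  invisible(path)
}

#' Read qualitative patterns from YAML
#'
#' @param path file written by [write_patterns()].
#' @return list of `qihb_pattern`.
#' @export
read_patterns <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(p) {
    qualitative_pattern(p$disease, p$factor, p$kind, p$direction,
                        p$dimension %||% NA_character_,
                        p$gender %||% "ALL")
  })
}
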