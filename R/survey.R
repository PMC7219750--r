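# Survey container and deterministic coding transforms.

SURVEY_FIELDS <- c("age_bucket", "gender", "activity_level", "smoke",
                   "secsmoke", "alcohol", "veg", "fruit", "education",
                   "income", "bmi_excess", "trust", "region", "method",
                   "year")
DISEASES <- c("IHD", "Diabetes")

AGE_LABELS <- c("15-24", "25-34", "35-44", "45-54", "55-64", "65-74", "75+")
ACTIVITY_LABELS <- c("Inactive", "Insufficiently Active", "Active",
                     "Highly Active")
CONSUMPTION_LABELS <- c("None", "<once a week", "1-3 times a week",
                        "4-6 times a week", "One or more per day")

#' BMI excess transform
#'
#' Converts body-mass index to the hinge-transformed excess used as the BMI
#' covariate: values at or below the reference contribute zero risk, values
#' above contribute linearly.
#'
#' @param bmi numeric vector of body-mass index values (kg/m^2), all positive.
#' @param reference hinge point in kg/m^2 (default 22.55).
#' @return `pmax(0, bmi - reference)`.
#' @examples
#' bmi_transform(c(20, 22.55, 30))
#' @export
bmi_transform <- function(bmi, reference = 22.55) {
  if (!is.numeric(bmi) || any(!is.finite(bmi)) || any(bmi <= 0)) {
    abort_qihb("`bmi` must be finite and positive", "qihb_invalid_input")
  }
  pmax(0, bmi - reference)
}

#' Weekly MET-minutes to activity level
#'
#' Buckets weekly metabolic-equivalent minutes into the four physical
#' activity levels: Inactive (<600), Insufficiently Active (600-3999),
#' Active (4000-7999) and Highly Active (>= 8000).
#'
#' @param weekly_mets numeric vector of non-negative weekly MET-minutes.
#' @return integer vector of levels 1..4.
#' @examples
#' mets_to_activity_level(c(599, 600, 8000))
#' @export
mets_to_activity_level <- function(weekly_mets) {
  if (!is.numeric(weekly_mets) || any(is.na(weekly_mets)) ||
      any(weekly_mets < 0)) {
    abort_qihb("`weekly_mets` must be non-negative", "qihb_invalid_input")
  }
  findInterval(weekly_mets, c(600, 4000, 8000)) + 1L
}

#' Construct a survey object
#'
#' Validates a data frame of respondent records (one row each) and tags it
#' with provenance. Columns must use the canonical field names; binary
#' disease outcome columns (`IHD`, `Diabetes`) are optional.
#'
#' @param data data frame with the survey fields.
#' @param provenance `"real"` or `"synthetic"`.
#' @param seed integer seed used to generate the data, if synthetic.
#' @return the validated data frame with class `qihb_survey`.
#' @export
as_survey <- function(data, provenance = "real", seed = NULL) {
  missing_cols <- setdiff(SURVEY_FIELDS, names(data))
  if (length(missing_cols)) {
    abort_qihb(paste("survey is missing columns:",
                     paste(missing_cols, collapse = ", ")),
               "qihb_data_error")
  }
  if (nrow(data) == 0) abort_qihb("survey has no records", "qihb_data_error")
  validate_survey_fields(data)
  structure(as.data.frame(data),
            class = c("qihb_survey", "data.frame"),
            provenance = provenance, seed = seed)
}

validate_survey_fields <- function(data) {
  in_range <- function(x, lo, hi, allow_na = FALSE) {
    x <- if (allow_na) x[!is.na(x)] else x
    !anyNA(x) && all(x >= lo & x <= hi)
  }
  ok <- in_range(data$age_bucket, 1, 7) &&
    all(data$gender %in% c("M", "F")) &&
    in_range(data$activity_level, 1, 4, allow_na = TRUE) &&
    in_range(data$smoke, 0, 1) && in_range(data$secsmoke, 0, 1) &&
    in_range(data$alcohol, 1, 5) &&
    in_range(data$veg, 1, 5) && in_range(data$fruit, 1, 5) &&
    in_range(data$education, 0, Inf) &&
    all(is.finite(data$income)) &&
    in_range(data$bmi_excess, 0, Inf) &&
    in_range(data$trust, 1, 4) && in_range(data$region, 1, 12) &&
    in_range(data$method, 0, 1)
  for (d in intersect(DISEASES, names(data))) {
    ok <- ok && all(data[[d]] %in% c(0L, 1L))
  }
  if (!ok) abort_qihb("survey fields violate coding invariants",
                      "qihb_data_error")
  invisible(TRUE)
}

#' @export
print.qihb_survey <- function(x, ...) {
  cat(sprintf("<qihb_survey> %d records (%s)\n", nrow(x),
              attr(x, "provenance") %||% "unknown"))
  cat("outcomes:", paste(intersect(DISEASES, names(x)), collapse = ", "),
      "\n")
  print(utils::head(as.data.frame(x), 4))
  invisible(x)
}

#' Read / write a survey CSV
#'
#' Headered CSV with one row per respondent, columns named exactly as the
#' survey fields; missing values are empty cells.
#'
#' @param path file path.
#' @param provenance provenance label attached on read.
#' @return `read_survey()` returns a `qihb_survey`.
#' @export
read_survey <- function(path, provenance = "real") {
  df <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE)
  as_survey(df, provenance = provenance)
}

#' @param survey a `qihb_survey`.
#' @rdname read_survey
#' @export
write_survey <- function(survey, path) {
  cols <- c(SURVEY_FIELDS, intersect(DISEASES, names(survey)))
  utils::write.csv(as.data.frame(survey)[cols], path, row.names = FALSE,
                   na = "")
  invisible(path)
}
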