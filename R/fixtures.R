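# Packaged example inputs. Both tables are synthetic stand-ins built to
# embody the qualitative structure of the global meta-analysis inputs (the
# real extractions are not redistributable); filenames say so.

#' Path to a packaged example file
#'
#' @param file file name under the package's `extdata` (empty to list).
#' @return full path.
#' @export
qihb_example <- function(file = "") {
  if (file == "") {
    return(dir(system.file("extdata", package = "qihb")))
  }
  path <- system.file("extdata", file, package = "qihb")
  if (path == "") abort_qihb(paste("no packaged file", file),
                             "qihb_config_error")
  path
}

#' Packaged synthetic relative-risk table
#'
#' A synthetic RR table whose mean relative risks embody the canonical
#' qualitative patterns (see [default_patterns()]): protective physical
#' activity declining with level and (for IHD) with age, harmful smoking
#' declining with age for both genders in IHD, harmful second-hand smoke
#' and BMI, and risk rising with age for both genders.
#'
#' @return a `qihb_rr_table`.
#' @export
rr_table_synthetic <- function() {
  read_rr_table(qihb_example("rr_table_synthetic.csv"))
}

#' Packaged synthetic DALY-per-prevalent-case table
#'
#' Synthetic DPP values spanning 0.24-0.83 years for IHD (male values
#' peaking in the 35-44 bucket) and 0.08-0.27 for Diabetes, generally
#' increasing with age.
#'
#' @return a `qihb_dpp_table`.
#' @export
dpp_table_synthetic <- function() {
  read_dpp_table(qihb_example("dpp_synthetic.csv"))
}

#' Generator configuration YAML I/O
#'
#' The YAML mirrors the behavior -> level -> probability layout plus copula
#' targets and demographic marginals; keys match the arguments of
#' [generator_config()].
#'
#' @param path YAML file.
#' @return a `qihb_generator_config`.
#' @export
read_generator_config <- function(path) {
  raw <- yaml::read_yaml(path)
  lvl <- function(x) if (is.list(x)) unlist(x, use.names = FALSE) else x
  args <- list()
  for (nm in c("activity", "veg", "fruit", "alcohol", "age", "trust",
               "region")) {
    if (!is.null(raw[[nm]])) args[[nm]] <- lvl(raw[[nm]])
  }
  for (nm in c("smoke", "secsmoke", "fruit_veg_cor", "smoke_secsmoke_cor",
               "female", "income_meanlog", "income_sdlog", "bmi_mean",
               "bmi_sd", "activity_missing", "latent_fruit_veg",
               "latent_smoke_secsmoke")) {
    if (!is.null(raw[[nm]])) args[[nm]] <- raw[[nm]]
  }
  for (nm in c("education_years", "years")) {
    if (!is.null(raw[[nm]])) args[[nm]] <- unlist(raw[[nm]])
  }
  do.call(generator_config, args)
}

#' @param config a [generator_config()].
#' @rdname read_generator_config
#' @export
write_generator_config <- function(config, path) {
  out <- unclass(config)
  out <- out[!vapply(out, is.null, logical(1))]
  out$education_years <- as.list(out$education_years)
  out$years <- as.list(out$years)
  yaml::write_yaml(out, path)
  invisible(path)
}
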