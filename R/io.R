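# Table schemas, validated CSV I/O, configuration and provenance.

table_schemas <- list(
  timeseries = list(
    columns = c(age_months = "numeric", n_total_mean = "numeric",
                n_total_sem = "numeric", frac_active_mean = "numeric",
                frac_active_sem = "numeric", frac_resting_mean = "numeric",
                frac_resting_sem = "numeric", n_mice = "integer"),
    validator = "observed_series"),
  tally = list(
    columns = c(mouse_id = "character", age_months = "numeric",
                chase_hours = "numeric", edu_pos_ki67_pos = "integer",
                edu_pos_ki67_neg = "integer", edu_neg_ki67_pos = "integer",
                edu_neg_ki67_neg = "integer", total_nsc = "integer"),
    validator = "pulse_chase_tally"),
  trajectory = list(
    columns = c(time_days = "numeric", d = "numeric", r = "numeric",
                a = "numeric", depleted_cum = "numeric", n_total = "numeric"),
    validator = NULL),
  ratios = list(
    columns = c(cell_id = "character", ratio = "numeric"),
    validator = NULL),
  intensities = list(
    columns = c(cell_id = "character", cohort = "character",
                integrated_density = "numeric", area = "numeric",
                background_mean = "numeric"),
    validator = NULL))

#' Read and validate a CSV table against a named schema
#'
#' @param path CSV file with header.
#' @param schema one of "timeseries", "tally", "trajectory", "ratios",
#'   "intensities".
#' @return validated data frame.
#' @export
read_table <- function(path, schema = names(table_schemas)) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  sc <- table_schemas[[schema]]
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(names(sc$columns), names(df))
  if (length(miss)) stop("missing column ", paste(miss, collapse = ", "))
  for (col in names(sc$columns)) {
    want <- sc$columns[[col]]
    x <- df[[col]]
    if (want %in% c("numeric", "integer") && !is.numeric(x))
      stop("column ", col, " must be numeric")
    if (want == "integer" && any(x != round(x), na.rm = TRUE)) {
      bad <- which(x != round(x))[1]
      stop("column ", col, " must hold integer counts (row ", bad, ")")
    }
  }
  if (!is.null(sc$validator)) df <- do.call(sc$validator, list(df))
  df
}

#' Write a table as CSV (UTF-8, header, '.' decimal)
#'
#' @param df data frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_table <- function(df, path) {
  write.csv(as.data.frame(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a structured run configuration (YAML)
#'
#' Sections `parameters`, `variant`, `protocol` are mapped onto the
#' package constructors; unknown keys are rejected.
#'
#' @param path YAML file.
#' @return list with `params`, `variant`, `protocol` and any remaining
#'   top-level scalar settings.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("parameters", "variant", "protocol", "solver", "seed", "ages_months",
             "n_animals", "noise_cv", "cells_per_mouse")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) stop("unknown config key: ", paste(unknown, collapse = ", "))
  out <- list()
  out$params <- if (!is.null(cfg$parameters)) do.call(model_parameters, cfg$parameters)
  out$variant <- if (!is.null(cfg$variant)) do.call(model_variant, cfg$variant)
                 else model_variant()
  out$protocol <- if (!is.null(cfg$protocol)) do.call(label_protocol, cfg$protocol)
                  else label_protocol()
  extra <- setdiff(known, c("parameters", "variant", "protocol", "solver"))
  out[intersect(extra, names(cfg))] <- cfg[intersect(extra, names(cfg))]
  out
}

#' Write a provenance record for a run
#'
#' Records the configuration, seed and package version next to the
#' outputs so every table can be regenerated.
#'
#' @param dir output directory.
#' @param config list of settings used.
#' @param seed integer seed used.
#' @return invisibly, the file path.
#' @export
write_provenance <- function(dir, config, seed) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "provenance.yaml")
  yaml::write_yaml(list(
    package = "nscdyn",
    version = as.character(utils::packageVersion("nscdyn")),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = rapply(config, unclass, how = "replace")), path)
  invisible(path)
}
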