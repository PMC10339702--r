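obs_columns <- c("participant_id", "cohort", "analyte", "time_h",
                 "conc_ng_ml", "flag")

#' Read observation records (standard delimited format)
#'
#' Tab-delimited with header `participant_id, cohort, analyte, time_h,
#' conc_ng_ml, flag`. An empty file with a valid header yields an empty
#' record set.
#'
#' @param path file path.
#' @return Observation data frame.
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(time_h = "numeric",
                                         conc_ng_ml = "numeric")[
                                           character(0)])
  miss <- setdiff(obs_columns, names(df))
  if (length(miss))
    stop("observation file missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(df)) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df$time_h))) |
                 !is.finite(suppressWarnings(as.numeric(df$conc_ng_ml))))
    if (length(bad))
      stop("unparseable observation row(s) at line(s): ",
           paste(bad + 1L, collapse = ", "), call. = FALSE)
    df$time_h <- as.numeric(df$time_h)
    df$conc_ng_ml <- as.numeric(df$conc_ng_ml)
  }
  df[, obs_columns]
}

#' Write observation records
#'
#' @param records observation data frame.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(records, path) {
  miss <- setdiff(obs_columns, names(records))
  if (length(miss))
    stop("records missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  utils::write.table(records[, obs_columns], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a simulated series as a delimited table
#'
#' Long format with columns `subject_id`, `analyte`, `matrix`, `time_h`,
#' `conc_ng_ml`.
#'
#' @param series `conc_time_series`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_simulation <- function(series, path) {
  utils::write.table(as.data.frame(series), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a JSON run configuration
#'
#' Strict: unknown top-level keys are rejected. Recognised keys:
#' `seed`, `regimen` (preset name), `horizon_h`, `n_per_arm`, `n_trials`,
#' `n_grid`, `alpha`, `cohort` (`sars_neg`/`sars_pos`), `population`
#' (`healthy`/`mild_covid`), `observations` (path), `subject`
#' (list: `body_weight`, `bp`, plus multipliers), `fit` (list:
#' `parameter`, `bounds`, `objective`, `grid`), `options` (model options),
#' `out_dir`.
#'
#' @param path JSON file path.
#' @return Named list of class `config_bundle`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  known <- c("seed", "regimen", "horizon_h", "n_per_arm", "n_trials",
             "n_grid", "alpha", "cohort", "population", "observations",
             "subject", "fit", "options", "out_dir")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(cfg$observations) && !file.exists(cfg$observations))
    stop("referenced observation file does not exist: ", cfg$observations,
         call. = FALSE)
  structure(cfg, class = "config_bundle")
}
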