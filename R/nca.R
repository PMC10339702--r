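series_column <- function(series, analyte, matrix) {
  stopifnot(inherits(series, "conc_time_series"))
  analyte <- match.arg(toupper(analyte), c("HCQ", "DHCQ"))
  matrix <- match.arg(matrix, c("blood", "plasma"))
  series$conc[, paste(tolower(analyte), matrix, sep = "_")]
}

#' Terminal half-life by log-linear regression
#'
#' Least-squares regression of the natural log of concentration on time
#' within a window; the half-life is `ln 2 / |slope|`.
#'
#' @param series `conc_time_series`.
#' @param analyte `"HCQ"` or `"DHCQ"`.
#' @param window_h numeric length-2, regression window (h).
#' @param matrix `"blood"` (default) or `"plasma"`.
#' @return Terminal half-life, h.
#' @export
estimate_terminal_halflife <- function(series, analyte = "HCQ",
                                       window_h, matrix = "blood") {
  conc <- series_column(series, analyte, matrix)
  sel <- series$time_h >= window_h[1] & series$time_h <= window_h[2] &
    conc > 0
  if (sum(sel) < 3L)
    stop("need at least 3 positive concentrations in the window",
         call. = FALSE)
  fit <- stats::lm(log(conc[sel]) ~ series$time_h[sel])
  slope <- stats::coef(fit)[[2]]
  log(2) / abs(slope)
}

#' Exposure metrics (AUC and Cmax) over a window
#'
#' AUC by the linear trapezoid rule on the simulation output grid; Cmax as
#' the grid maximum within the window.
#'
#' @param series `conc_time_series`.
#' @param analyte `"HCQ"` or `"DHCQ"`.
#' @param matrix `"blood"` or `"plasma"`.
#' @param t_start_h,t_end_h window, h; `t_start_h < t_end_h` and the window
#'   must lie on the output grid.
#' @return Named numeric vector `c(auc, cmax)` (ng·h/mL, ng/mL).
#' @export
compute_exposure <- function(series, analyte = "HCQ", matrix = "blood",
                             t_start_h = 0, t_end_h = 672) {
  conc <- series_column(series, analyte, matrix)
  if (t_start_h >= t_end_h)
    stop("t_start_h must be < t_end_h", call. = FALSE)
  if (t_end_h > max(series$time_h) + 1e-9 || t_start_h < min(series$time_h))
    stop("exposure window outside the simulation grid", call. = FALSE)
  sel <- series$time_h >= t_start_h - 1e-9 & series$time_h <= t_end_h + 1e-9
  tt <- series$time_h[sel]
  cc <- conc[sel]
  auc <- sum(diff(tt) * (utils::head(cc, -1) + utils::tail(cc, -1)) / 2)
  c(auc = auc, cmax = max(cc))
}
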