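#' Rank-based percentile (ordinal rank n = P/100 x N)
#'
#' The percentile of a dataset is the value at ordinal rank
#' `round(P/100 * N)` (half-up rounding, clamped to `[1, N]`) of the
#' sorted data — no interpolation, matching the rank definition used for
#' the 5th/95th prediction band.
#'
#' @param x numeric dataset (nonempty).
#' @param P percentile in `[0, 100]`.
#' @return The dataset value at the rank.
#' @export
percentile_eq1 <- function(x, P) {
  if (!length(x)) stop("empty dataset", call. = FALSE)
  n <- floor(P / 100 * length(x) + 0.5)  # half-up
  n <- min(max(n, 1L), length(x))
  sort(x)[n]
}

#' Proportion of observations within the simulated prediction band
#'
#' Matches each observation to the nearest simulation grid time (within
#' `tol_h`), takes the 5th and 95th rank percentiles of the simulated
#' population cross-section at that time for the observation's analyte and
#' matrix, and reports the proportion of observations inside the closed
#' band. (The band is labeled a "95% prediction interval" in the field but
#' spans the 5th-95th percentiles, i.e. nominal 90% coverage; the
#' convention is preserved.) Unmatched observations are excluded and
#' counted.
#'
#' @param observations data frame with columns `analyte`, `time_h`,
#'   `conc_ng_ml` (e.g. from [read_observations()]); rows with other
#'   analytes/flags should be filtered by the caller.
#' @param simulations list of `conc_time_series` (the simulated
#'   population).
#' @param matrix `"blood"` (default) or `"plasma"`.
#' @param tol_h time-matching tolerance, h.
#' @return List with `wpi`, `n_used`, `n_excluded`,
#'   `band` (data frame of matched times and band edges).
#' @export
wpi <- function(observations, simulations, matrix = "blood", tol_h = 0.5) {
  stopifnot(is.data.frame(observations), length(simulations) > 0)
  grid <- simulations[[1]]$time_h
  inside <- logical(0)
  band <- list()
  n_excl <- 0L
  for (r in seq_len(nrow(observations))) {
    obs <- observations[r, ]
    j <- which.min(abs(grid - obs$time_h))
    if (abs(grid[j] - obs$time_h) > tol_h) { n_excl <- n_excl + 1L; next }
    cross <- vapply(simulations, function(s)
      series_column(s, obs$analyte, matrix)[j], numeric(1))
    lo <- percentile_eq1(cross, 5)
    hi <- percentile_eq1(cross, 95)
    inside <- c(inside, obs$conc_ng_ml >= lo && obs$conc_ng_ml <= hi)
    band[[length(band) + 1L]] <- data.frame(
      time_h = grid[j], analyte = obs$analyte, lo = lo, hi = hi,
      obs = obs$conc_ng_ml)
  }
  if (!length(inside)) stop("no observation matched the grid", call. = FALSE)
  list(wpi = mean(inside), n_used = length(inside), n_excluded = n_excl,
       band = do.call(rbind, band))
}

#' Average fold error and absolute average fold error
#'
#' `AFE = 10^(mean(log10(pred/obs)))`;
#' `AAFE = 10^(mean(|log10(pred/obs)|))`. Pairs with a nonpositive member
#' are excluded and counted; zero usable pairs is an error.
#'
#' @param predicted,observed positive concentration vectors of equal
#'   length.
#' @return List with `afe`, `aafe`, `n_used`, `n_excluded`.
#' @export
afe_aafe <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("predicted and observed must have equal length", call. = FALSE)
  ok <- is.finite(predicted) & is.finite(observed) &
    predicted > 0 & observed > 0
  if (!any(ok)) stop("no usable predicted/observed pairs", call. = FALSE)
  lr <- log10(predicted[ok] / observed[ok])
  list(afe = 10^mean(lr), aafe = 10^mean(abs(lr)),
       n_used = sum(ok), n_excluded = sum(!ok))
}

#' Qualify a population simulation against sparse observations
#'
#' Pairs each observation with the geometric mean of the simulated
#' population cross-section at its matched time (the standard
#' predicted-central-tendency choice on log scale), computes AFE/AAFE per
#' analyte and overall, and the within-band proportion (WPI).
#'
#' @param observations observation data frame (quantifiable records).
#' @param simulations list of `conc_time_series`.
#' @param matrix `"blood"` or `"plasma"`.
#' @param tol_h time-matching tolerance, h.
#' @return An `evaluation_report` list: `wpi`, `afe`, `aafe`, `per_analyte`
#'   data frame, exclusion counts, band definition.
#' @export
evaluate_model <- function(observations, simulations, matrix = "blood",
                           tol_h = 0.5) {
  grid <- simulations[[1]]$time_h
  pred <- rep(NA_real_, nrow(observations))
  for (r in seq_len(nrow(observations))) {
    obs <- observations[r, ]
    j <- which.min(abs(grid - obs$time_h))
    if (abs(grid[j] - obs$time_h) > tol_h) next
    cross <- vapply(simulations, function(s)
      series_column(s, obs$analyte, matrix)[j], numeric(1))
    cross <- cross[cross > 0]
    if (length(cross)) pred[r] <- exp(mean(log(cross)))
  }
  usable <- !is.na(pred)
  fe <- afe_aafe(pred[usable], observations$conc_ng_ml[usable])
  per <- lapply(unique(observations$analyte), function(a) {
    sel <- usable & observations$analyte == a
    if (!any(sel)) return(NULL)
    f <- afe_aafe(pred[sel], observations$conc_ng_ml[sel])
    data.frame(analyte = a, afe = f$afe, aafe = f$aafe, n = f$n_used)
  })
  w <- wpi(observations, simulations, matrix, tol_h)
  structure(list(wpi = w$wpi, afe = fe$afe, aafe = fe$aafe,
                 per_analyte = do.call(rbind, per),
                 n_used = fe$n_used,
                 n_excluded = sum(!usable) + fe$n_excluded,
                 band = "5th-95th rank percentile (nominal 90% coverage)"),
            class = "evaluation_report")
}
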