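#' Dose regimen
#'
#' A table of dosing events. Amounts are labeled-product (sulfate salt) mg
#' for every route and are converted to base internally with the compound
#' salt factor; the `iv310` preset therefore ships 400 mg labeled, i.e.
#' 310 mg base.
#'
#' @param time_h event times, h since first dose, nondecreasing, >= 0.
#' @param amount_mg labeled amounts, mg, >= 0.
#' @param route `"oral"` or `"iv_infusion"` (recycled).
#' @param infusion_h infusion duration, h; must be > 0 for iv events.
#' @return An object of class `dose_regimen` (a data frame).
#' @export
dose_regimen <- function(time_h, amount_mg, route = "oral", infusion_h = NA) {
  n <- length(time_h)
  route <- rep_len(route, n)
  infusion_h <- rep_len(infusion_h, n)
  if (any(time_h < 0) || is.unsorted(time_h))
    stop("event times must be >= 0 and nondecreasing", call. = FALSE)
  if (any(amount_mg < 0)) stop("amounts must be >= 0", call. = FALSE)
  if (!all(route %in% c("oral", "iv_infusion")))
    stop("route must be 'oral' or 'iv_infusion'", call. = FALSE)
  iv <- route == "iv_infusion"
  if (any(iv & (is.na(infusion_h) | infusion_h <= 0)))
    stop("infusion duration must be > 0 for iv_infusion events",
         call. = FALSE)
  structure(data.frame(time_h = time_h, amount_mg = amount_mg, route = route,
                       infusion_h = infusion_h),
            class = c("dose_regimen", "data.frame"))
}

#' Named regimen presets
#'
#' * `"pep"` — post-exposure prophylaxis: 400 mg daily for 3 days then
#'   200 mg daily for 11 days (labeled sulfate doses).
#' * `"treatment"` — mild-COVID-19 treatment: 400 mg twice daily for 1 day
#'   then 200 mg twice daily for 9 days.
#' * `"iv310"` — single 310 mg base i.v. infusion (default duration 0.5 h).
#'
#' @param name preset name.
#' @param infusion_h infusion duration for `"iv310"`, h.
#' @return A `dose_regimen`.
#' @export
regimen_preset <- function(name = c("pep", "treatment", "iv310"),
                           infusion_h = 0.5) {
  name <- match.arg(name)
  switch(name,
    pep = dose_regimen(c(0:2 * 24, 3:13 * 24),
                       c(rep(400, 3), rep(200, 11))),
    treatment = dose_regimen(c(0, 12, 24 + 0:17 * 12),
                             c(400, 400, rep(200, 18))),
    iv310 = dose_regimen(0, 310 / 0.775, route = "iv_infusion",
                         infusion_h = infusion_h))
}
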