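#' Empirical blood-to-plasma ratio frequency table
#'
#' Discrete distribution of B/P levels applied per individual. The default
#' table covers the reported range 1-12 (90% of observations after a single
#' i.v. dose) with uniform weights; a user-supplied frequency table is used
#' verbatim.
#'
#' @param values B/P levels (> 0).
#' @param weights probabilities (>= 0, summing to 1 within 1e-9).
#' @return An object of class `bp_frequency_table`.
#' @export
bp_frequency_table <- function(values, weights = NULL) {
  if (!length(values)) stop("empty B/P table", call. = FALSE)
  if (is.null(weights)) weights <- rep(1 / length(values), length(values))
  if (length(weights) != length(values))
    stop("values and weights must have equal length", call. = FALSE)
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9)
    stop("weights must be >= 0 and sum to 1", call. = FALSE)
  if (any(values <= 0)) stop("B/P values must be > 0", call. = FALSE)
  structure(list(values = as.numeric(values), weights = as.numeric(weights)),
            class = "bp_frequency_table")
}

#' Default B/P table: levels 1..12, uniform weights
#' @return A `bp_frequency_table`.
#' @export
default_bp_table <- function() bp_frequency_table(1:12)

#' Population sampling specification
#'
#' Distributional recipe for virtual subjects. Pathway expression
#' multipliers are log-normal with the given mean and CV; the mild-COVID-19
#' population shifts the CYP2C8 and CYP3A4 means only (60% and 30%
#' reductions), leaving every CV — and CYP2D6 entirely — unchanged. Body
#' weight is log-normal (median/CV); the renal multiplier is log-normal
#' with mean 1.
#'
#' @param label `"healthy"` or `"mild_covid"`.
#' @param mean_mult named means for `cyp2c8`, `cyp3a4`, `cyp2d6`.
#' @param cv named CVs for the same pathways (lognormal).
#' @param renal_cv CV of the renal multiplier.
#' @param weight_median_kg,weight_cv body-weight distribution.
#' @param bp_table `bp_frequency_table`.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(label = c("healthy", "mild_covid"),
                            mean_mult = NULL,
                            cv = c(cyp2c8 = 0.45, cyp3a4 = 0.45,
                                   cyp2d6 = 0.60),
                            renal_cv = 0.30,
                            weight_median_kg = 78, weight_cv = 0.25,
                            bp_table = default_bp_table()) {
  label <- match.arg(label)
  if (is.null(mean_mult)) {
    mean_mult <- if (label == "mild_covid")
      c(cyp2c8 = 0.40, cyp3a4 = 0.70, cyp2d6 = 1) else
      c(cyp2c8 = 1, cyp3a4 = 1, cyp2d6 = 1)
  }
  p <- c("cyp2c8", "cyp3a4", "cyp2d6")
  if (length(setdiff(p, names(mean_mult))) || length(setdiff(p, names(cv))))
    stop("mean_mult and cv must name cyp2c8, cyp3a4, cyp2d6", call. = FALSE)
  if (any(mean_mult[p] <= 0))
    stop("mean multipliers must be > 0", call. = FALSE)
  if (any(cv[p] < 0) || renal_cv < 0 || weight_cv < 0)
    stop("CVs must be >= 0", call. = FALSE)
  stopifnot(inherits(bp_table, "bp_frequency_table"))
  structure(list(label = label, mean_mult = mean_mult[p], cv = cv[p],
                 renal_cv = renal_cv, weight_median_kg = weight_median_kg,
                 weight_cv = weight_cv, bp_table = bp_table),
            class = "population_spec")
}

#' Draw one B/P value from a frequency table
#'
#' @param table `bp_frequency_table`.
#' @param n number of draws.
#' @return Numeric vector of B/P values.
#' @export
sample_bp <- function(table, n = 1) {
  stopifnot(inherits(table, "bp_frequency_table"))
  if (length(table$values) == 1L) return(rep(table$values, n))
  sample(table$values, n, replace = TRUE, prob = table$weights)
}

# lognormal draw with arithmetic mean m and CV; CV 0 degenerates to m
rlnorm_mean_cv <- function(n, m, cv) {
  if (cv == 0) return(rep(m, n))
  sdlog <- sqrt(log(1 + cv^2))
  m * exp(stats::rnorm(n, 0, sdlog) - sdlog^2 / 2)
}

#' Sample a virtual subject from a population specification
#'
#' The draw order (weight, B/P, CYP2C8, CYP3A4, CYP2D6, renal) is fixed so
#' that, under a common seed, pathways whose distributions are identical in
#' two specifications (e.g. CYP2D6 in healthy vs. mild COVID-19) receive
#' identical draws.
#'
#' @param spec `population_spec`.
#' @param id subject identifier.
#' @param model `model_params` used to resolve the subject.
#' @return A resolved `virtual_subject`.
#' @export
sample_subject <- function(spec, id = "subj1", model = default_model()) {
  stopifnot(inherits(spec, "population_spec"))
  w <- spec$weight_median_kg * exp(stats::rnorm(1, 0,
         sqrt(log(1 + spec$weight_cv^2))))
  bp <- sample_bp(spec$bp_table)
  mult <- c(
    cyp2c8 = rlnorm_mean_cv(1, spec$mean_mult[["cyp2c8"]],
                            spec$cv[["cyp2c8"]]),
    cyp3a4 = rlnorm_mean_cv(1, spec$mean_mult[["cyp3a4"]],
                            spec$cv[["cyp3a4"]]),
    cyp2d6 = rlnorm_mean_cv(1, spec$mean_mult[["cyp2d6"]],
                            spec$cv[["cyp2d6"]]))
  renal <- rlnorm_mean_cv(1, 1, spec$renal_cv)
  virtual_subject(id = id, body_weight = w, bp = bp, multipliers = mult,
                  renal_multiplier = renal, model = model)
}

#' Analytic expected exposure change from pathway expression reductions
#'
#' Percent of total clearance removed is `100 * sum(fm_p * reduction_p)`;
#' the reciprocal AUC ratio `1 / (1 - sum(fm_p * reduction_p))` is the
#' steady-state exposure multiplier implied by the clearance change. With
#' the reported fm/fe partition and the 60%/30% CYP2C8/CYP3A4 reductions
#' this evaluates to ~28%.
#'
#' @param partition `clearance_partition`.
#' @param reductions named vector of fractional reductions in `[0, 1]`
#'   for any of `cyp2c8`, `cyp3a4`, `cyp2d6`, `renal`.
#' @return Named vector `c(percent_removed, auc_ratio)`.
#' @export
expected_exposure_change <- function(partition,
                                     reductions = c(cyp2c8 = 0.60,
                                                    cyp3a4 = 0.30)) {
  stopifnot(inherits(partition, "clearance_partition"))
  if (any(reductions < 0 | reductions > 1))
    stop("reductions must be in [0, 1]", call. = FALSE)
  fm <- c(cyp2c8 = partition$fm_cyp2c8, cyp3a4 = partition$fm_cyp3a4,
          cyp2d6 = partition$fm_cyp2d6, renal = partition$fe_renal)
  red <- stats::setNames(numeric(4), names(fm))
  red[names(reductions)] <- reductions
  removed <- sum(fm * red)
  c(percent_removed = 100 * removed, auc_ratio = 1 / (1 - removed))
}

#' Export a sampled cohort as a subject table
#'
#' @param spec `population_spec`.
#' @param n number of subjects.
#' @param model `model_params`.
#' @param id_prefix prefix for subject ids.
#' @return List of `virtual_subject`s with a `data.frame` audit table in
#'   attribute `"table"` (one row per subject with all multipliers).
#' @export
sample_cohort <- function(spec, n, model = default_model(),
                          id_prefix = spec$label) {
  subjects <- lapply(seq_len(n), function(i)
    sample_subject(spec, id = sprintf("%s_%04d", id_prefix, i), model))
  tab <- do.call(rbind, lapply(subjects, function(s)
    data.frame(id = s$id, body_weight = s$body_weight, bp = s$bp,
               cyp2c8 = s$multipliers[["cyp2c8"]],
               cyp3a4 = s$multipliers[["cyp3a4"]],
               cyp2d6 = s$multipliers[["cyp2d6"]],
               renal = s$renal_multiplier)))
  attr(subjects, "table") <- tab
  subjects
}
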