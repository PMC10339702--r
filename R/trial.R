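#' Deterministic per-subject seed stream
#'
#' Splits one global seed into per-subject seeds so that adding subjects
#' (or arms) never perturbs earlier subjects' draws. The stream is the
#' affine sequence `(seed + 1000003 * k) mod 2147483629` (a prime below
#' 2^31), offset by a stage label hash so different stages decorrelate.
#'
#' @param seed global integer seed.
#' @param k subject index (1-based) or vector of indices.
#' @param stage character stage label.
#' @return Integer seed(s) in `[1, 2147483628]`.
#' @export
split_seed <- function(seed, k, stage = "default") {
  p <- 2147483629
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% p
  s <- (as.numeric(seed) %% p + h + 1000003 * as.numeric(k)) %% p
  as.integer(s + 1)
}

#' Virtual trial design
#'
#' @param n_per_arm participants per trial per arm (>= 2).
#' @param n_trials number of replicate trials (default 10).
#' @param regimen regimen preset name or `dose_regimen` (default
#'   `"treatment"`).
#' @param horizon_h simulation horizon (default 672 h).
#' @param seed global seed.
#' @return An object of class `trial_design`.
#' @export
trial_design <- function(n_per_arm, n_trials = 10, regimen = "treatment",
                         horizon_h = 672, seed = 1) {
  if (n_per_arm < 2) stop("n_per_arm must be >= 2", call. = FALSE)
  if (n_trials < 1) stop("n_trials must be >= 1", call. = FALSE)
  if (is.character(regimen)) regimen <- regimen_preset(regimen)
  stopifnot(inherits(regimen, "dose_regimen"))
  structure(list(n_per_arm = n_per_arm, n_trials = n_trials,
                 regimen = regimen, horizon_h = horizon_h, seed = seed),
            class = "trial_design")
}

simulate_arm <- function(design, spec, arm, model) {
  n_tot <- design$n_per_arm * design$n_trials
  rows <- vector("list", n_tot)
  for (i in seq_len(n_tot)) {
    set.seed(split_seed(design$seed, i, stage = paste0("trial_", arm)))
    s <- sample_subject(spec, id = sprintf("%s_%05d", arm, i), model)
    sim <- simulate_profile(s, design$regimen, design$horizon_h)
    eh <- compute_exposure(sim, "HCQ", "blood", 0, design$horizon_h)
    ed <- compute_exposure(sim, "DHCQ", "blood", 0, design$horizon_h)
    rows[[i]] <- data.frame(
      subject_id = s$id, arm = arm,
      trial = (i - 1L) %/% design$n_per_arm + 1L,
      bp = s$bp,
      hcq_auc = eh[["auc"]], hcq_cmax = eh[["cmax"]],
      dhcq_auc = ed[["auc"]], dhcq_cmax = ed[["cmax"]])
  }
  do.call(rbind, rows)
}

#' Run a two-arm virtual trial set
#'
#' Simulates `n_trials` trials of `n_per_arm` subjects per arm (1:1
#' healthy vs. mild COVID-19) on blood concentrations over the horizon and
#' returns per-subject exposure metrics. Per-subject seeds derive from the
#' design seed via [split_seed()], so results are reproducible and
#' insensitive to subject-count extension.
#'
#' @param design `trial_design`.
#' @param healthy,covid `population_spec` for the two arms.
#' @param model `model_params`.
#' @return Data frame of per-subject metrics (one row per subject;
#'   columns `subject_id`, `arm`, `trial`, `bp`, `hcq_auc`, `hcq_cmax`,
#'   `dhcq_auc`, `dhcq_cmax`).
#' @export
run_trial_set <- function(design, healthy = population_spec("healthy"),
                          covid = population_spec("mild_covid"),
                          model = default_model()) {
  stopifnot(inherits(design, "trial_design"))
  rbind(simulate_arm(design, healthy, "healthy", model),
        simulate_arm(design, covid, "mild_covid", model))
}

#' Pool per-subject metrics into per-arm mean/SD summaries
#'
#' Pooling is over individuals (the concatenated per-subject metrics), not
#' over trial means.
#'
#' @param metrics data frame from [run_trial_set()].
#' @return Data frame with one row per (analyte, metric, arm).
#' @export
pool_metrics <- function(metrics) {
  cols <- c(hcq_auc = "hcq_auc", hcq_cmax = "hcq_cmax",
            dhcq_auc = "dhcq_auc", dhcq_cmax = "dhcq_cmax")
  out <- expand.grid(metric = names(cols), arm = unique(metrics$arm),
                     stringsAsFactors = FALSE)
  out$mean <- NA_real_; out$sd <- NA_real_; out$n <- NA_integer_
  for (r in seq_len(nrow(out))) {
    v <- metrics[metrics$arm == out$arm[r], cols[[out$metric[r]]]]
    out$mean[r] <- mean(v); out$sd[r] <- stats::sd(v); out$n[r] <- length(v)
  }
  out
}

#' Two-arm comparison with the pooled-summary t-test convention
#'
#' Equal-variance two-sample t-test computed from pooled-over-trials means
#' and SDs with `n_effective` = participants per trial per arm:
#' `t = (m1 - m2) / sqrt((s1^2 + s2^2) / n_effective)`, `df = 2
#' n_effective - 2`, two-sided. This convention reproduces the published
#' virtual-trial p-values exactly; the ratio reported is arm2/arm1.
#'
#' @param mean1,sd1 pooled mean and SD of the reference (healthy) arm.
#' @param mean2,sd2 pooled mean and SD of the comparison (COVID) arm.
#' @param n_effective participants per trial per arm (>= 2).
#' @return List with `ratio`, `t`, `df`, `p`.
#' @export
compare_arms <- function(mean1, sd1, mean2, sd2, n_effective) {
  if (n_effective < 2) stop("n_effective must be >= 2", call. = FALSE)
  if (sd1 < 0 || sd2 < 0) stop("SDs must be >= 0", call. = FALSE)
  if (sd1 == 0 && sd2 == 0 && mean1 != mean2)
    stop("degenerate input: zero SDs with unequal means", call. = FALSE)
  se <- sqrt((sd1^2 + sd2^2) / n_effective)
  tstat <- if (se == 0) 0 else (mean2 - mean1) / se
  df <- 2 * n_effective - 2
  p <- 2 * stats::pt(-abs(tstat), df)
  list(ratio = mean2 / mean1, t = tstat, df = df, p = p)
}

#' Arm-comparison summary for all analytes and metrics
#'
#' @param metrics per-subject metrics from [run_trial_set()].
#' @param n_effective per-trial arm size used in the t-test; defaults to
#'   the per-trial arm size inferred from the data.
#' @param ref,alt arm labels (ratio and t are alt vs. ref).
#' @return Data frame with one row per (analyte, metric): pooled means,
#'   SDs, ratio, t, df, p.
#' @export
summarize_comparison <- function(metrics, n_effective = NULL,
                                 ref = "healthy", alt = "mild_covid") {
  pooled <- pool_metrics(metrics)
  if (is.null(n_effective)) {
    n_effective <- nrow(metrics[metrics$arm == ref, ]) /
      max(metrics$trial[metrics$arm == ref])
  }
  mets <- unique(pooled$metric)
  out <- lapply(mets, function(mm) {
    a <- pooled[pooled$metric == mm & pooled$arm == ref, ]
    b <- pooled[pooled$metric == mm & pooled$arm == alt, ]
    cmp <- compare_arms(a$mean, a$sd, b$mean, b$sd, n_effective)
    data.frame(metric = mm,
               analyte = toupper(sub("_.*", "", mm)),
               quantity = sub(".*_", "", mm),
               mean_ref = a$mean, sd_ref = a$sd,
               mean_alt = b$mean, sd_alt = b$sd,
               n_effective = n_effective,
               ratio = cmp$ratio, t = cmp$t, df = cmp$df, p = cmp$p)
  })
  do.call(rbind, out)
}

#' Sample-size scan over trial designs
#'
#' Runs [run_trial_set()] at each arm size in `n_grid` and reports, per
#' (n, analyte, metric), the arm ratio, p-value and significance at
#' `alpha` (two-sided, no multiplicity adjustment).
#'
#' @param n_grid vector of per-trial arm sizes.
#' @param n_trials replicate trials per design.
#' @param healthy,covid population specs.
#' @param model `model_params`.
#' @param alpha significance level (default 0.05).
#' @param seed global seed.
#' @param regimen,horizon_h forwarded to [trial_design()].
#' @return Data frame with columns `n_per_arm`, `analyte`, `quantity`,
#'   `ratio`, `p`, `significant`.
#' @export
power_scan <- function(n_grid, n_trials = 10,
                       healthy = population_spec("healthy"),
                       covid = population_spec("mild_covid"),
                       model = default_model(), alpha = 0.05, seed = 1,
                       regimen = "treatment", horizon_h = 672) {
  if (!length(n_grid)) stop("empty n grid", call. = FALSE)
  out <- lapply(n_grid, function(n) {
    des <- trial_design(n, n_trials, regimen, horizon_h,
                        seed = split_seed(seed, n, "power_scan"))
    cmpr <- summarize_comparison(run_trial_set(des, healthy, covid, model))
    data.frame(n_per_arm = n, analyte = cmpr$analyte,
               quantity = cmpr$quantity, ratio = cmpr$ratio, p = cmpr$p,
               significant = cmpr$p <= alpha)
  })
  do.call(rbind, out)
}
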