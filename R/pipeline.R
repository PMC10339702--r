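cfg_default <- function(cfg, key, default) {
  if (is.null(cfg[[key]])) default else cfg[[key]]
}

log_stage <- function(fmt, ...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), sprintf(fmt, ...))
}

#' Run one pipeline command
#'
#' Orchestrates the analysis stages behind a single entry point with a
#' configuration bundle; every stage logs its seed and writes its outputs
#' (delimited tables plus a summary JSON) under `out_dir`. Rerunning with
#' the same config and seed reproduces the outputs.
#'
#' Commands:
#' * `simulate` — default subject (or `subject` config) on `regimen`;
#'   writes the concentration table.
#' * `trial` — two-arm virtual trial (`n_per_arm`, `n_trials`); writes
#'   per-subject metrics and the arm-comparison summary.
#' * `power` — sample-size scan over `n_grid`.
#' * `fit` — single-parameter estimation against `observations`.
#' * `evaluate` — qualification of a population simulation against
#'   `observations` (WPI, AFE, AAFE).
#' * `synth` — synthetic DBS cohort generation (`cohort`).
#'
#' @param config `config_bundle` from [read_config()], or a plain list.
#' @param command one of `simulate`, `trial`, `power`, `fit`, `evaluate`,
#'   `synth`.
#' @return A result bundle (list) with `command`, `seed`, `outputs` (paths)
#'   and `summary`, invisibly; the summary JSON is also written.
#' @export
run_pipeline <- function(config, command = c("simulate", "trial", "power",
                                             "fit", "evaluate", "synth")) {
  command <- match.arg(command)
  cfg <- config
  seed <- cfg_default(cfg, "seed", 1)
  out_dir <- cfg_default(cfg, "out_dir", ".")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  model <- default_model(options = cfg_default(cfg, "options", list()))
  regimen_name <- cfg_default(cfg, "regimen", "treatment")
  horizon <- cfg_default(cfg, "horizon_h", 672)
  log_stage("command=%s seed=%d", command, as.integer(seed))
  outputs <- character(0)
  summary <- list(command = command, seed = seed,
                  config = unclass(cfg))

  if (command == "simulate") {
    sc <- cfg_default(cfg, "subject", list())
    mult <- c(cyp2c8 = cfg_default(sc, "cyp2c8", 1),
              cyp3a4 = cfg_default(sc, "cyp3a4", 1),
              cyp2d6 = cfg_default(sc, "cyp2d6", 1))
    s <- virtual_subject(id = "sim1",
                         body_weight = cfg_default(sc, "body_weight", NULL),
                         bp = cfg_default(sc, "bp", NULL),
                         multipliers = mult,
                         renal_multiplier = cfg_default(sc, "renal", 1),
                         model = model)
    sim <- simulate_profile(s, regimen_preset(regimen_name), horizon)
    f <- file.path(out_dir, "simulation.tsv")
    write_simulation(sim, f); outputs <- f
    summary$exposure <- list(
      hcq = as.list(compute_exposure(sim, "HCQ", "blood", 0, horizon)),
      dhcq = as.list(compute_exposure(sim, "DHCQ", "blood", 0, horizon)))
  } else if (command == "trial") {
    des <- trial_design(cfg_default(cfg, "n_per_arm", 30),
                        cfg_default(cfg, "n_trials", 10),
                        regimen_name, horizon, seed = seed)
    metrics <- run_trial_set(des, model = model)
    cmp <- summarize_comparison(metrics)
    f1 <- file.path(out_dir, "trial_metrics.tsv")
    f2 <- file.path(out_dir, "trial_comparison.tsv")
    utils::write.table(metrics, f1, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    utils::write.table(cmp, f2, sep = "\t", row.names = FALSE, quote = FALSE)
    outputs <- c(f1, f2)
    summary$comparison <- cmp
  } else if (command == "power") {
    scan <- power_scan(cfg_default(cfg, "n_grid", c(10, 30, 100)),
                       cfg_default(cfg, "n_trials", 10), model = model,
                       alpha = cfg_default(cfg, "alpha", 0.05), seed = seed,
                       regimen = regimen_name, horizon_h = horizon)
    f <- file.path(out_dir, "power_scan.tsv")
    utils::write.table(scan, f, sep = "\t", row.names = FALSE, quote = FALSE)
    outputs <- f
    summary$scan <- scan
  } else if (command == "fit") {
    fit_cfg <- cfg$fit
    if (is.null(fit_cfg)) stop("fit command needs a 'fit' config block",
                               call. = FALSE)
    obs <- read_observations(cfg$observations)
    spec <- fit_spec(fit_cfg$parameter, as.numeric(fit_cfg$bounds),
                     cfg_default(fit_cfg, "objective", "sse_log_conc"),
                     fit_cfg$grid)
    res <- fit_parameter(spec, obs, regimen_preset(regimen_name),
                         model = model)
    summary$fit <- res[c("estimate", "objective", "degenerate")]
  } else if (command == "evaluate") {
    obs <- read_observations(cfg$observations)
    obs <- obs[obs$flag == "quantifiable", , drop = FALSE]
    pop <- population_spec(cfg_default(cfg, "population", "healthy"))
    n_sim <- cfg_default(cfg, "n_per_arm", 30)
    sims <- lapply(seq_len(n_sim), function(i) {
      set.seed(split_seed(seed, i, "evaluate"))
      simulate_profile(sample_subject(pop, sprintf("eval_%03d", i), model),
                       regimen_preset(regimen_name), horizon)
    })
    rep <- evaluate_model(obs, sims)
    summary$evaluation <- rep[c("wpi", "afe", "aafe", "n_used",
                                "n_excluded")]
  } else if (command == "synth") {
    csp <- cohort_spec(cfg_default(cfg, "cohort", "sars_neg"))
    pop <- population_spec(cfg_default(cfg, "population", "healthy"))
    rec <- generate_dbs_dataset(csp, pop, seed = seed, model = model)
    f <- file.path(out_dir, paste0(csp$label, "_observations.tsv"))
    write_observations(rec, f); outputs <- f
    summary$counts <- as.list(table(rec$analyte[rec$flag == "quantifiable"]))
  }

  sf <- file.path(out_dir, paste0(command, "_summary.json"))
  jsonlite::write_json(summary, sf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  outputs <- c(outputs, sf)
  log_stage("done: %s", paste(outputs, collapse = ", "))
  invisible(list(command = command, seed = seed, outputs = outputs,
                 summary = summary))
}
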