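# Shared fixtures built in code. The default model bundle is cached once
# per test run; tests that mutate it must copy it first.
the_model <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- default_model()
    m
  }
})

# Minimal conc_time_series for NCA tests, built directly from a formula.
make_series <- function(time_h, hcq_blood, dhcq_blood = hcq_blood * 0,
                        bp = 1) {
  conc <- cbind(hcq_blood = hcq_blood, hcq_plasma = hcq_blood / bp,
                dhcq_blood = dhcq_blood, dhcq_plasma = dhcq_blood / bp)
  structure(list(time_h = time_h, conc = conc,
                 eliminated = matrix(0, length(time_h), 4),
                 bp = bp, subject_id = "synthetic", balance_rel_max = 0),
            class = "conc_time_series")
}

# Synthetic calibration data: DHCQ blood concentrations after the single
# i.v. HCQ infusion, generated by the simulator itself with a known
# metabolite clearance.
make_iv_obs <- function(model, clearance, times, noise_cv = 0, seed = NULL) {
  m <- model
  m$metabolite$metabolic_clearance <- clearance
  s <- virtual_subject(model = m)
  sim <- simulate_profile(s, regimen_preset("iv310"), max(times) + 1)
  conc <- stats::approx(sim$time_h, sim$conc[, "dhcq_blood"],
                        xout = times)$y
  if (noise_cv > 0) {
    if (!is.null(seed)) set.seed(seed)
    sdlog <- sqrt(log(1 + noise_cv^2))
    conc <- conc * exp(stats::rnorm(length(conc), 0, sdlog) - sdlog^2 / 2)
  }
  data.frame(analyte = "DHCQ", time_h = times, conc_ng_ml = conc)
}

iv_times <- c(24, 72, 168, 336, 504)

# Well-mixed single-compartment limit: organ flows scaled up, unit Kp,
# B/P 1, metabolite formation off (fe = 1).
one_compartment_model <- function(flow_scale = 1e6) {
  m <- the_model()
  ov <- stats::setNames(rep(1, 12), pbpk_organs())
  for (cmp in c("hcq", "dhcq")) {
    m$compounds[[cmp]]$kp_overrides <- ov
    m$compounds[[cmp]]$kp_scalar <- 1
    m$compounds[[cmp]]$default_BP <- 1
  }
  m$partition <- clearance_partition(5.8, 0, 0, 0, 1)
  m$physiology$flows <- m$physiology$flows * flow_scale
  m$physiology$cardiac_output <- m$physiology$cardiac_output * flow_scale
  m
}
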