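test_that("an empty regimen yields an all-zero profile", {
  s <- virtual_subject(model = the_model())
  sim <- simulate_profile(s, dose_regimen(numeric(0), numeric(0)), 48)
  expect_true(all(sim$conc == 0))
  expect_true(all(sim$eliminated == 0))
})

test_that("fast-flow unit-Kp limit matches the one-compartment closed form", {
  m <- one_compartment_model()
  s <- virtual_subject(bp = 1, model = m)
  dose_base <- 310
  reg <- dose_regimen(0, dose_base / 0.775, route = "iv_infusion",
                      infusion_h = 0.01)
  sim <- simulate_profile(s, reg, 240, dt = 1)
  V <- sum(m$physiology$volumes)          # all compartments well mixed
  CL <- 5.8                               # renal only
  sel <- sim$time_h >= 1
  pred <- dose_base / V * exp(-CL * sim$time_h[sel] / V) * 1000  # ng/mL
  expect_equal(sim$conc[sel, "hcq_blood"], pred, tolerance = 0.01)
  expect_true(all(sim$conc[, "dhcq_blood"] == 0))  # formation off
})

test_that("mass balance, matrix consistency and dose linearity hold on a
           multi-dose oral run", {
  s <- virtual_subject(bp = 4, model = the_model())
  sim <- simulate_profile(s, regimen_preset("treatment"), 672)
  expect_lt(sim$balance_rel_max, 1e-3)
  expect_equal(sim$conc[, "hcq_blood"],
               sim$conc[, "hcq_plasma"] * s$bp)
  expect_equal(sim$conc[, "dhcq_blood"],
               sim$conc[, "dhcq_plasma"] * s$bp)
  # linear in dose
  reg2 <- regimen_preset("treatment")
  reg2$amount_mg <- reg2$amount_mg * 2
  sim2 <- simulate_profile(s, reg2, 672)
  expect_equal(sim2$conc, sim$conc * 2, tolerance = 1e-8)
  # horizon must cover the last dose
  expect_error(simulate_profile(s, regimen_preset("treatment"), 100),
               "horizon")
})

test_that("blood tmax after a single oral dose is in the absorption-
           calibrated 3-4 h range", {
  s <- virtual_subject(model = the_model())
  sim <- simulate_profile(s, dose_regimen(0, 200), 24, dt = 0.25)
  tmax <- sim$time_h[which.max(sim$conc[, "hcq_blood"])]
  expect_gte(tmax, 3)
  expect_lte(tmax, 4)
})

test_that("long daily dosing keeps accumulating for months", {
  s <- virtual_subject(model = the_model())
  reg <- dose_regimen(0:179 * 24, 200)
  sim <- simulate_profile(s, reg, 180 * 24, dt = 4)
  trough <- function(day) sim$conc[which.min(abs(sim$time_h - day * 24)),
                                   "hcq_blood"]
  expect_gt(trough(180) / trough(28), 1.5)
})

test_that("terminal half-life regression recovers known slopes", {
  tt <- 0:2000
  mono <- make_series(tt, 50 * exp(-log(2) / 100 * tt))
  expect_equal(estimate_terminal_halflife(mono, "HCQ", c(100, 900)), 100,
               tolerance = 1e-3)
  # biexponential: slow phase t1/2 = ln2/0.001 = 693 h past the crossover
  bi <- make_series(tt, 10 * exp(-0.1 * tt) + 1 * exp(-0.001 * tt))
  expect_equal(estimate_terminal_halflife(bi, "HCQ", c(500, 2000)),
               log(2) / 0.001, tolerance = 0.01)
  short <- make_series(0:4, c(1, 2, 0, 0, 0))
  expect_error(estimate_terminal_halflife(short, "HCQ", c(2, 4)),
               "at least 3")
})

test_that("exposure metrics follow the trapezoid rule", {
  flat <- make_series(0:672, rep(100, 673))
  e <- compute_exposure(flat, "HCQ", "blood", 0, 672)
  expect_equal(e[["auc"]], 67200)
  expect_equal(e[["cmax"]], 100)
  tt <- 0:672
  expo <- make_series(tt, 200 * exp(-0.01 * tt))
  e2 <- compute_exposure(expo, "HCQ", "blood", 0, 672)
  expect_equal(e2[["auc"]], 200 / 0.01 * (1 - exp(-0.01 * 672)),
               tolerance = 1e-3)
  expect_error(compute_exposure(flat, "HCQ", "blood", 100, 100), "t_start")
  expect_error(compute_exposure(flat, "HCQ", "blood", 0, 1000), "outside")
})
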