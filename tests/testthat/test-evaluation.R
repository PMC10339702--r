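test_that("rank percentile follows the ordinal-rank rule", {
  expect_equal(percentile_eq1(1:100, 95), 95)
  expect_equal(percentile_eq1(1:100, 5), 5)
  expect_equal(percentile_eq1(1:10, 50), 5)
  expect_equal(percentile_eq1(42, 99), 42)       # single element, clamped
  expect_equal(percentile_eq1(1:10, 1), 1)       # rank clamps at 1
  expect_error(percentile_eq1(numeric(0), 50), "empty")
})

test_that("AFE/AAFE identities and swap symmetry hold", {
  expect_equal(afe_aafe(c(1, 2, 3), c(1, 2, 3))[c("afe", "aafe")],
               list(afe = 1, aafe = 1))
  r <- afe_aafe(c(10, 0.1), c(1, 1))
  expect_equal(r$afe, 1)
  expect_equal(r$aafe, 10)
  r2 <- afe_aafe(c(2, 4, 8), c(1, 2, 4))
  expect_equal(r2$afe, 2)
  expect_equal(r2$aafe, 2)
  # nonpositive pairs are excluded, not fatal, until none remain
  r3 <- afe_aafe(c(2, 0), c(1, 5))
  expect_equal(r3$n_excluded, 1)
  expect_error(afe_aafe(c(0, 0), c(1, 1)), "no usable")
  # property: swap inverts AFE, fixes AAFE; AAFE >= max(AFE, 1/AFE)
  set.seed(8)
  for (i in 1:20) {
    p <- rlnorm(15, 0, 1)
    o <- rlnorm(15, 0, 1)
    a <- afe_aafe(p, o)
    b <- afe_aafe(o, p)
    expect_equal(a$afe, 1 / b$afe, tolerance = 1e-12)
    expect_equal(a$aafe, b$aafe, tolerance = 1e-12)
    expect_gte(a$aafe + 1e-12, max(a$afe, 1 / a$afe))
  }
})

test_that("WPI hits its trivial bounds and nominal coverage", {
  model <- the_model()
  pop <- population_spec("healthy")
  sims <- lapply(1:30, function(i) {
    set.seed(split_seed(21, i, "wpi_test"))
    simulate_profile(sample_subject(pop, sprintf("w%02d", i), model),
                     regimen_preset("treatment"), 480)
  })
  grid_t <- c(48, 120, 240, 360)
  cross <- function(t) sapply(sims, function(s)
    s$conc[s$time_h == t, "hcq_blood"])
  med <- sapply(grid_t, function(t) stats::median(cross(t)))
  obs_med <- data.frame(analyte = "HCQ", time_h = grid_t, conc_ng_ml = med)
  expect_equal(wpi(obs_med, sims)$wpi, 1)
  obs_hi <- obs_med
  obs_hi$conc_ng_ml <- sapply(grid_t, function(t) max(cross(t)) * 1.01)
  expect_equal(wpi(obs_hi, sims)$wpi, 0)
  # records drawn from the simulated cross-sections land in the 5th-95th
  # band about 90% of the time
  set.seed(99)
  n_obs <- 300
  obs_rand <- do.call(rbind, lapply(seq_len(n_obs), function(r) {
    t <- sample(grid_t, 1)
    data.frame(analyte = "HCQ", time_h = t,
               conc_ng_ml = sample(cross(t), 1))
  }))
  w <- wpi(obs_rand, sims)
  expect_lt(abs(w$wpi - 0.90), 3 * sqrt(0.9 * 0.1 / n_obs) + 0.02)
  # out-of-horizon observations are excluded and counted
  obs_far <- rbind(obs_med, data.frame(analyte = "HCQ", time_h = 5000,
                                       conc_ng_ml = 1))
  expect_equal(wpi(obs_far, sims)$n_excluded, 1)
})

test_that("evaluate_model pairs observations with the geometric-mean
           prediction", {
  model <- the_model()
  pop <- population_spec("healthy")
  sims <- lapply(1:12, function(i) {
    set.seed(split_seed(31, i, "eval_test"))
    simulate_profile(sample_subject(pop, sprintf("e%02d", i), model),
                     regimen_preset("treatment"), 240)
  })
  tt <- c(36, 96, 180)
  gm <- sapply(tt, function(t)
    exp(mean(log(sapply(sims, function(s)
      s$conc[s$time_h == t, "dhcq_blood"])))))
  obs <- data.frame(analyte = "DHCQ", time_h = tt, conc_ng_ml = 2 * gm)
  rep <- evaluate_model(obs, sims)
  expect_equal(rep$afe, 0.5, tolerance = 1e-9)  # predictions are half obs
  expect_equal(rep$aafe, 2, tolerance = 1e-9)
  expect_s3_class(rep$per_analyte, "data.frame")
})
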