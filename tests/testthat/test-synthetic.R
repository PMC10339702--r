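test_that("assay censoring flags records without altering values", {
  rec <- data.frame(participant_id = "p1", cohort = "sars_neg",
                    analyte = "HCQ", time_h = 1:3,
                    conc_ng_ml = c(0.5, 150, 2500))
  out <- apply_assay_censoring(rec, 1, 2000)
  expect_equal(out$flag, c("below_lloq", "quantifiable", "above_uloq"))
  expect_equal(out$conc_ng_ml, rec$conc_ng_ml)
  all_in <- apply_assay_censoring(rec[2, ], 1, 2000)
  expect_equal(all_in$flag, "quantifiable")
  expect_error(apply_assay_censoring(rec, 2000, 1), "LLOQ")
})

test_that("cohort generation is deterministic and respects quantifiable
           bounds", {
  spec <- cohort_spec("sars_neg", n_participants = 10,
                      target_counts = NULL)
  pop <- population_spec("healthy")
  a <- generate_dbs_dataset(spec, pop, seed = 4, model = the_model())
  b <- generate_dbs_dataset(spec, pop, seed = 4, model = the_model())
  expect_identical(a, b)
  q <- a[a$flag == "quantifiable", ]
  expect_true(all(q$conc_ng_ml >= spec$lloq & q$conc_ng_ml <= spec$uloq))
  expect_true(all(a$analyte %in% c("HCQ", "DHCQ")))
  # total censoring: an absurd LLOQ leaves nothing quantifiable
  hi <- cohort_spec("sars_neg", n_participants = 4, lloq = 1e6,
                    uloq = 2e6, target_counts = NULL)
  rec <- generate_dbs_dataset(hi, pop, seed = 4, model = the_model())
  expect_equal(sum(rec$flag == "quantifiable"), 0)
})

test_that("disabling noise reproduces the simulator concentrations", {
  model <- the_model()
  spec <- cohort_spec("sars_pos", n_participants = 3, time_error_sd = 0,
                      residual_cv = 0, adherence = 1,
                      target_counts = NULL)
  pop <- population_spec("healthy")
  rec <- generate_dbs_dataset(spec, pop, seed = 12, model = model)
  # re-derive each participant independently from the same seed stream
  for (i in 1:3) {
    set.seed(split_seed(split_seed(12, 1, "dbs_attempt"), i,
                        "dbs_sars_pos"))
    s <- sample_subject(pop, id = sprintf("sars_pos_%03d", i), model)
    stats::runif(nrow(spec$regimen))  # adherence draws (all kept)
    sim <- simulate_profile(s, spec$regimen, 672)
    k <- sample(spec$samples_range, 1)
    t_true <- sort(stats::runif(k, 24, 672))
    expected <- stats::approx(sim$time_h, sim$conc[, "hcq_blood"],
                              xout = t_true)$y
    got <- rec[rec$participant_id == s$id & rec$analyte == "HCQ", ]
    expect_equal(got$time_h, t_true)
    expect_equal(got$conc_ng_ml, expected)
  }
})

test_that("adherence thinning matches its probability", {
  spec <- cohort_spec("sars_pos", n_participants = 40, adherence = 0.9,
                      target_counts = NULL)
  rec <- generate_dbs_dataset(spec, population_spec("healthy"), seed = 6,
                              model = the_model())
  offered <- attr(rec, "doses_offered")
  taken <- attr(rec, "doses_taken")
  se <- sqrt(0.9 * 0.1 / offered)
  expect_lt(abs(taken / offered - 0.9), 3 * se)
})

test_that("unreachable target counts fail with a named shortfall", {
  spec <- cohort_spec("sars_pos", n_participants = 2,
                      target_counts = c(HCQ = 500, DHCQ = 500))
  expect_error(generate_dbs_dataset(spec, population_spec("healthy"),
                                    seed = 2, model = the_model(),
                                    max_retries = 2),
               "target quantifiable counts")
})
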