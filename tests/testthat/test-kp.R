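test_that("a plasma-like tissue partitions 1:1", {
  # composition identical to plasma: all drug in extracellular water at
  # plasma pH, no lipid, no acidic-phospholipid excess
  df <- data.frame(organ = c(pbpk_organs(), "blood_cells"),
                   f_ew = c(rep(1, 12), 0),
                   f_iw = c(rep(0, 12), 0.603),
                   f_nl = c(rep(0, 12), 0.0017),
                   f_np = c(rep(0, 12), 0.0029),
                   ap_mg_g = c(rep(0, 12), 0.5),
                   ph_iw = c(rep(7.4, 12), 7.22))
  cp <- the_model()$compounds$hcq
  cp$kp_scalar <- 1
  cp$kp_overrides <- numeric(0)
  kp <- predict_kp_method2(cp, tissue_composition(df), BP = 7)
  expect_equal(unname(kp[pbpk_organs()]), rep(1, 12))
})

test_that("predicted Kp matches an independent step-by-step evaluation", {
  m <- the_model()
  cp <- m$compounds$hcq
  tab <- m$tissues$table
  hct <- 0.45
  BP <- 7
  # independent, fully spelled-out evaluation of the partition equations
  P <- 10^cp$logP
  X <- function(ph) 10^(9.7 - ph) + 10^(9.7 + 8.3 - 2 * ph)
  Xp <- X(7.4)
  bc <- tab[tab$organ == "blood_cells", ]
  kbc <- (BP - (1 - hct)) / hct
  ka_ap <- (kbc / cp$fu_plasma * (1 + Xp) - (1 + X(bc$ph_iw)) * bc$f_iw -
              (P * bc$f_nl + (0.3 * P + 0.7) * bc$f_np)) /
    (bc$ap_mg_g * X(bc$ph_iw))
  oracle <- sapply(c("kidney", "brain", "gut", "lung", "bone"), function(o) {
    r <- tab[tab$organ == o, ]
    (r$f_ew + cp$fu_plasma *
       ((1 + X(r$ph_iw)) / (1 + Xp) * r$f_iw +
        ka_ap * r$ap_mg_g * X(r$ph_iw) / (1 + Xp) +
        (P * r$f_nl + (0.3 * P + 0.7) * r$f_np) / (1 + Xp))) * cp$kp_scalar
  })
  kp <- predict_kp_method2(cp, m$tissues, BP, hct)
  expect_equal(kp[names(oracle)], oracle, tolerance = 1e-12)
  expect_true(all(kp > 0))
  # overrides replace the scaled predictions
  expect_equal(unname(kp["adipose"]), 800)
  expect_equal(unname(kp["muscle"]), 900)
})

test_that("acidic phospholipid increases the organ's Kp and only it", {
  m <- the_model()
  cp <- m$compounds$hcq
  cp$kp_overrides <- numeric(0)
  tis2 <- m$tissues
  tis2$table$ap_mg_g[tis2$table$organ == "heart"] <-
    tis2$table$ap_mg_g[tis2$table$organ == "heart"] * 2
  kp1 <- predict_kp_method2(cp, m$tissues, 7)
  kp2 <- predict_kp_method2(cp, tis2, 7)
  expect_gt(kp2[["heart"]], kp1[["heart"]])
  other <- setdiff(names(kp1), "heart")
  expect_equal(kp1[other], kp2[other])
})

test_that("inconsistent B/P is rejected", {
  m <- the_model()
  expect_error(predict_kp_method2(m$compounds$hcq, m$tissues, BP = 0.4),
               "hematocrit")
})

test_that("Vss reduces to total volume for unit partitioning and scales
           linearly in the tissue term", {
  m <- the_model()
  phys <- m$physiology
  kp1 <- stats::setNames(rep(1, 13), c(pbpk_organs(), "blood_cells"))
  vss <- compute_vss(kp1, phys, BP = 1)
  expect_equal(vss[["vss_plasma"]], sum(phys$volumes))
  expect_equal(vss[["vss_blood"]], sum(phys$volumes))
  # doubling every organ Kp doubles the tissue term exactly
  kp2 <- kp1 * 2
  v_pl <- sum(phys$volumes[c("arterial_blood", "venous_blood")]) *
    (1 - phys$hematocrit)
  expect_equal(compute_vss(kp2, phys, 1)[["vss_plasma"]] - v_pl,
               2 * (vss[["vss_plasma"]] - v_pl))
  expect_error(compute_vss(kp1[-1], phys, 1), "missing organ")
})

test_that("default HCQ parameterization yields a Vss in the reported range", {
  m <- the_model()
  kp <- predict_kp_method2(m$compounds$hcq, m$tissues, 7)
  vss <- compute_vss(kp, m$physiology, 7)[["vss_plasma"]]
  expect_gt(vss, 25000)
  expect_lt(vss, 94000)
})
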