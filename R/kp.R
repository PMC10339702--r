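#' Mechanistic tissue-to-plasma partition coefficients for an ionizable base
#'
#' Predicts plasma-referenced Kp values for every organ (plus `blood_cells`)
#' from tissue composition, in the Rodgers-Rowland style for
#' moderate-to-strong diprotic bases: drug in extracellular water is treated
#' as plasma-equivalent; intracellular water partition follows the
#' ionization ratio between intracellular and plasma pH; neutral lipid and
#' neutral phospholipid partition uses the ionization-corrected
#' lipophilicity; and electrostatic association with acidic phospholipids
#' is calibrated so that the blood-cell compartment reproduces the supplied
#' blood-to-plasma ratio (B/P) given the hematocrit and plasma unbound
#' fraction.
#'
#' For a diprotic base the ionized:neutral ratio at pH is
#' `X(pH) = 10^(pKa1 - pH) + 10^(pKa1 + pKa2 - 2 pH)`.
#' The organ Kp is
#' `Kp = f_EW + fu_p * [ (1 + X_iw)/(1 + X_p) * f_IW
#'                      + Ka_AP * AP * X_iw / (1 + X_p)
#'                      + (P f_NL + (0.3 P + 0.7) f_NP) / (1 + X_p) ]`
#' with `Ka_AP` solved from the blood-cell row and the implied
#' blood-cell-to-plasma ratio `K_BC = (BP - (1 - Hct)) / Hct`.
#' Predicted values are multiplied by the compound `kp_scalar`, then any
#' `kp_overrides` replace the scaled values.
#'
#' @param compound `compound_parameters`.
#' @param tissues `tissue_composition`.
#' @param BP blood-to-plasma concentration ratio; must exceed
#'   `1 - hematocrit` so the implied blood-cell partition is positive.
#' @param hematocrit fraction, default 0.45.
#' @return Named numeric vector of plasma-referenced Kp (12 organs plus
#'   `blood_cells`; the blood-cell value is the implied K_BC, not scaled).
#' @export
predict_kp_method2 <- function(compound, tissues, BP,
                               hematocrit = 0.45) {
  stopifnot(inherits(compound, "compound_parameters"),
            inherits(tissues, "tissue_composition"))
  if (BP <= 1 - hematocrit)
    stop("BP must exceed 1 - hematocrit for a positive blood-cell partition",
         call. = FALSE)
  tab <- tissues$table
  fu <- compound$fu_plasma
  P <- 10^compound$logP
  pka <- compound$base_pKa  # sorted decreasing: pka1 >= pka2
  X <- function(pH) 10^(pka[1] - pH) + 10^(pka[1] + pka[2] - 2 * pH)
  Xp <- X(tissues$plasma_pH)

  bc <- tab[tab$organ == "blood_cells", ]
  Xbc <- X(bc$ph_iw)
  k_bc <- (BP - (1 - hematocrit)) / hematocrit
  lip_bc <- P * bc$f_nl + (0.3 * P + 0.7) * bc$f_np
  # solve the acidic-phospholipid association constant from the blood cells
  num <- k_bc / fu * (1 + Xp) - (1 + Xbc) * bc$f_iw - lip_bc
  if (num <= 0)
    stop("BP inconsistent with hematocrit/fu_plasma: implied blood-cell ",
         "association is nonpositive", call. = FALSE)
  ka_ap <- num / (bc$ap_mg_g * Xbc)

  org <- tab[tab$organ != "blood_cells", ]
  Xiw <- X(org$ph_iw)
  kp <- org$f_ew + fu * ((1 + Xiw) / (1 + Xp) * org$f_iw +
                         ka_ap * org$ap_mg_g * Xiw / (1 + Xp) +
                         (P * org$f_nl + (0.3 * P + 0.7) * org$f_np) /
                           (1 + Xp))
  kp <- kp * compound$kp_scalar
  names(kp) <- org$organ
  ov <- compound$kp_overrides
  ov <- ov[names(ov) %in% names(kp)]
  kp[names(ov)] <- ov
  c(kp, blood_cells = k_bc)
}

#' Steady-state volume of distribution
#'
#' Plasma-referenced Vss is plasma volume plus the Kp-weighted sum of organ
#' volumes (red cells enter through the `blood_cells` Kp); the
#' blood-referenced value is the plasma-referenced value divided by B/P.
#'
#' @param kp_map named Kp vector from [predict_kp_method2()] (must cover
#'   all organs and `blood_cells`).
#' @param physiology `physiology_system`.
#' @param BP blood-to-plasma ratio.
#' @param fu_plasma unused in the volume sum; retained for signature
#'   completeness (unbound-referenced volumes are `Vss / fu_plasma`).
#' @return Named numeric vector `c(vss_plasma, vss_blood)`, L.
#' @export
compute_vss <- function(kp_map, physiology, BP, fu_plasma = NULL) {
  stopifnot(inherits(physiology, "physiology_system"))
  organs <- pbpk_organs()
  miss <- setdiff(c(organs, "blood_cells"), names(kp_map))
  if (length(miss))
    stop("kp_map missing organ(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  v <- physiology$volumes
  v_blood <- v[["arterial_blood"]] + v[["venous_blood"]]
  v_plasma <- v_blood * (1 - physiology$hematocrit)
  v_bc <- v_blood * physiology$hematocrit
  vss_p <- v_plasma + sum(v[organs] * kp_map[organs]) +
    v_bc * kp_map[["blood_cells"]]
  c(vss_plasma = vss_p, vss_blood = vss_p / BP)
}
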