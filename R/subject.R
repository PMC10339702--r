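#' Construct a (resolved) virtual subject
#'
#' Resolves one individual against a model parameter bundle: physiology is
#' scaled allometrically to body weight (volumes proportional to weight,
#' flows and clearances to weight^0.75), per-compound Kp maps are predicted
#' from the subject's B/P (or the default B/P when `freeze_bp_kp` is set),
#' and pathway intrinsic clearances are back-calculated from the total
#' blood clearance, the fm/fe partition and the well-stirred liver relation
#' so that the default subject reproduces the total blood clearance.
#' CYP expression multipliers scale the pathway intrinsic clearances; the
#' renal multiplier scales both renal clearances. The DHCQ whole-organ
#' metabolic clearance is not CYP-partitioned (its isoform contributions
#' are unknown) and is unaffected by the CYP multipliers.
#'
#' @param id subject identifier.
#' @param body_weight kg.
#' @param bp blood-to-plasma concentration ratio (shared by HCQ and DHCQ).
#' @param multipliers named numeric vector with entries `cyp2c8`,
#'   `cyp3a4`, `cyp2d6` (expression multipliers, > 0).
#' @param renal_multiplier renal function multiplier, > 0.
#' @param model `model_params` bundle from [default_model()].
#' @return An object of class `virtual_subject`.
#' @export
virtual_subject <- function(id = "subj1", body_weight = NULL, bp = NULL,
                            multipliers = c(cyp2c8 = 1, cyp3a4 = 1,
                                            cyp2d6 = 1),
                            renal_multiplier = 1,
                            model = default_model()) {
  stopifnot(inherits(model, "model_params"))
  phys <- model$physiology
  if (is.null(body_weight)) body_weight <- phys$body_weight
  hcq <- model$compounds$hcq
  dhcq <- model$compounds$dhcq
  if (is.null(bp)) bp <- hcq$default_BP
  if (any(multipliers <= 0) || renal_multiplier <= 0)
    stop("multipliers must be > 0", call. = FALSE)
  miss <- setdiff(c("cyp2c8", "cyp3a4", "cyp2d6"), names(multipliers))
  if (length(miss))
    stop("multipliers missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (bp <= 0) stop("bp must be > 0", call. = FALSE)

  wr <- body_weight / phys$body_weight
  phys_s <- phys
  phys_s$volumes <- phys$volumes * wr
  phys_s$flows <- phys$flows * wr^0.75
  phys_s$cardiac_output <- phys$cardiac_output * wr^0.75
  phys_s$body_weight <- body_weight

  kp_bp <- if (isTRUE(model$options$freeze_bp_kp)) hcq$default_BP else bp
  kp <- list(
    hcq = predict_kp_method2(hcq, model$tissues, kp_bp, phys$hematocrit),
    dhcq = predict_kp_method2(dhcq, model$tissues, kp_bp, phys$hematocrit))

  # reference hepatic-vein flow (unscaled) for the well-stirred back-calc
  q_hv <- sum(phys$flows[c("liver", "gut", "pancreas", "spleen")])
  part <- model$partition
  fu_b_ref <- hcq$fu_plasma / hcq$default_BP
  fm_tot <- 1 - part$fe_renal
  cl_hep <- part$total_blood_clearance * fm_tot
  if (cl_hep >= q_hv)
    stop("hepatic clearance exceeds hepatic blood flow; cannot invert ",
         "the well-stirred relation", call. = FALSE)
  fuclint_ref <- q_hv * cl_hep / (q_hv - cl_hep)
  clint_ref <- fuclint_ref / fu_b_ref
  fm <- c(cyp2c8 = part$fm_cyp2c8, cyp3a4 = part$fm_cyp3a4,
          cyp2d6 = part$fm_cyp2d6)
  clint_path <- if (fm_tot > 0) clint_ref * fm / fm_tot else fm * 0
  m <- multipliers[c("cyp2c8", "cyp3a4", "cyp2d6")]
  clint_hcq <- sum(clint_path * m) * wr^0.75

  met <- model$metabolite
  cl_m <- met$metabolic_clearance
  if (cl_m >= q_hv)
    stop("DHCQ metabolic clearance exceeds hepatic blood flow", call. = FALSE)
  clint_dhcq <- (q_hv * cl_m / (q_hv - cl_m)) / fu_b_ref * wr^0.75

  cl_renal_hcq <- part$total_blood_clearance * part$fe_renal *
    renal_multiplier * wr^0.75
  cl_renal_dhcq <- met$renal_clearance * renal_multiplier * wr^0.75
  if (isTRUE(model$options$dhcq_renal_plasma_referenced))
    cl_renal_dhcq <- cl_renal_dhcq / bp

  structure(list(id = id, body_weight = body_weight, bp = bp,
                 multipliers = m, renal_multiplier = renal_multiplier,
                 fu_blood = hcq$fu_plasma / bp,
                 kp = kp,
                 clearances = list(hcq_intrinsic = clint_hcq,
                                   hcq_renal = cl_renal_hcq,
                                   dhcq_intrinsic = clint_dhcq,
                                   dhcq_renal = cl_renal_dhcq),
                 physiology = phys_s,
                 compounds = model$compounds,
                 options = model$options),
            class = "virtual_subject")
}
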