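#' Compound parameter set
#'
#' Physicochemical and absorption parameters for one analyte (HCQ or DHCQ).
#' Both analytes are diprotic bases; `base_pKa` holds the two basic pKa
#' values. `kp_scalar` is a global multiplier applied to every predicted
#' tissue-to-plasma partition coefficient (Kp); `kp_overrides` replaces
#' individual organ Kp values after scaling (used for the deep-tissue
#' adipose/muscle adjustment that captures the extended terminal phase).
#'
#' @param name analyte label.
#' @param molecular_weight g/mol.
#' @param base_pKa numeric vector of length 2, basic pKa values.
#' @param logP octanol-water log partition coefficient of the neutral species.
#' @param fu_plasma unbound fraction in plasma, in (0, 1].
#' @param default_BP default blood-to-plasma concentration ratio (> 0).
#' @param ka first-order oral absorption rate constant, 1/h.
#' @param fa fraction absorbed, in (0, 1].
#' @param salt_factor mg base per mg labeled product, in (0, 1].
#' @param kp_scalar global multiplier on predicted Kp (> 0).
#' @param kp_overrides named numeric vector, organ -> plasma-referenced Kp.
#' @return An object of class `compound_parameters`.
#' @export
compound_parameters <- function(name, molecular_weight, base_pKa, logP,
                                fu_plasma, default_BP, ka, fa,
                                salt_factor = 1, kp_scalar = 1,
                                kp_overrides = numeric(0)) {
  stopifnot(is.character(name), length(base_pKa) == 2L)
  if (!(fu_plasma > 0 && fu_plasma <= 1))
    stop("fu_plasma must be in (0, 1]", call. = FALSE)
  if (default_BP <= 0) stop("default_BP must be > 0", call. = FALSE)
  if (!(salt_factor > 0 && salt_factor <= 1))
    stop("salt_factor must be in (0, 1]", call. = FALSE)
  if (kp_scalar <= 0) stop("kp_scalar must be > 0", call. = FALSE)
  if (length(kp_overrides) && any(kp_overrides <= 0))
    stop("kp_overrides must be > 0", call. = FALSE)
  if (!(fa > 0 && fa <= 1)) stop("fa must be in (0, 1]", call. = FALSE)
  if (ka <= 0) stop("ka must be > 0", call. = FALSE)
  structure(list(name = name, molecular_weight = molecular_weight,
                 base_pKa = sort(as.numeric(base_pKa), decreasing = TRUE),
                 logP = logP, fu_plasma = fu_plasma, default_BP = default_BP,
                 ka = ka, fa = fa, salt_factor = salt_factor,
                 kp_scalar = kp_scalar, kp_overrides = kp_overrides),
            class = "compound_parameters")
}

#' Partition of total parent clearance into pathways
#'
#' Fractions of total (blood-referenced) HCQ clearance attributed to
#' CYP2C8, CYP3A4 and CYP2D6 metabolism and to renal excretion. The three
#' CYP pathways all form DHCQ.
#'
#' @param total_blood_clearance total systemic blood clearance, L/h.
#' @param fm_cyp2c8,fm_cyp3a4,fm_cyp2d6 fractions metabolized per pathway.
#' @param fe_renal fraction excreted renally.
#' @return An object of class `clearance_partition`.
#' @export
clearance_partition <- function(total_blood_clearance, fm_cyp2c8, fm_cyp3a4,
                                fm_cyp2d6, fe_renal) {
  fr <- c(fm_cyp2c8, fm_cyp3a4, fm_cyp2d6, fe_renal)
  if (any(fr < 0 | fr > 1))
    stop("clearance fractions must be in [0, 1]", call. = FALSE)
  if (abs(sum(fr) - 1) > 1e-6)
    stop("fm_cyp2c8 + fm_cyp3a4 + fm_cyp2d6 + fe_renal must sum to 1",
         call. = FALSE)
  if (total_blood_clearance <= 0)
    stop("total_blood_clearance must be > 0", call. = FALSE)
  structure(list(total_blood_clearance = total_blood_clearance,
                 fm_cyp2c8 = fm_cyp2c8, fm_cyp3a4 = fm_cyp3a4,
                 fm_cyp2d6 = fm_cyp2d6, fe_renal = fe_renal),
            class = "clearance_partition")
}

#' Metabolite (DHCQ) clearance parameters
#'
#' DHCQ is eliminated by renal excretion (observed value 2.9 L/h) and a
#' whole-organ hepatic metabolic clearance, the quantity estimated against
#' i.v.-dose metabolite data. Both are blood-referenced by default.
#'
#' @param compound `compound_parameters` for DHCQ.
#' @param renal_clearance L/h, >= 0.
#' @param metabolic_clearance L/h, >= 0 (whole-organ hepatic).
#' @return An object of class `metabolite_parameters`.
#' @export
metabolite_parameters <- function(compound, renal_clearance,
                                  metabolic_clearance) {
  stopifnot(inherits(compound, "compound_parameters"))
  if (renal_clearance < 0 || metabolic_clearance < 0)
    stop("metabolite clearances must be >= 0", call. = FALSE)
  structure(list(compound = compound, renal_clearance = renal_clearance,
                 metabolic_clearance = metabolic_clearance),
            class = "metabolite_parameters")
}

#' Tissue composition table
#'
#' Fractional extracellular/intracellular water, neutral lipid, neutral
#' phospholipid, acidic phospholipid concentration (mg/g) and intracellular
#' pH per organ, plus a `blood_cells` row used to calibrate the
#' acidic-phospholipid association constant from the observed B/P.
#'
#' @param df data frame with columns `organ`, `f_ew`, `f_iw`, `f_nl`,
#'   `f_np`, `ap_mg_g`, `ph_iw`.
#' @param plasma_pH plasma pH (default 7.4).
#' @return An object of class `tissue_composition`.
#' @export
tissue_composition <- function(df, plasma_pH = 7.4) {
  need <- c("organ", "f_ew", "f_iw", "f_nl", "f_np", "ap_mg_g", "ph_iw")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("tissue composition table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  fr <- as.matrix(df[, c("f_ew", "f_iw", "f_nl", "f_np")])
  if (any(fr < 0 | fr > 1))
    stop("tissue fractions must be in [0, 1]", call. = FALSE)
  if (any(df$ph_iw < 6 | df$ph_iw > 8) || plasma_pH < 6 || plasma_pH > 8)
    stop("pH values must be in [6, 8]", call. = FALSE)
  if (!"blood_cells" %in% df$organ)
    stop("tissue composition table must contain a 'blood_cells' row",
         call. = FALSE)
  structure(list(table = as.data.frame(df), plasma_pH = plasma_pH),
            class = "tissue_composition")
}

#' System physiology
#'
#' Organ volumes (L) and blood flows (L/h) for a reference adult, plus
#' hematocrit and body weight. The lung receives total cardiac output,
#' defined as the sum of venous-return flows (non-splanchnic organ flows
#' plus the hepatic-vein flow). Gut, pancreas and spleen drain into the
#' liver (portal vein); the liver additionally receives hepatic arterial
#' flow.
#'
#' @param volumes named numeric vector of organ volumes, L (must include
#'   the 12 tissues plus `arterial_blood` and `venous_blood`).
#' @param flows named numeric vector of organ blood flows, L/h (tissues
#'   only; the liver entry is the hepatic arterial flow).
#' @param hematocrit fraction in (0, 1).
#' @param body_weight kg.
#' @param gfr glomerular filtration reference, L/h.
#' @return An object of class `physiology_system`.
#' @export
physiology_system <- function(volumes, flows, hematocrit = 0.45,
                              body_weight = 78, gfr = 7.2) {
  organs <- pbpk_organs()
  miss <- setdiff(c(organs, "arterial_blood", "venous_blood"), names(volumes))
  if (length(miss))
    stop("physiology volumes missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  fl_need <- setdiff(organs, "lung")
  miss <- setdiff(fl_need, names(flows))
  if (length(miss))
    stop("physiology flows missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(volumes <= 0) || any(flows[fl_need] <= 0))
    stop("volumes and flows must be > 0", call. = FALSE)
  if (!(hematocrit > 0 && hematocrit < 1))
    stop("hematocrit must be in (0, 1)", call. = FALSE)
  co <- sum(flows[fl_need])  # all venous return passes through the lung
  structure(list(volumes = volumes[c(organs, "arterial_blood", "venous_blood")],
                 flows = flows[fl_need], cardiac_output = co,
                 hematocrit = hematocrit, body_weight = body_weight,
                 gfr = gfr),
            class = "physiology_system")
}

#' Organ names of the whole-body model
#' @return Character vector of the 12 tissue compartments plus lung order.
#' @export
pbpk_organs <- function() {
  c("adipose", "bone", "brain", "gut", "heart", "kidney", "liver", "lung",
    "muscle", "pancreas", "skin", "spleen")
}

path_extdata <- function(file) {
  system.file("extdata", file, package = "hcqpbpk", mustWork = TRUE)
}

read_tsv_strict <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Load the shipped default tissue composition
#' @return A `tissue_composition` object.
#' @export
default_tissue_composition <- function() {
  tissue_composition(read_tsv_strict(path_extdata("tissue_composition.tsv")))
}

#' Load the shipped default physiology
#' @return A `physiology_system` object (78 kg reference adult).
#' @export
default_physiology <- function() {
  df <- read_tsv_strict(path_extdata("physiology.tsv"))
  vols <- stats::setNames(df$volume_L, df$organ)
  fl <- df[!is.na(df$flow_L_h), ]
  physiology_system(vols, stats::setNames(fl$flow_L_h, fl$organ))
}

read_compound_row <- function(row, overrides) {
  ov <- overrides[overrides$compound == row$name, ]
  compound_parameters(
    name = row$name, molecular_weight = row$molecular_weight,
    base_pKa = c(row$pka1, row$pka2), logP = row$logP,
    fu_plasma = row$fu_plasma, default_BP = row$default_BP,
    ka = row$ka, fa = row$fa, salt_factor = row$salt_factor,
    kp_scalar = row$kp_scalar,
    kp_overrides = stats::setNames(ov$kp, ov$organ))
}

#' Default model parameter bundle
#'
#' Assembles the shipped compound, clearance, physiology and tissue tables
#' into the bundle consumed by [virtual_subject()] and [simulate_profile()].
#' Every component can be replaced.
#'
#' @param compounds list with elements `hcq` and `dhcq`
#'   (`compound_parameters`).
#' @param partition `clearance_partition` for HCQ.
#' @param metabolite `metabolite_parameters` for DHCQ.
#' @param physiology `physiology_system`.
#' @param tissues `tissue_composition`.
#' @param options list; recognised entries: `freeze_bp_kp` (logical,
#'   predict Kp at the default B/P instead of the subject's sampled B/P),
#'   `dt` output grid step in h, `dhcq_renal_plasma_referenced` (logical,
#'   reinterpret the DHCQ renal clearance as plasma-referenced).
#' @return An object of class `model_params`.
#' @export
default_model <- function(compounds = NULL, partition = NULL,
                          metabolite = NULL, physiology = NULL,
                          tissues = NULL, options = list()) {
  cp <- read_tsv_strict(path_extdata("compound_parameters.tsv"))
  ov <- read_tsv_strict(path_extdata("kp_overrides.tsv"))
  if (is.null(compounds)) {
    compounds <- list(hcq = read_compound_row(cp[cp$name == "HCQ", ], ov),
                      dhcq = read_compound_row(cp[cp$name == "DHCQ", ], ov))
  }
  if (is.null(partition)) {
    pr <- read_tsv_strict(path_extdata("clearance_partition.tsv"))
    partition <- clearance_partition(pr$total_blood_clearance, pr$fm_cyp2c8,
                                     pr$fm_cyp3a4, pr$fm_cyp2d6, pr$fe_renal)
  }
  if (is.null(metabolite)) {
    mr <- read_tsv_strict(path_extdata("metabolite_clearance.tsv"))
    metabolite <- metabolite_parameters(compounds$dhcq, mr$renal_clearance,
                                        mr$metabolic_clearance)
  }
  if (is.null(physiology)) physiology <- default_physiology()
  if (is.null(tissues)) tissues <- default_tissue_composition()
  opt <- list(freeze_bp_kp = FALSE, dt = 1,
              dhcq_renal_plasma_referenced = FALSE)
  unknown <- setdiff(names(options), names(opt))
  if (length(unknown))
    stop("unknown model option(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  opt[names(options)] <- options
  structure(list(compounds = compounds, partition = partition,
                 metabolite = metabolite, physiology = physiology,
                 tissues = tissues, options = opt),
            class = "model_params")
}

#' Convert a labeled product dose to base-equivalent dose
#'
#' Oral HCQ is dosed as the sulfate salt; 1 mg labeled product contains
#' `salt_factor` mg HCQ base (0.775 for the sulfate).
#'
#' @param amount_mg_labeled labeled dose, mg (>= 0).
#' @param salt_factor mg base per mg labeled product.
#' @return Base-equivalent dose, mg.
#' @export
#' @examples
#' labeled_to_base_dose(400, 0.775) # the 310 mg base i.v. dose
labeled_to_base_dose <- function(amount_mg_labeled, salt_factor) {
  if (any(amount_mg_labeled < 0))
    stop("dose amount must be >= 0", call. = FALSE)
  amount_mg_labeled * salt_factor
}
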