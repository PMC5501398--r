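# Configurable physical constants and published reference values.

#' Speciation constants for the assay-mix equilibria
#'
#' Bundles the constants the speciation operations use: the acid
#' dissociation pK of the phosphoenolpyruvate enol phosphate (the
#' PEP(2-)/PEP(3-) couple), the dissociation constants of the 1:1
#' ADP-metal complexes, and the charge table for ionic-strength sums.
#'
#' The ADP-Mg and ADP-Mn dissociation constants are configurable
#' defaults appropriate near 0.1-0.3 M ionic strength, not measured
#' values of this package; any analysis that depends on them should
#' state the constant used.
#'
#' @param pk_pep acid pK of PEP (dimensionless), default 6.3.
#' @param kd_adp_mg dissociation constant of ADP-Mg, mM.
#' @param kd_adp_mn dissociation constant of ADP-Mn, mM.
#' @param charge_table named integer vector mapping species to charge.
#' @param include_substrate_counterions logical; if `TRUE`,
#'   [speciate()] adds monovalent counter-ions for the PEP and ADP
#'   salts to the ionic-strength sum. Buffer and NADH are always
#'   excluded.
#' @return object of class `speciation_constants`.
#' @export
speciation_constants <- function(pk_pep = 6.3,
                                 kd_adp_mg = 0.38,
                                 kd_adp_mn = 0.10,
                                 charge_table = default_charge_table(),
                                 include_substrate_counterions = FALSE) {
  if (pk_pep <= 4 || pk_pep >= 8)
    stop("pk_pep must lie in (4, 8)", call. = FALSE)
  .check_pos(kd_adp_mg, "kd_adp_mg")
  .check_pos(kd_adp_mn, "kd_adp_mn")
  structure(
    list(pk_pep = pk_pep, kd_adp_mg = kd_adp_mg, kd_adp_mn = kd_adp_mn,
         charge_table = charge_table,
         include_substrate_counterions = include_substrate_counterions),
    class = "speciation_constants")
}

#' Default charge table for ionic-strength calculations
#'
#' @return named numeric vector, species name to formal charge.
#' @export
default_charge_table <- function() {
  c(K = 1, Na = 1, Li = 1, Rb = 1, Cs = 1, NH4 = 1, TMA = 1,
    Cl = -1, Mg = 2, Mn = 2,
    PEP3 = -3, PEP_H = -2, ADP_free = -3, ADP_metal = -1,
    oxalate = -2)
}

#' Molar absorptivity of NAD(P)H at 340 nm
#'
#' Standard value used by the coupled-assay quantification, in
#' mM^-1 cm^-1. Configurable at every call site that uses it.
#' @export
epsilon_nadh_340 <- 6.22

#' Monovalent-cation concentration series of the activation assays
#'
#' The K+ (and other monovalent cation) concentration series used for
#' the saturation curves of the K+-dependent isozyme, mM.
#' @return numeric vector, mM.
#' @export
default_cation_series <- function() c(1, 2.5, 5, 10, 20, 50, 100)

#' Substrate grids of the initial-velocity experiments
#'
#' The PEP(3-) and ADP-metal concentration series used for the
#' initial-velocity grids of the two V. cholerae pyruvate kinase
#' isozymes: the Mg design (type I enzyme, ADP-Mg varied against
#' PEP(3-)) and the Mn design (type II enzyme, ADP-Mn).
#'
#' @param metal `"Mg"` or `"Mn"`.
#' @return list with numeric vectors `pep3` and `adp_metal`, mM.
#' @export
default_grid_design <- function(metal = c("Mg", "Mn")) {
  metal <- match.arg(metal)
  if (metal == "Mg")
    list(pep3 = c(0.06, 0.16, 0.28, 0.4, 1.21),
         adp_metal = c(0.15, 0.3, 0.6, 0.75, 1.5))
  else
    list(pep3 = c(0.0408, 0.061, 0.097, 0.28, 0.81),
         adp_metal = c(0.025, 0.04, 0.06, 0.275, 1.3))
}

#' Published kinetic parameters of the V. cholerae pyruvate kinases
#'
#' Reference parameter values reported for the two isozymes (VcIPK,
#' the K+-dependent enzyme, and VcIIPK, the K+-independent,
#' Rib 5-P-activated enzyme), used as generator truths for scaled
#' reproductions of the original experimental designs.
#'
#' @return nested list: `monovalent` (Hill parameters per cation for
#'   VcIPK, kcat s^-1), `bisubstrate` (per enzyme: Vmax in
#'   umol min^-1 mg^-1, Km for PEP(3-) and ADP-metal in mM, monomer
#'   mass in Da), `inhibition` (dead-end inhibition constants and
#'   pattern calls), and `activation` (basal and activated specific
#'   activities, umol min^-1 mg^-1).
#' @export
vcpk_reference_params <- function() {
  list(
    monovalent = list(
      K   = list(k_half = 8.5,  kcat = 1361, n = 1.1),
      Rb  = list(k_half = 5.9,  kcat = 1067, n = 1.4),
      NH4 = list(k_half = 2.7,  kcat = 723,  n = 1.3),
      Cs  = list(k_half = 13.5, kcat = 515,  n = 1.6)),
    bisubstrate = list(
      VcIPK  = list(vmax = 476, ka = 0.3,  kb = 0.5,  metal = "Mg",
                    monomer_da = 53138, n_subunits = 4),
      VcIIPK = list(vmax = 147, ka = 0.06, kb = 0.13, metal = "Mn",
                    monomer_da = 54914, n_subunits = 4)),
    inhibition = list(
      VcIPK  = list(ki_oxalate_uM = 7.8, ki_adpcr_mM = 1.1,
                    oxalate_vs_A = "C", oxalate_vs_B = "MT_alpha_lt_1",
                    adpcr_vs_A = "NC", adpcr_vs_B = "C"),
      VcIIPK = list(ki_oxalate_uM = 71, ki_adpcr_mM = 1.3,
                    oxalate_vs_A = "C", oxalate_vs_B = "MT_alpha_lt_1",
                    adpcr_vs_A = "MT_alpha_gt_1", adpcr_vs_B = "C")),
    activation = list(
      VcIPK_fbp  = list(basal = 9,   activated = 279),
      VcIIPK_r5p = list(basal = 1.5, activated = 300),
      VcIIPK_g6p = list(basal = 1.5, activated = 239)),
    hill_pep = list(
      # K0.5 (mM), kcat (s^-1), n for PEP(3-) saturation of VcIPK,
      # without and with 5 mM effector; Mg and Mn assay media
      VcIPK_mg = list(none = list(k_half = 1.7, kcat = 1114, n = 3.7),
                      eff5 = list(k_half = 0.3, kcat = 1402, n = 1.0)),
      VcIPK_mn = list(none = list(k_half = 2.8, kcat = 778, n = 3.1),
                      eff5 = list(k_half = 0.4, kcat = 740, n = 1.5))))
}
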