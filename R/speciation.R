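# Assay-mix speciation: totals -> free species and back.
#
# The rate laws take free-species concentrations (PEP3-, ADP-metal,
# free divalent cation); the bench works in pipetted totals. These
# operations convert in both directions under a single-equilibrium
# model: acid-base ionization of PEP (Henderson-Hasselbalch) and 1:1
# mass-action complexation of ADP with the divalent metal. PEP-metal
# and PEP-K+ binding are deliberately ignored.

#' Describe the total composition of one reaction mix
#'
#' @param pep_total total phosphoenolpyruvate, mM.
#' @param adp_total total ADP, mM.
#' @param metal_identity `"Mg"` or `"Mn"`.
#' @param metal_total total divalent metal, mM.
#' @param monovalent named numeric vector of monovalent cation
#'   concentrations (mM), e.g. `c(K = 90)`. Assumed added as
#'   chloride salts.
#' @param effector optional `list(name =, mM =)`.
#' @param ph assay pH, must lie in (5, 9).
#' @param tmacl tetramethylammonium chloride, mM.
#' @param temperature_c assay temperature, degrees C.
#' @return object of class `assay_composition`.
#' @export
assay_composition <- function(pep_total = 0, adp_total = 0,
                              metal_identity = c("Mg", "Mn"),
                              metal_total = 0,
                              monovalent = c(K = 0),
                              effector = NULL,
                              ph = 7.0, tmacl = 0,
                              temperature_c = 25) {
  metal_identity <- match.arg(metal_identity)
  .check_nonneg(c(pep_total, adp_total, metal_total, tmacl,
                  unname(monovalent)), "concentrations")
  if (ph <= 5 || ph >= 9) stop("ph must lie in (5, 9)", call. = FALSE)
  if (!is.null(effector) &&
      (is.null(effector$name) || is.null(effector$mM)))
    stop("effector must be list(name =, mM =)", call. = FALSE)
  structure(list(pep_total = pep_total, adp_total = adp_total,
                 metal_identity = metal_identity,
                 metal_total = metal_total, monovalent = monovalent,
                 effector = effector, ph = ph, tmacl = tmacl,
                 temperature_c = temperature_c),
            class = "assay_composition")
}

#' Ionize PEP by the Henderson-Hasselbalch relation
#'
#' Partitions total phosphoenolpyruvate between the fully ionized
#' PEP(3-) form (the substrate species) and the protonated form, at
#' the given pH, for a single ionization with the given pK.
#'
#' @param pep_total total PEP, mM (vectorized).
#' @param ph assay pH.
#' @param pk acid pK of the relevant ionization (default 6.3).
#' @return list with `pep3` and `pep_protonated`, mM.
#' @export
ionize_pep <- function(pep_total, ph, pk = 6.3) {
  .check_nonneg(pep_total, "pep_total")
  frac <- 1 / (1 + 10^(pk - ph))
  list(pep3 = pep_total * frac, pep_protonated = pep_total * (1 - frac))
}

#' Speciate ADP and a divalent metal into the 1:1 complex
#'
#' Solves the mass-action equilibrium `ADP + M <-> ADP-M` with
#' dissociation constant `kd` for total ADP `adp_total` and total
#' metal `metal_total`. The complex concentration is the physically
#' valid (smaller) root of
#' `x^2 - (A0 + M0 + Kd) x + A0 M0 = 0`, evaluated in the
#' cancellation-free form `2 A0 M0 / (S + sqrt(S^2 - 4 A0 M0))`.
#'
#' @param adp_total,metal_total totals, mM (vectorized).
#' @param kd dissociation constant, mM, `> 0`.
#' @return list with `complex`, `metal_free`, `adp_free`, mM.
#' @export
complex_metal_adp <- function(adp_total, metal_total, kd) {
  .check_nonneg(adp_total, "adp_total")
  .check_nonneg(metal_total, "metal_total")
  .check_pos(kd, "kd")
  s <- adp_total + metal_total + kd
  disc <- s^2 - 4 * adp_total * metal_total
  disc[disc < 0] <- 0                     # numerical guard
  cplx <- 2 * adp_total * metal_total / (s + sqrt(disc))
  cplx <- pmin(cplx, adp_total, metal_total)
  list(complex = cplx,
       metal_free = metal_total - cplx,
       adp_free = adp_total - cplx)
}

#' Invert speciation: totals that realize target free species
#'
#' Experiments are reported at target free-species values (ADP-metal
#' complex and free metal); this computes the pipettable totals that
#' produce them, by algebraic inversion of the 1:1 binding
#' equilibrium.
#'
#' @param target_complex target ADP-metal complex, mM.
#' @param target_metal_free target free metal, mM.
#' @param kd dissociation constant, mM.
#' @return list with `adp_total` and `metal_total`, mM.
#' @export
compose_for_targets <- function(target_complex, target_metal_free, kd) {
  .check_nonneg(target_complex, "target_complex")
  .check_nonneg(target_metal_free, "target_metal_free")
  .check_pos(kd, "kd")
  if (any(target_metal_free == 0 & target_complex > 0))
    stop("target_metal_free = 0 with a nonzero complex is infeasible ",
         "(unbounded ADP required)", call. = FALSE)
  adp_free <- ifelse(target_complex == 0, 0,
                     kd * target_complex / target_metal_free)
  list(adp_total = target_complex + adp_free,
       metal_total = target_complex + target_metal_free)
}

#' Ionic strength of a set of charged species
#'
#' `mu = 1/2 * sum(c_i * z_i^2)` over every species in `conc`. Every
#' species name must appear in the charge table; an unknown species is
#' an error naming it, never silently dropped.
#'
#' @param conc named numeric vector of species concentrations, mM.
#' @param charges named charge table, see [default_charge_table()].
#' @return ionic strength, mM.
#' @export
ionic_strength <- function(conc, charges = default_charge_table()) {
  .check_nonneg(unname(conc), "conc")
  missing <- setdiff(names(conc), names(charges))
  if (length(missing))
    stop("species missing from charge table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  z <- charges[names(conc)]
  sum(conc * z^2) / 2
}

#' TMACl needed to reach a target ionic strength
#'
#' Tetramethylammonium chloride is a kinetically inert 1:1 salt; at
#' concentration c it contributes c to the ionic strength, so the
#' make-up amount is simply the deficit.
#'
#' @param current_mu ionic strength of the mix before TMACl, mM.
#' @param target_mu target ionic strength, mM.
#' @return TMACl concentration, mM.
#' @export
balance_ionic_strength <- function(current_mu, target_mu) {
  .check_nonneg(current_mu, "current_mu")
  .check_nonneg(target_mu, "target_mu")
  if (current_mu > target_mu)
    stop(sprintf(
      "ionic strength already exceeds target by %.6g mM",
      current_mu - target_mu), call. = FALSE)
  target_mu - current_mu
}

#' Full speciation of an assay composition
#'
#' Applies [ionize_pep()] and [complex_metal_adp()] to a composition
#' and computes the ionic strength of the resulting species mix.
#' Monovalent cations and the divalent metal are assumed added as
#' chloride salts; TMACl contributes both ions; PEP/ADP counter-ions
#' are included only when the constants object says so; buffer and
#' NADH are excluded.
#'
#' @param composition an [assay_composition()].
#' @param constants a [speciation_constants()].
#' @return object of class `speciated_state` with fields `pep3`,
#'   `pep_protonated`, `adp_metal_complex`, `metal_free`, `adp_free`,
#'   `ionic_strength` (all mM).
#' @export
speciate <- function(composition, constants = speciation_constants()) {
  stopifnot(inherits(composition, "assay_composition"),
            inherits(constants, "speciation_constants"))
  pep <- ionize_pep(composition$pep_total, composition$ph,
                    constants$pk_pep)
  kd <- switch(composition$metal_identity,
               Mg = constants$kd_adp_mg, Mn = constants$kd_adp_mn)
  cm <- complex_metal_adp(composition$adp_total,
                          composition$metal_total, kd)

  mono <- composition$monovalent
  mono <- mono[mono > 0]
  cl <- sum(mono) + composition$tmacl + 2 * composition$metal_total
  species <- c(mono,
               TMA = composition$tmacl,
               Cl = cl,
               PEP3 = pep$pep3, PEP_H = pep$pep_protonated,
               ADP_free = cm$adp_free, ADP_metal = cm$complex)
  species[composition$metal_identity] <- cm$metal_free
  if (isTRUE(constants$include_substrate_counterions))
    species["Na"] <- sum(species["Na"], 3 * composition$pep_total,
                         3 * composition$adp_total, na.rm = TRUE)
  species <- species[species > 0]
  mu <- ionic_strength(species, constants$charge_table)

  structure(list(pep3 = pep$pep3, pep_protonated = pep$pep_protonated,
                 adp_metal_complex = cm$complex,
                 metal_free = cm$metal_free, adp_free = cm$adp_free,
                 ionic_strength = mu),
            class = "speciated_state")
}

#' @export
print.speciated_state <- function(x, ...) {
  cat("Speciated assay mix (mM):\n")
  v <- unlist(x)
  for (nm in names(v)) cat(sprintf("  %-18s %g\n", nm, v[[nm]]))
  invisible(x)
}
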