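# Closed-form initial-velocity equations.
#
# Velocity units are carried as a tag on each parameter object:
# "umol_min_mg" (specific activity) or "per_s" (turnover). Functions
# that combine a dataset with parameters check tags and refuse to mix
# them silently.

.velocity_units <- c("umol_min_mg", "per_s")

.check_unit <- function(unit) {
  if (!unit %in% .velocity_units)
    stop("unknown velocity unit tag: ", unit, call. = FALSE)
  unit
}

#' Hill saturation parameters
#'
#' @param vmax limiting velocity (in `unit`).
#' @param k_half half-saturating ligand concentration K0.5, mM.
#' @param n Hill number (dimensionless, > 0).
#' @param unit velocity unit tag, `"umol_min_mg"` or `"per_s"`.
#' @export
hill_params <- function(vmax, k_half, n = 1, unit = "umol_min_mg") {
  .check_pos(vmax, "vmax"); .check_pos(k_half, "k_half")
  .check_pos(n, "n"); .check_unit(unit)
  structure(list(vmax = vmax, k_half = k_half, n = n, unit = unit),
            class = "hill_params")
}

#' Rapid-equilibrium random-order bisubstrate parameters
#'
#' A is PEP(3-), B the ADP-metal complex, by the convention used
#' throughout the package.
#'
#' @param vmax limiting velocity.
#' @param ka,kb Michaelis constants for A and B, mM.
#' @inheritParams hill_params
#' @export
bisubstrate_params <- function(vmax, ka, kb, unit = "umol_min_mg") {
  .check_pos(vmax, "vmax"); .check_pos(ka, "ka"); .check_pos(kb, "kb")
  .check_unit(unit)
  structure(list(vmax = vmax, ka = ka, kb = kb, unit = unit),
            class = "bisubstrate_params")
}

#' Linear dead-end inhibition parameters
#'
#' One evaluator covers the three linear modes. Competitive (C)
#' inhibition touches only the slope term, which is the alpha -> Inf
#' limit of the mixed-type equation; noncompetitive (NC) is mixed
#' type with alpha = 1; mixed type (MT) carries a free alpha. The
#' convention for alpha follows the dead-end analysis of the V.
#' cholerae isozymes: alpha < 1 means the enzyme-inhibitor binary
#' complex binds the other substrate more tightly than free enzyme.
#'
#' @param vmax limiting velocity.
#' @param km Michaelis constant of the varied substrate, mM.
#' @param ki inhibition constant, in `ki_unit`.
#' @param mode `"C"`, `"NC"` or `"MT"`.
#' @param alpha interaction factor, only free for mode `"MT"`.
#' @param ki_unit unit tag of `ki` (`"mM"` or `"uM"`); inhibitor
#'   concentrations handed to the evaluator must carry the same unit.
#' @inheritParams hill_params
#' @export
inhibition_params <- function(vmax, km, ki, mode = c("C", "NC", "MT"),
                              alpha = NULL, ki_unit = "mM",
                              unit = "umol_min_mg") {
  mode <- match.arg(mode)
  .check_pos(vmax, "vmax"); .check_pos(km, "km"); .check_pos(ki, "ki")
  .check_unit(unit)
  if (!ki_unit %in% c("mM", "uM"))
    stop("ki_unit must be 'mM' or 'uM'", call. = FALSE)
  alpha <- switch(mode,
    C = Inf,
    NC = 1,
    MT = { if (is.null(alpha)) stop("mode MT needs alpha", call. = FALSE)
           .check_pos(alpha, "alpha"); alpha })
  structure(list(vmax = vmax, km = km, ki = ki, alpha = alpha,
                 mode = mode, ki_unit = ki_unit, unit = unit),
            class = "inhibition_params")
}

#' Hyperbolic monovalent-cation activation parameters
#'
#' Type Ib activation: the cation is catalytically essential and the
#' turnover rises hyperbolically with its concentration from `basal`
#' (default 0) to `kcat_max`.
#'
#' @param kcat_max limiting turnover, s^-1.
#' @param k_act half-saturating activator concentration, mM.
#' @param basal turnover at zero activator, s^-1 (>= 0).
#' @export
activation_params <- function(kcat_max, k_act, basal = 0) {
  .check_pos(kcat_max, "kcat_max"); .check_pos(k_act, "k_act")
  .check_nonneg(basal, "basal")
  structure(list(kcat_max = kcat_max, k_act = k_act, basal = basal,
                 unit = "per_s"),
            class = "activation_params")
}

#' Hill-equation velocity
#'
#' `v = vmax * s^n / (k_half^n + s^n)`.
#'
#' @param s ligand concentration, mM (vectorized, >= 0).
#' @param p a [hill_params()].
#' @return velocity in the unit of `p`.
#' @export
hill_velocity <- function(s, p) {
  stopifnot(inherits(p, "hill_params"))
  .check_nonneg(s, "s")
  sn <- s^p$n
  p$vmax * sn / (p$k_half^p$n + sn)
}

#' Rapid-equilibrium random-order bisubstrate velocity
#'
#' `v = vmax * a * b / (ka*kb + ka*b + kb*a + a*b)`.
#'
#' @param a PEP(3-) concentration, mM (vectorized).
#' @param b ADP-metal concentration, mM (vectorized).
#' @param p a [bisubstrate_params()].
#' @export
random_bi_velocity <- function(a, b, p) {
  stopifnot(inherits(p, "bisubstrate_params"))
  .check_nonneg(a, "a"); .check_nonneg(b, "b")
  p$vmax * a * b / (p$ka * p$kb + p$ka * b + p$kb * a + a * b)
}

#' Linear dead-end inhibition velocity
#'
#' `v = vmax * s / (km * (1 + i/ki) + s * (1 + i/(alpha*ki)))`, the
#' mixed-type form; competitive mode has alpha = Inf (no intercept
#' effect) and noncompetitive alpha = 1.
#'
#' @param s varied-substrate concentration, mM (vectorized).
#' @param i inhibitor concentration, in `i_unit` (vectorized).
#' @param p an [inhibition_params()].
#' @param i_unit unit of `i`; must match `p$ki_unit`.
#' @export
inhibited_velocity <- function(s, i, p, i_unit = p$ki_unit) {
  stopifnot(inherits(p, "inhibition_params"))
  .check_nonneg(s, "s"); .check_nonneg(i, "i")
  if (!identical(i_unit, p$ki_unit))
    stop(sprintf("inhibitor unit '%s' does not match ki unit '%s'",
                 i_unit, p$ki_unit), call. = FALSE)
  p$vmax * s / (p$km * (1 + i / p$ki) + s * (1 + i / (p$alpha * p$ki)))
}

#' Hyperbolic monovalent-cation activation
#'
#' `kcat(m) = basal + (kcat_max - basal) * m / (k_act + m)`.
#'
#' @param m activator concentration, mM (vectorized).
#' @param p an [activation_params()].
#' @return turnover, s^-1.
#' @export
activation_velocity <- function(m, p) {
  stopifnot(inherits(p, "activation_params"))
  .check_nonneg(m, "m")
  p$basal + (p$kcat_max - p$basal) * m / (p$k_act + m)
}

# JSON (de)serialization of parameter objects -------------------------

#' Write / read rate-law parameters as JSON
#'
#' Parameter files are flat JSON objects tagged with the parameter
#' class, so generator truths and fitted values travel between
#' sessions losslessly.
#'
#' @param p a parameter object (`hill_params`, `bisubstrate_params`,
#'   `inhibition_params` or `activation_params`).
#' @param path file path.
#' @export
write_params_json <- function(p, path) {
  stopifnot(inherits(p, c("hill_params", "bisubstrate_params",
                          "inhibition_params", "activation_params")))
  obj <- unclass(p)
  obj$.class <- class(p)[1]
  if (identical(obj$alpha, Inf)) obj$alpha <- "Inf"
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- obj$.class
  switch(cls,
    hill_params = hill_params(obj$vmax, obj$k_half, obj$n, obj$unit),
    bisubstrate_params =
      bisubstrate_params(obj$vmax, obj$ka, obj$kb, obj$unit),
    inhibition_params =
      inhibition_params(obj$vmax, obj$km, obj$ki, obj$mode,
                        alpha = if (obj$mode == "MT") obj$alpha,
                        ki_unit = obj$ki_unit, unit = obj$unit),
    activation_params =
      activation_params(obj$kcat_max, obj$k_act, obj$basal),
    stop("unknown parameter class in file: ", cls, call. = FALSE))
}
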