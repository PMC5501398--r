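# Nonlinear least-squares estimation of the rate-law parameters.
#
# All fits share one engine: Levenberg-Marquardt (minpack.lm::nls.lm)
# on log-transformed parameters (every kinetic parameter is positive,
# so the log scale enforces the bound without constrained
# optimization), with five multi-starts log-spaced around data-driven
# heuristics. Standard errors are asymptotic, from a numerical
# Jacobian of the residuals at the optimum; they are computed on the
# log scale and mapped back by the delta method, and confidence
# intervals are built on the log scale (so they respect positivity).

.lm_multistart <- function(resid_fn, start, spread_par = names(start),
                           n_starts = 5) {
  factors <- 10^seq(-1, 1, length.out = n_starts)
  best <- NULL
  for (f in factors) {
    st <- start
    st[spread_par] <- st[spread_par] * f
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = log(st), fn = resid_fn,
        control = minpack.lm::nls.lm.control(
          maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) {
      best <- fit
      best$start_used <- st
    }
  }
  best
}

# central-difference Jacobian of resid_fn w.r.t. log-parameters
.num_jacobian <- function(resid_fn, logpar, h = 1e-6) {
  r0 <- resid_fn(logpar)
  J <- matrix(NA_real_, length(r0), length(logpar))
  for (j in seq_along(logpar)) {
    up <- dn <- logpar
    up[j] <- up[j] + h; dn[j] <- dn[j] - h
    J[, j] <- (resid_fn(up) - resid_fn(dn)) / (2 * h)
  }
  J
}

.fit_result <- function(model, fit, resid_fn, n_points, unit,
                        extra = list()) {
  est <- exp(fit$par)
  converged <- fit$info %in% 1:4
  p <- length(est)
  rss <- fit$deviance
  se <- se_log <- setNames(rep(NA_real_, p), names(est))
  if (converged && n_points > p) {
    J <- .num_jacobian(resid_fn, fit$par)
    sigma2 <- rss / (n_points - p)
    vc <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) NULL)
    if (!is.null(vc)) {
      se_log <- setNames(sqrt(pmax(diag(vc), 0)), names(est))
      se <- est * se_log               # delta method
    }
  }
  structure(list(model = model, estimates = est,
                 std_errors = if (converged) se else NULL,
                 se_log = if (converged) se_log else NULL,
                 rss = rss, n_points = n_points,
                 converged = converged, start = fit$start_used,
                 unit = unit, extra = extra),
            class = "kin_fit")
}

#' @export
print.kin_fit <- function(x, ...) {
  cat(sprintf("Nonlinear fit: %s model, %d points, rss = %.4g%s\n",
              x$model, x$n_points, x$rss,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  tab <- data.frame(estimate = x$estimates,
                    std_error = if (is.null(x$std_errors))
                      NA_real_ else x$std_errors)
  print(signif(tab, 5))
  invisible(x)
}

#' Wald confidence intervals for a fit
#'
#' Intervals are computed on the log-parameter scale (the scale of
#' the optimization) and exponentiated, so they are positive and
#' asymmetric like the sampling distribution of a positive parameter.
#'
#' @param fit a `kin_fit`.
#' @param level confidence level.
#' @return matrix with columns `lower`, `upper`.
#' @export
confint_kin_fit <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "kin_fit"))
  if (is.null(fit$se_log)) stop("fit did not converge", call. = FALSE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  lp <- log(fit$estimates)
  cbind(lower = exp(lp - z * fit$se_log),
        upper = exp(lp + z * fit$se_log))
}

.get_velocity <- function(ds) ds$velocity

.residual_maker <- function(predict_fn, v, weighting) {
  if (weighting == "relative")
    function(lp) { vh <- predict_fn(exp(lp)); (v - vh) / pmax(vh, 1e-12) }
  else
    function(lp) v - predict_fn(exp(lp))
}

#' Fit the Hill equation to a saturation curve
#'
#' Estimates `(vmax, k_half, n)` by multi-start Levenberg-Marquardt
#' least squares. Starting heuristics: `vmax` at 1.1 x max observed
#' velocity, `k_half` at the concentration nearest half of the
#' maximal observed velocity, `n` at 1; five starts log-spaced around
#' the `k_half` heuristic.
#'
#' @param ds a [velocity_dataset()] whose varied-species column holds
#'   the ligand concentration. At least 4 points are required.
#' @param start optional [hill_params()] used as the single start.
#' @param weighting `"none"` (default) or `"relative"`.
#' @return a `kin_fit` with estimates `vmax`, `k_half`, `n`.
#' @export
fit_hill <- function(ds, start = NULL,
                     weighting = c("none", "relative")) {
  stopifnot(inherits(ds, "velocity_dataset"))
  weighting <- match.arg(weighting)
  s <- .ds_conc(ds, attr(ds, "varied_species"))
  v <- .get_velocity(ds)
  if (length(v) < 4)
    stop("Hill fit is under-determined with fewer than 4 points",
         call. = FALSE)
  predict_fn <- function(p) p[1] * s^p[3] / (p[2]^p[3] + s^p[3])
  resid_fn <- .residual_maker(predict_fn, v, weighting)
  if (is.null(start)) {
    vmax0 <- 1.1 * max(v)
    k0 <- s[which.min(abs(v - max(v) / 2))]
    if (k0 <= 0) k0 <- median(s[s > 0])
    st <- c(vmax = vmax0, k_half = k0, n = 1)
    fit <- .lm_multistart(resid_fn, st, spread_par = "k_half")
  } else {
    st <- c(vmax = start$vmax, k_half = start$k_half, n = start$n)
    fit <- .lm_multistart(resid_fn, st, n_starts = 1)
  }
  if (is.null(fit))
    return(structure(list(model = "hill", estimates = NULL,
                          converged = FALSE, rss = NA_real_,
                          n_points = length(v)),
                     class = "kin_fit"))
  .fit_result("hill", fit, resid_fn, length(v),
              attr(ds, "velocity_unit"))
}

#' Global fit of the rapid-equilibrium random-order bisubstrate law
#'
#' Fits one `(vmax, ka, kb)` triple jointly to every point of an
#' A x B initial-velocity grid (A = PEP(3-), B = ADP-metal, taken
#' from the first two `conc_` columns in that order).
#'
#' @param ds a [velocity_dataset()] with two `conc_` columns and at
#'   least 6 points spanning >= 2 distinct levels of each substrate.
#' @inheritParams fit_hill
#' @return a `kin_fit` with estimates `vmax`, `ka`, `kb`.
#' @export
fit_bisubstrate_global <- function(ds, start = NULL,
                                   weighting = c("none", "relative")) {
  stopifnot(inherits(ds, "velocity_dataset"))
  weighting <- match.arg(weighting)
  sp <- dataset_species(ds)
  if (length(sp) < 2)
    stop("bisubstrate fit needs two conc_ columns", call. = FALSE)
  a <- .ds_conc(ds, sp[1]); b <- .ds_conc(ds, sp[2])
  v <- .get_velocity(ds)
  if (length(unique(a)) < 2 || length(unique(b)) < 2)
    stop("rank-deficient design: need >= 2 distinct levels of each ",
         "substrate", call. = FALSE)
  if (length(v) < 6)
    stop("global bisubstrate fit needs >= 6 points", call. = FALSE)
  predict_fn <- function(p)
    p[1] * a * b / (p[2] * p[3] + p[2] * b + p[3] * a + a * b)
  resid_fn <- .residual_maker(predict_fn, v, weighting)
  if (is.null(start)) {
    st <- c(vmax = 1.1 * max(v), ka = median(a[a > 0]),
            kb = median(b[b > 0]))
    fit <- .lm_multistart(resid_fn, st, spread_par = c("ka", "kb"))
  } else {
    st <- c(vmax = start$vmax, ka = start$ka, kb = start$kb)
    fit <- .lm_multistart(resid_fn, st, n_starts = 1)
  }
  .fit_result("random_bi", fit, resid_fn, length(v),
              attr(ds, "velocity_unit"))
}

#' Global fit of a linear dead-end inhibition model
#'
#' Fits `(vmax, km, ki)` (plus `alpha` for mixed type) jointly to all
#' substrate x inhibitor series, using the single mixed-type
#' evaluator with alpha fixed at Inf (competitive) or 1
#' (noncompetitive) or free (mixed).
#'
#' @param ds a [velocity_dataset()] with the varied-substrate
#'   `conc_` column and an `inhibitor_conc` column (in the dataset's
#'   `inhibitor_unit`). At least 3 inhibitor levels are required; a
#'   missing zero-inhibitor series triggers a warning (the fit is
#'   weakly anchored), not an error.
#' @param mode `"C"`, `"NC"` or `"MT"`.
#' @inheritParams fit_hill
#' @return a `kin_fit`; `ki` is reported in the dataset's inhibitor
#'   unit (`fit$extra$ki_unit`).
#' @export
fit_inhibition_global <- function(ds, mode = c("C", "NC", "MT"),
                                  start = NULL,
                                  weighting = c("none", "relative")) {
  stopifnot(inherits(ds, "velocity_dataset"))
  mode <- match.arg(mode)
  weighting <- match.arg(weighting)
  if (!"inhibitor_conc" %in% names(ds))
    stop("dataset has no inhibitor_conc column", call. = FALSE)
  s <- .ds_conc(ds, attr(ds, "varied_species"))
  i <- ds$inhibitor_conc
  v <- .get_velocity(ds)
  if (length(unique(i)) < 3)
    stop("need >= 3 inhibitor levels", call. = FALSE)
  if (!any(i == 0))
    warning("no zero-inhibitor series: Vmax and Km are weakly anchored")
  predict_fn <- switch(mode,
    C  = function(p) p[1] * s / (p[2] * (1 + i / p[3]) + s),
    NC = function(p) p[1] * s / ((p[2] + s) * (1 + i / p[3])),
    MT = function(p) p[1] * s /
           (p[2] * (1 + i / p[3]) + s * (1 + i / (p[4] * p[3]))))
  resid_fn <- .residual_maker(predict_fn, v, weighting)
  if (is.null(start)) {
    st <- c(vmax = 1.1 * max(v), km = median(s[s > 0]),
            ki = if (any(i > 0)) exp(mean(log(i[i > 0]))) else 1)
    if (mode == "MT") st <- c(st, alpha = 1)
    fit <- .lm_multistart(resid_fn, st, spread_par = c("km", "ki"))
  } else {
    st <- c(vmax = start$vmax, km = start$km, ki = start$ki)
    if (mode == "MT") st <- c(st, alpha = start$alpha)
    fit <- .lm_multistart(resid_fn, st, n_starts = 1)
  }
  .fit_result(paste0("inhibition_", mode), fit, resid_fn, length(v),
              attr(ds, "velocity_unit"),
              extra = list(mode = mode,
                           ki_unit = attr(ds, "inhibitor_unit")))
}

# Derived scalar quantities -------------------------------------------

#' Turnover number from specific activity
#'
#' Converts a limiting specific activity (umol min^-1 mg^-1) to a
#' per-oligomer turnover (s^-1): `kcat = vmax/60 * M_oligomer/1000`
#' with the oligomer mass in Da. The default oligomer is a
#' homotetramer, the convention that reproduces the published
#' turnovers of the V. cholerae isozymes from their printed specific
#' activities and monomer masses.
#'
#' @param vmax specific activity, umol min^-1 mg^-1.
#' @param monomer_mass_da monomer mass, Da.
#' @param n_subunits subunits per catalytic oligomer (default 4).
#' @return turnover, s^-1 per oligomer.
#' @export
kcat_from_vmax <- function(vmax, monomer_mass_da, n_subunits = 4) {
  .check_pos(vmax, "vmax"); .check_pos(monomer_mass_da, "monomer_mass_da")
  .check_pos(n_subunits, "n_subunits")
  vmax / 60 * (monomer_mass_da * n_subunits) / 1000
}

#' @rdname kcat_from_vmax
#' @param kcat turnover, s^-1 per oligomer.
#' @export
vmax_from_kcat <- function(kcat, monomer_mass_da, n_subunits = 4) {
  .check_pos(kcat, "kcat"); .check_pos(monomer_mass_da, "monomer_mass_da")
  kcat * 60 * 1000 / (monomer_mass_da * n_subunits)
}

#' Catalytic efficiency in log form
#'
#' `log10(kcat / Km)` with Km converted from mM to M, the form in
#' which bisubstrate efficiencies are tabulated.
#'
#' @param kcat turnover, s^-1.
#' @param km_mM Michaelis constant, mM.
#' @return log10 of kcat/Km in M^-1 s^-1.
#' @export
catalytic_efficiency <- function(kcat, km_mM) {
  .check_pos(kcat, "kcat"); .check_pos(km_mM, "km_mM")
  log10(kcat / (km_mM * 1e-3))
}

#' Activation fold and fractional basal activity
#'
#' @param basal velocity without effector.
#' @param activated velocity with effector (same unit).
#' @return list with `fold` (`activated/basal`, `NA` with a warning
#'   when basal is zero) and `percent_of_activated`
#'   (`100 * basal/activated`).
#' @export
relative_activation <- function(basal, activated) {
  .check_nonneg(basal, "basal"); .check_pos(activated, "activated")
  fold <- if (basal == 0) {
    warning("zero basal activity: fold activation undefined")
    NA_real_
  } else activated / basal
  list(fold = fold, percent_of_activated = 100 * basal / activated)
}
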