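# Cleland pattern classification and mechanism inference.
#
# Double-reciprocal (1/v vs 1/[S]) line families diagnose bireactant
# mechanisms: for the rapid-equilibrium random-order law the family
# at several fixed co-substrate levels intersects on the 1/[S] axis
# at x = -1/Ka. Dead-end inhibition patterns (competitive /
# noncompetitive / mixed) against each substrate then discriminate
# random from ordered addition.

#' Double-reciprocal line family from an initial-velocity grid
#'
#' For each level of the fixed species, fits an ordinary
#' least-squares line through (1/[varied], 1/v). Points with zero
#' velocity are excluded with a warning (their reciprocal is
#' undefined); each line must keep >= 3 points and the family >= 2
#' lines.
#'
#' @param ds a [velocity_dataset()] grid with conc columns for both
#'   species.
#' @param varied,fixed species names; default to the first and second
#'   `conc_` columns.
#' @return object of class `reciprocal_family`: data.frame with
#'   `fixed_level`, `slope`, `intercept`, `n_points`; attribute
#'   `n_dropped` counts excluded zero-velocity rows.
#' @export
reciprocal_lines <- function(ds, varied = NULL, fixed = NULL) {
  stopifnot(inherits(ds, "velocity_dataset"))
  sp <- dataset_species(ds)
  if (is.null(varied)) varied <- sp[1]
  if (is.null(fixed)) fixed <- setdiff(sp, varied)[1]
  if (is.na(fixed)) stop("need a fixed-species column", call. = FALSE)
  x <- .ds_conc(ds, varied); f <- .ds_conc(ds, fixed)
  v <- ds$velocity
  drop <- v <= 0 | x <= 0
  n_dropped <- sum(drop)
  if (n_dropped)
    warning(sprintf("%d zero-velocity/zero-concentration point(s) %s",
                    n_dropped, "excluded from reciprocal lines"))
  x <- x[!drop]; f <- f[!drop]; v <- v[!drop]
  levels <- sort(unique(f))
  if (length(levels) < 2)
    stop("need >= 2 fixed-species levels for a line family",
         call. = FALSE)
  lines <- lapply(levels, function(lv) {
    sel <- f == lv
    if (sum(sel) < 3)
      stop(sprintf("fewer than 3 points at fixed level %g", lv),
           call. = FALSE)
    co <- coef(lm(I(1 / v[sel]) ~ I(1 / x[sel])))
    data.frame(fixed_level = lv, slope = unname(co[2]),
               intercept = unname(co[1]), n_points = sum(sel))
  })
  structure(do.call(rbind, lines),
            class = c("reciprocal_family", "data.frame"),
            varied_species = varied, fixed_species = fixed,
            n_dropped = n_dropped)
}

.pattern_call <- function(category, intersection = NULL,
                          inhibition_mode = NULL, diagnostics = list()) {
  structure(list(category = category, intersection = intersection,
                 inhibition_mode = inhibition_mode,
                 diagnostics = diagnostics),
            class = "pattern_call")
}

#' @export
print.pattern_call <- function(x, ...) {
  cat("Pattern call:", x$category)
  if (!is.null(x$inhibition_mode)) cat(" /", x$inhibition_mode)
  cat("\n")
  if (!is.null(x$intersection))
    cat(sprintf("  pooled intersection (%.4g, %.4g), dispersion (%.3g, %.3g)\n",
                x$intersection["x"], x$intersection["y"],
                x$intersection["sd_x"], x$intersection["sd_y"]))
  invisible(x)
}

#' Classify a double-reciprocal line family
#'
#' Pairwise line intersections are pooled; the family is called
#' `parallel` when the relative slope spread is below `tol`,
#' `intersecting_on_1S_axis` when the pooled intersection lies left
#' of the 1/v axis with |y| within `tol` of the vertical scale
#' 1/Vmax (estimated as the smallest intercept), and above/below the
#' 1/[S] axis otherwise. Intersections more dispersed than
#' `dispersion_tol` (relative to the same scales) are reported as
#' `indeterminate` with diagnostics.
#'
#' @param fam a [reciprocal_lines()] family.
#' @param tol relative tolerance for "on the axis" and for parallel
#'   slopes (default 0.05).
#' @param dispersion_tol maximal relative dispersion of the pooled
#'   intersection (default 0.5).
#' @return a `pattern_call`.
#' @export
classify_initial_velocity <- function(fam, tol = 0.05,
                                      dispersion_tol = 0.5) {
  stopifnot(inherits(fam, "reciprocal_family"))
  m <- fam$slope; c0 <- fam$intercept
  pairs <- utils::combn(nrow(fam), 2)
  dm <- m[pairs[1, ]] - m[pairs[2, ]]
  dc <- c0[pairs[2, ]] - c0[pairs[1, ]]
  scale_m <- mean(abs(m))
  if (any(abs(dm) < 1e-12 * scale_m & abs(dc) < 1e-12 * mean(abs(c0))))
    stop("family contains (near-)identical lines", call. = FALSE)
  if ((max(m) - min(m)) / scale_m <= tol)
    return(.pattern_call("parallel",
                         diagnostics = list(slope_spread =
                           (max(m) - min(m)) / scale_m)))
  xi <- dc / dm
  yi <- m[pairs[1, ]] * xi + c0[pairs[1, ]]
  inter <- c(x = mean(xi), y = mean(yi),
             sd_x = if (length(xi) > 1) sd(xi) else 0,
             sd_y = if (length(yi) > 1) sd(yi) else 0)
  y_scale <- min(c0[c0 > 0])            # 1/Vmax estimate
  x_scale <- max(abs(xi))
  if (inter[["sd_y"]] > dispersion_tol * y_scale ||
      inter[["sd_x"]] > dispersion_tol * x_scale)
    return(.pattern_call("indeterminate", intersection = inter,
                         diagnostics = list(
                           reason = "intersections too dispersed",
                           y_scale = y_scale, x_scale = x_scale)))
  category <-
    if (abs(inter[["y"]]) <= tol * y_scale && inter[["x"]] < 0)
      "intersecting_on_1S_axis"
    else if (inter[["y"]] > 0) "intersecting_above_axis"
    else "intersecting_below_axis"
  .pattern_call(category, intersection = inter,
                diagnostics = list(left_of_1v_axis = inter[["x"]] < 0,
                                   y_scale = y_scale))
}

# corrected AIC for a least-squares fit
.aicc <- function(rss, n, p) {
  k <- p + 1
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1)
}

# slope/intercept replots vs [I] must be linear for the linear
# inhibition modes; curvature beyond tol rejects the classification
.replot_linearity <- function(ds, tol) {
  s <- .ds_conc(ds, attr(ds, "varied_species"))
  i <- ds$inhibitor_conc; v <- ds$velocity
  levels <- sort(unique(i))
  keep <- v > 0 & s > 0
  rows <- lapply(levels, function(lv) {
    sel <- keep & i == lv
    if (sum(sel) < 3) return(NULL)
    co <- coef(lm(I(1 / v[sel]) ~ I(1 / s[sel])))
    data.frame(i = lv, slope = unname(co[2]), intercept = unname(co[1]))
  })
  rep_df <- do.call(rbind, rows)
  if (is.null(rep_df) || nrow(rep_df) < 3)
    return(list(linear = TRUE, detail = "too few levels to test"))
  rel_curv <- function(y) {
    f1 <- lm(y ~ rep_df$i)
    sqrt(mean(resid(f1)^2)) / diff(range(y))
  }
  curv <- c(slope = rel_curv(rep_df$slope),
            intercept = if (diff(range(rep_df$intercept)) >
                            1e-9 * mean(abs(rep_df$intercept)))
              rel_curv(rep_df$intercept) else 0)
  list(linear = all(curv <= tol), curvature = curv, replots = rep_df)
}

#' Classify a dead-end inhibition pattern
#'
#' Fits the competitive (C), noncompetitive (NC) and mixed-type (MT)
#' linear models globally to a substrate x inhibitor grid and selects
#' among them by extra-sum-of-squares F-tests of each 3-parameter
#' model against the 4-parameter mixed model (both are nested in it),
#' with AICc reported alongside. A reduced model is adequate when the
#' F-test does not reject it at `alpha_level`, or when its fit is
#' already numerically perfect. Among adequate models the most
#' parsimonious (then lowest-RSS) wins; a mixed call is subdivided by
#' the fitted alpha against 1. Slope and intercept replots against
#' [I] must be linear (relative curvature <= `replot_tol`), otherwise
#' the classification is rejected as `non-linear replot`.
#'
#' @param ds a [velocity_dataset()] with `inhibitor_conc`, >= 3
#'   inhibitor levels.
#' @param candidates subset of `c("C", "NC", "MT")` to consider.
#' @param alpha_level F-test significance level (default 0.05).
#' @param replot_tol relative curvature tolerance for the replots.
#' @param alpha_band half-width of the alpha ~ 1 band inside which a
#'   mixed fit is reported as noncompetitive.
#' @return a `pattern_call` with `inhibition_mode` in
#'   `C, NC, MT_alpha_lt_1, MT_alpha_gt_1`; diagnostics carry the
#'   per-model RSS/F/p/AICc table and the fitted models.
#' @export
classify_inhibition <- function(ds, candidates = c("C", "NC", "MT"),
                                alpha_level = 0.05, replot_tol = 0.05,
                                alpha_band = 0.05) {
  stopifnot(inherits(ds, "velocity_dataset"))
  candidates <- match.arg(candidates, c("C", "NC", "MT"),
                          several.ok = TRUE)
  if (!"MT" %in% candidates)
    stop("the mixed-type model is needed as the full model",
         call. = FALSE)
  rl <- .replot_linearity(ds, replot_tol)
  if (!rl$linear)
    return(.pattern_call("rejected",
                         diagnostics = c(list(reason = "non-linear replot"),
                                         rl)))
  fits <- lapply(setNames(candidates, candidates),
                 function(md) fit_inhibition_global(ds, mode = md))
  v <- ds$velocity
  n <- length(v)
  tss <- sum((v - mean(v))^2)
  near_perfect <- function(rss) rss <= 1e-9 * max(tss, 1e-12)
  full <- fits[["MT"]]
  p_full <- length(full$estimates)
  sel <- data.frame(mode = candidates,
                    rss = vapply(fits, `[[`, 0, "rss"),
                    p = NA_real_, aicc = NA_real_)
  for (k in seq_along(candidates)) {
    md <- candidates[k]
    p_red <- length(fits[[md]]$estimates)
    sel$aicc[k] <- .aicc(sel$rss[k], n, p_red)
    if (md == "MT") { sel$p[k] <- 1; next }
    if (near_perfect(sel$rss[k])) { sel$p[k] <- 1; next }
    fstat <- ((sel$rss[k] - full$rss) / (p_full - p_red)) /
      (full$rss / (n - p_full))
    sel$p[k] <- if (!is.finite(fstat) || fstat < 0) 1 else
      pf(fstat, p_full - p_red, n - p_full, lower.tail = FALSE)
  }
  adequate <- sel$mode[sel$p > alpha_level | sel$mode == "MT"]
  reduced <- setdiff(adequate, "MT")
  chosen <- if (length(reduced)) {
    rr <- sel[sel$mode %in% reduced, ]
    rr$mode[which.min(rr$rss)]
  } else "MT"
  mode_call <- chosen
  if (chosen == "MT") {
    alpha_hat <- full$estimates[["alpha"]]
    mode_call <- if (abs(alpha_hat - 1) <= alpha_band) "NC"
      else if (alpha_hat < 1) "MT_alpha_lt_1" else "MT_alpha_gt_1"
  }
  .pattern_call("inhibition", inhibition_mode = mode_call,
                diagnostics = list(selection = sel, fits = fits,
                                   replots = rl$replots))
}

.norm_mode <- function(x) {
  if (inherits(x, "pattern_call")) x <- x$inhibition_mode
  if (is.null(x)) return(NA_character_)
  if (x %in% c("MT_alpha_lt_1", "MT_alpha_gt_1")) "MT" else x
}

#' Infer the bireactant kinetic mechanism from pattern evidence
#'
#' Applies the dead-end inference rules: with an intersecting
#' initial-velocity family, each dead-end analog competitive against
#' its own substrate and noncompetitive or mixed against the other
#' substrate (for both analogs) identifies the rapid-equilibrium
#' random-order mechanism; an analog competitive against both
#' substrates identifies ordered addition with its substrate first;
#' anything else is indeterminate, with the conflicts listed.
#' Intersecting initial-velocity patterns alone cannot separate
#' ordered steady-state from random rapid-equilibrium addition, so a
#' definite label always requires the dead-end evidence.
#'
#' @param evidence list with `initial_velocity` (a `pattern_call` or
#'   category string) and any of `oxalate_vs_A`, `oxalate_vs_B`,
#'   `adpcr_vs_A`, `adpcr_vs_B` (pattern calls or mode strings);
#'   oxalate is the dead-end analog of A = PEP(3-), Cr-ADP of
#'   B = ADP-metal.
#' @return object of class `mechanism_call`: `label` in
#'   `rapid_equilibrium_random, ordered_A_first, ordered_B_first,
#'   indeterminate`, plus the evidence and rule notes.
#' @export
infer_mechanism <- function(evidence) {
  iv <- evidence$initial_velocity
  if (is.null(iv)) stop("initial-velocity call required", call. = FALSE)
  iv_cat <- if (inherits(iv, "pattern_call")) iv$category else iv
  iv_intersecting <- grepl("^intersecting", iv_cat)
  ox_a <- .norm_mode(evidence$oxalate_vs_A)
  ox_b <- .norm_mode(evidence$oxalate_vs_B)
  cr_a <- .norm_mode(evidence$adpcr_vs_A)
  cr_b <- .norm_mode(evidence$adpcr_vs_B)
  have_ox <- !is.na(ox_a) && !is.na(ox_b)
  have_cr <- !is.na(cr_a) && !is.na(cr_b)
  if (!have_ox && !have_cr)
    return(structure(list(label = "indeterminate", evidence = evidence,
                          notes = "no complete dead-end analog evidence"),
                     class = "mechanism_call"))
  notes <- character()
  random_ok <- iv_intersecting && have_ox && have_cr &&
    ox_a == "C" && ox_b %in% c("NC", "MT") &&
    cr_b == "C" && cr_a %in% c("NC", "MT")
  ordered_a <- have_ox && ox_a == "C" && ox_b == "C"
  ordered_b <- have_cr && cr_b == "C" && cr_a == "C"
  label <- if (random_ok) "rapid_equilibrium_random"
    else if (ordered_a && !ordered_b) "ordered_A_first"
    else if (ordered_b && !ordered_a) "ordered_B_first"
    else "indeterminate"
  if (label == "indeterminate") {
    if (!iv_intersecting)
      notes <- c(notes, sprintf("initial-velocity pattern '%s' %s",
                                iv_cat, "is not intersecting"))
    if (have_ox && ox_a != "C")
      notes <- c(notes, "analog of A is not competitive vs A")
    if (have_cr && cr_b != "C")
      notes <- c(notes, "analog of B is not competitive vs B")
    if (!(have_ox && have_cr))
      notes <- c(notes, "only one analog's pattern pair present")
    if (ordered_a && ordered_b)
      notes <- c(notes, "both analogs competitive vs both substrates")
  }
  structure(list(label = label, evidence = evidence, notes = notes),
            class = "mechanism_call")
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat("Kinetic mechanism:", x$label, "\n")
  if (length(x$notes)) cat(paste0("  - ", x$notes, collapse = "\n"), "\n")
  invisible(x)
}
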