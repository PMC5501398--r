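# End-to-end characterization: speciate -> fit -> derive -> mechanism.

#' Run a full kinetic characterization from a dataset manifest
#'
#' Orchestrates the analysis stages over a manifest of datasets with
#' named roles and returns one report: Hill parameter tables for the
#' saturation curves, the global bisubstrate fit with derived
#' turnover and log catalytic efficiencies, the dead-end inhibition
#' classifications, the inferred mechanism, and activation folds.
#' Missing roles produce a partial report with the gap named in
#' `$missing`, never an error.
#'
#' @param manifest list with any of:
#'   * `saturation`: named list of [velocity_dataset()]s (one Hill
#'     fit each);
#'   * `bisubstrate`: one grid [velocity_dataset()];
#'   * `inhibition`: named list of inhibitor grids, names among
#'     `oxalate_vs_A`, `oxalate_vs_B`, `adpcr_vs_A`, `adpcr_vs_B`;
#'   * `activation`: named list of `list(basal =, activated =)`
#'     velocity pairs.
#' @param monomer_da monomer mass, Da, for turnover conversion.
#' @param n_subunits subunits per catalytic oligomer (default 4).
#' @param constants a [speciation_constants()], recorded in the
#'   report so every number is reproducible from it.
#' @return object of class `characterization_report`; `$status` is
#'   `"ok"`, `"partial"` or `"empty"`.
#' @export
run_characterization <- function(manifest, monomer_da = NULL,
                                 n_subunits = 4,
                                 constants = speciation_constants()) {
  stopifnot(is.list(manifest))
  roles <- c("saturation", "bisubstrate", "inhibition", "activation")
  present <- intersect(roles, names(manifest))
  missing <- setdiff(roles, present)
  report <- list(constants = constants, missing = missing)

  if (!length(present)) {
    report$status <- "empty"
    class(report) <- "characterization_report"
    return(report)
  }

  if ("saturation" %in% present) {
    fits <- lapply(manifest$saturation, fit_hill)
    report$saturation <- data.frame(
      dataset = names(fits),
      vmax = vapply(fits, function(f) f$estimates[["vmax"]], 0),
      k_half = vapply(fits, function(f) f$estimates[["k_half"]], 0),
      n = vapply(fits, function(f) f$estimates[["n"]], 0),
      rss = vapply(fits, `[[`, 0, "rss"),
      converged = vapply(fits, `[[`, TRUE, "converged"),
      row.names = NULL)
    report$saturation_fits <- fits
  }

  if ("bisubstrate" %in% present) {
    ds <- manifest$bisubstrate
    fit <- fit_bisubstrate_global(ds)
    block <- list(fit = fit)
    sp <- dataset_species(ds)
    fam_a <- reciprocal_lines(ds, varied = sp[1], fixed = sp[2])
    fam_b <- reciprocal_lines(ds, varied = sp[2], fixed = sp[1])
    block$pattern_vs_A <- classify_initial_velocity(fam_a)
    block$pattern_vs_B <- classify_initial_velocity(fam_b)
    if (!is.null(monomer_da)) {
      kc <- kcat_from_vmax(fit$estimates[["vmax"]], monomer_da,
                           n_subunits)
      block$kcat <- kc
      block$log_eff_A <- catalytic_efficiency(kc, fit$estimates[["ka"]])
      block$log_eff_B <- catalytic_efficiency(kc, fit$estimates[["kb"]])
    }
    report$bisubstrate <- block
  }

  if ("inhibition" %in% present) {
    report$inhibition <- lapply(manifest$inhibition, classify_inhibition)
  }

  if (!is.null(report$bisubstrate) && !is.null(report$inhibition)) {
    ev <- c(list(initial_velocity = report$bisubstrate$pattern_vs_A),
            report$inhibition)
    report$mechanism <- infer_mechanism(ev)
  }

  if ("activation" %in% present) {
    report$activation <- data.frame(
      pair = names(manifest$activation),
      fold = vapply(manifest$activation, function(p)
        relative_activation(p$basal, p$activated)$fold, 0),
      percent_of_activated = vapply(manifest$activation, function(p)
        relative_activation(p$basal, p$activated)$percent_of_activated,
        0),
      row.names = NULL)
  }

  report$status <- if (length(missing)) "partial" else "ok"
  class(report) <- "characterization_report"
  report
}

#' @export
print.characterization_report <- function(x, ...) {
  cat("Kinetic characterization report  [", x$status, "]\n", sep = "")
  if (length(x$missing))
    cat("  missing roles:", paste(x$missing, collapse = ", "), "\n")
  if (!is.null(x$saturation)) {
    cat("\nHill fits:\n")
    print(transform(x$saturation, vmax = signif(vmax, 4),
                    k_half = signif(k_half, 4), n = signif(n, 3),
                    rss = signif(rss, 3)))
  }
  if (!is.null(x$bisubstrate)) {
    est <- x$bisubstrate$fit$estimates
    cat(sprintf("\nBisubstrate global fit: Vmax %.4g, Ka %.4g mM, Kb %.4g mM\n",
                est[["vmax"]], est[["ka"]], est[["kb"]]))
    cat("  pattern vs A:", x$bisubstrate$pattern_vs_A$category, "\n")
    cat("  pattern vs B:", x$bisubstrate$pattern_vs_B$category, "\n")
    if (!is.null(x$bisubstrate$kcat))
      cat(sprintf("  kcat %.4g s^-1, log(kcat/Km) %.3f (A), %.3f (B)\n",
                  x$bisubstrate$kcat, x$bisubstrate$log_eff_A,
                  x$bisubstrate$log_eff_B))
  }
  if (!is.null(x$inhibition)) {
    cat("\nDead-end inhibition calls:\n")
    for (nm in names(x$inhibition))
      cat(sprintf("  %-14s %s\n", nm,
                  x$inhibition[[nm]]$inhibition_mode))
  }
  if (!is.null(x$mechanism))
    cat("\nInferred mechanism:", x$mechanism$label, "\n")
  if (!is.null(x$activation)) {
    cat("\nActivation:\n")
    print(transform(x$activation, fold = signif(fold, 4),
                    percent_of_activated =
                      signif(percent_of_activated, 3)))
  }
  invisible(x)
}
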