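# Metabolite quantification from stepwise coupled assays.
#
# Each coupling enzyme added in sequence converts one analyte
# stoichiometrically, producing (or consuming) one NAD(P)H per
# analyte molecule; the plateau-to-plateau absorbance change at
# 340 nm therefore measures the analyte amount in the cuvette.

#' Stoichiometry registry of the coupled assays
#'
#' NAD(P)H equivalents per analyte for each assay step. All the
#' coupling chains used here reduce or oxidize one nicotinamide per
#' analyte; the registry is data so an unusual chain can override it.
#' @export
coupled_assay_stoichiometry <- function() {
  c(Glc6P = 1, Fru6P = 1, ATP = 1, Fru16BP = 1, Rib5P = 1)
}

#' A stepped coupled-assay absorbance trace
#'
#' @param steps data.frame with columns `label` and `a340`; the first
#'   row is the basal plateau before any coupling enzyme, each later
#'   row the plateau after one addition.
#' @param direction `"NADPH_formation"` (absorbance rises) or
#'   `"NADH_consumption"` (absorbance falls).
#' @param epsilon molar absorptivity at 340 nm, mM^-1 cm^-1.
#' @param path_cm optical path, cm.
#' @param cuvette_volume_ml reaction volume in the cuvette, ml.
#' @param extract_volume_added_ml volume of extract pipetted in, ml.
#' @param extract_total_volume_ml total extract volume, ml.
#' @return object of class `stepped_assay_trace`.
#' @export
stepped_assay_trace <- function(steps,
                                direction = c("NADPH_formation",
                                              "NADH_consumption"),
                                epsilon = epsilon_nadh_340,
                                path_cm = 1,
                                cuvette_volume_ml = 2,
                                extract_volume_added_ml = 0.5,
                                extract_total_volume_ml = 0.5) {
  direction <- match.arg(direction)
  steps <- as.data.frame(steps)
  stopifnot(all(c("label", "a340") %in% names(steps)))
  if (nrow(steps) < 2)
    stop("a trace needs >= 2 plateaus", call. = FALSE)
  .check_pos(c(epsilon, path_cm, cuvette_volume_ml,
               extract_volume_added_ml, extract_total_volume_ml),
             "epsilon/path/volumes")
  structure(list(steps = steps, direction = direction,
                 epsilon = epsilon, path_cm = path_cm,
                 cuvette_volume_ml = cuvette_volume_ml,
                 extract_volume_added_ml = extract_volume_added_ml,
                 extract_total_volume_ml = extract_total_volume_ml),
            class = "stepped_assay_trace")
}

#' Metabolite amounts from a stepped trace
#'
#' Per step, `delta_c = delta_A / (epsilon * path)` (mM in the
#' cuvette), scaled to micromoles in the whole extract by the cuvette
#' volume and the extract dilution, at 1:1 metabolite:NAD(P)H
#' stoichiometry (override per step via `stoichiometry`). Plateaus
#' must move in the stated direction; a step moving the other way
#' (beyond `tol`) is an error naming the step.
#'
#' @param trace a [stepped_assay_trace()].
#' @param stoichiometry named vector, NAD(P)H per analyte.
#' @param tol absorbance tolerance for direction violations.
#' @return named numeric vector, umol per step label, in extract.
#' @export
amounts_from_trace <- function(trace,
                               stoichiometry = coupled_assay_stoichiometry(),
                               tol = 1e-9) {
  stopifnot(inherits(trace, "stepped_assay_trace"))
  a <- trace$steps$a340
  labels <- trace$steps$label[-1]
  da <- diff(a)
  sign <- if (trace$direction == "NADPH_formation") 1 else -1
  bad <- which(sign * da < -tol)
  if (length(bad))
    stop("plateau moves against the stated direction at step: ",
         paste(labels[bad], collapse = ", "), call. = FALSE)
  da <- pmax(sign * da, 0)
  stoich <- ifelse(labels %in% names(stoichiometry),
                   stoichiometry[labels], 1)
  dc <- da / (trace$epsilon * trace$path_cm)      # mM in cuvette
  amount <- dc * trace$cuvette_volume_ml *
    (trace$extract_total_volume_ml / trace$extract_volume_added_ml) /
    stoich
  setNames(amount, labels)
}

#' Correct an apparent Rib 5-P amount for donor contamination
#'
#' The transketolase assay for ribose 5-phosphate uses commercial
#' xylulose 5-phosphate as donor, which itself carries a Rib 5-P
#' contamination (40-50% in the original determinations); the
#' contaminating amount is subtracted from the apparent value.
#'
#' @param apparent_rib5p apparent Rib 5-P, umol.
#' @param xul5p_added Xul 5-P added, umol.
#' @param contamination_fraction fraction of the added Xul 5-P that
#'   is Rib 5-P, in `[0, 1]` (default 0.45).
#' @return list with `corrected` (umol, floored at 0), `floored`
#'   (logical) and `failed` (`TRUE` when the correction exceeds the
#'   apparent amount by more than 10%, flagging an unusable assay).
#' @export
correct_rib5p <- function(apparent_rib5p, xul5p_added,
                          contamination_fraction = 0.45) {
  .check_nonneg(apparent_rib5p, "apparent_rib5p")
  .check_nonneg(xul5p_added, "xul5p_added")
  if (contamination_fraction < 0 || contamination_fraction > 1)
    stop("contamination_fraction must lie in [0, 1]", call. = FALSE)
  raw <- apparent_rib5p - contamination_fraction * xul5p_added
  failed <- raw < -0.1 * apparent_rib5p
  floored <- raw < 0
  if (floored && !failed)
    warning("corrected Rib 5-P below zero; floored at 0")
  if (failed)
    warning("contamination correction exceeds apparent amount by >10%; ",
            "assay flagged as failed")
  list(corrected = max(raw, 0), floored = floored, failed = failed)
}

#' Spherocylinder cell volume
#'
#' Volume of a rod of total length L and width w with hemispherical
#' caps: `pi (w/2)^2 (L - w) + (pi/6) w^3`, in femtoliters (1 um^3 =
#' 1 fL). The degenerate case L = w is a sphere.
#'
#' @param width_um cell width, um.
#' @param length_um cell length, um, `>= width_um`.
#' @return volume, fL.
#' @export
cell_volume <- function(width_um, length_um) {
  .check_pos(width_um, "width_um"); .check_pos(length_um, "length_um")
  if (any(length_um < width_um))
    stop("length must be >= width", call. = FALSE)
  pi * (width_um / 2)^2 * (length_um - width_um) +
    pi / 6 * width_um^3
}

#' A cultured cell sample for intracellular normalization
#'
#' @param a600 culture absorbance at 600 nm.
#' @param culture_volume_ml culture volume, ml.
#' @param cells_per_ml_ref cell density at A600 = 0.7 (default 6e8).
#' @param cell_width_um,cell_length_um cell dimensions, um.
#' @return object of class `cell_sample`.
#' @export
cell_sample <- function(a600, culture_volume_ml,
                        cells_per_ml_ref = 6e8,
                        cell_width_um = 0.5, cell_length_um = 2) {
  .check_pos(c(a600, culture_volume_ml, cells_per_ml_ref,
               cell_width_um, cell_length_um), "cell sample fields")
  structure(list(a600 = a600, culture_volume_ml = culture_volume_ml,
                 cells_per_ml_ref = cells_per_ml_ref,
                 cell_width_um = cell_width_um,
                 cell_length_um = cell_length_um),
            class = "cell_sample")
}

#' Cell count of a sample
#'
#' `N = a600/0.7 * cells_per_ml_ref * culture_volume_ml`, assuming
#' linearity of scattering with cell density.
#' @param sample a [cell_sample()].
#' @export
cell_count <- function(sample) {
  stopifnot(inherits(sample, "cell_sample"))
  sample$a600 / 0.7 * sample$cells_per_ml_ref * sample$culture_volume_ml
}

#' Intracellular concentration of a metabolite
#'
#' Divides the extract amount by the total intracellular volume
#' (cell count x single-cell volume).
#'
#' @param amount_umol metabolite in the extract, umol.
#' @param sample a [cell_sample()].
#' @param v_cell_fl single-cell volume, fL; defaults to the
#'   spherocylinder volume of the sample's dimensions.
#' @return concentration, mM.
#' @export
intracellular_concentration <- function(amount_umol, sample,
                                        v_cell_fl = NULL) {
  .check_nonneg(amount_umol, "amount_umol")
  stopifnot(inherits(sample, "cell_sample"))
  if (is.null(v_cell_fl))
    v_cell_fl <- cell_volume(sample$cell_width_um,
                             sample$cell_length_um)
  .check_pos(v_cell_fl, "v_cell_fl")
  total_volume_l <- cell_count(sample) * v_cell_fl * 1e-15
  (amount_umol / 1000) / total_volume_l       # mmol / L = mM
}
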