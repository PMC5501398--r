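# Seeded synthetic-data generation.
#
# Every dataset shape the analysis consumes can be generated from a
# rate law plus a noise model, reproducing the concentration designs
# of the original isozyme study at any chosen truth. The default
# noise emulates triplicate initial-velocity assays with typical
# spectrophotometric scatter: multiplicative, CV 5%, 3 replicates.

#' Noise model for synthetic velocities
#'
#' @param kind `"none"`, `"additive"` (SD in velocity units) or
#'   `"multiplicative"` (scale is a CV, fraction).
#' @param scale noise scale (>= 0; ignored for `"none"`).
#' @param seed integer seed; every generator call with the same seed
#'   and design returns the identical dataset.
#' @param replicates measurements per design point.
#' @export
noise_model <- function(kind = c("none", "additive", "multiplicative"),
                        scale = 0, seed = 1L, replicates = 1L) {
  kind <- match.arg(kind)
  .check_nonneg(scale, "scale")
  stopifnot(replicates >= 1)
  structure(list(kind = kind, scale = scale, seed = as.integer(seed),
                 replicates = as.integer(replicates)),
            class = "noise_model")
}

#' Default study-condition noise: triplicates at 5% CV
#' @param seed integer seed.
#' @export
default_noise <- function(seed = 1L)
  noise_model("multiplicative", scale = 0.05, seed = seed,
              replicates = 3L)

.apply_noise <- function(v, noise) {
  v <- rep(v, times = noise$replicates)
  if (noise$kind == "none") return(list(v = v))
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(noise$seed)
  v_noisy <- switch(noise$kind,
    additive = v + rnorm(length(v), 0, noise$scale),
    multiplicative = v * (1 + rnorm(length(v), 0, noise$scale)))
  list(v = pmax(v_noisy, 0))
}

.truth_velocity <- function(params, s) {
  if (inherits(params, "hill_params")) hill_velocity(s, params)
  else if (inherits(params, "activation_params"))
    activation_velocity(s, params)
  else stop("params must be hill_params or activation_params",
            call. = FALSE)
}

#' Generate a single-ligand saturation dataset
#'
#' Velocities from the Hill law (for [hill_params()]) or the
#' hyperbolic activation law (for [activation_params()]) at the given
#' concentration series, with noise applied per replicate. The
#' generating truth is recorded on the dataset.
#'
#' @param params a [hill_params()] or [activation_params()].
#' @param conc_series ligand concentrations, mM; defaults to the
#'   monovalent-cation series of the original activation assays.
#' @param noise a [noise_model()].
#' @param species ligand name for the `conc_` column.
#' @param enzyme,effector,effector_mM,metal metadata labels.
#' @return a [velocity_dataset()].
#' @export
gen_saturation <- function(params, conc_series = default_cation_series(),
                           noise = noise_model("none"),
                           species = "K", enzyme = NA_character_,
                           effector = NA_character_,
                           effector_mM = NA_real_,
                           metal = NA_character_) {
  if (!length(conc_series)) stop("empty conc_series", call. = FALSE)
  .check_nonneg(conc_series, "conc_series")
  v0 <- .truth_velocity(params, conc_series)
  nz <- .apply_noise(v0, noise)
  data <- data.frame(conc = rep(conc_series, times = noise$replicates),
                     velocity = nz$v)
  names(data)[1] <- paste0("conc_", species)
  velocity_dataset(data, velocity_unit = params$unit, enzyme = enzyme,
                   varied_species = species, effector = effector,
                   effector_mM = effector_mM, metal = metal,
                   truth = params)
}

#' Generate a full-factorial bisubstrate initial-velocity grid
#'
#' @param params a [bisubstrate_params()].
#' @param a_levels,b_levels PEP(3-) and ADP-metal levels, mM; default
#'   to the printed grid design for the chosen metal.
#' @param noise a [noise_model()].
#' @param metal `"Mg"` or `"Mn"` (selects the default design).
#' @param species names for the two `conc_` columns.
#' @param enzyme metadata label.
#' @return a [velocity_dataset()]; a single-level grid is accepted
#'   with a warning (it will fail rank checks downstream).
#' @export
gen_bisubstrate_grid <- function(params, a_levels = NULL,
                                 b_levels = NULL,
                                 noise = noise_model("none"),
                                 metal = c("Mg", "Mn"),
                                 species = c("pep3", "adp_metal"),
                                 enzyme = NA_character_) {
  stopifnot(inherits(params, "bisubstrate_params"))
  metal <- match.arg(metal)
  design <- default_grid_design(metal)
  if (is.null(a_levels)) a_levels <- design$pep3
  if (is.null(b_levels)) b_levels <- design$adp_metal
  if (length(a_levels) < 2 || length(b_levels) < 2)
    warning("fewer than 2 levels of a substrate: grid will be ",
            "rank-deficient for a global fit")
  grid <- expand.grid(a = a_levels, b = b_levels)
  v0 <- random_bi_velocity(grid$a, grid$b, params)
  nz <- .apply_noise(v0, noise)
  rep_idx <- rep(seq_len(nrow(grid)), times = noise$replicates)
  data <- data.frame(grid$a[rep_idx], grid$b[rep_idx], nz$v)
  names(data) <- c(paste0("conc_", species), "velocity")
  velocity_dataset(data, velocity_unit = params$unit, enzyme = enzyme,
                   varied_species = species[1], metal = metal,
                   truth = params)
}

#' Generate a substrate x inhibitor dead-end inhibition grid
#'
#' @param params an [inhibition_params()].
#' @param s_levels varied-substrate levels, mM.
#' @param i_levels inhibitor levels in the params' `ki_unit`; a grid
#'   without a zero level triggers a warning.
#' @param noise a [noise_model()].
#' @param species,inhibitor column name / inhibitor label.
#' @param enzyme metadata label.
#' @return a [velocity_dataset()] with an `inhibitor_conc` column.
#' @export
gen_inhibition_grid <- function(params, s_levels, i_levels,
                                noise = noise_model("none"),
                                species = "pep3",
                                inhibitor = "oxalate",
                                enzyme = NA_character_) {
  stopifnot(inherits(params, "inhibition_params"))
  .check_nonneg(s_levels, "s_levels"); .check_nonneg(i_levels, "i_levels")
  if (!any(i_levels == 0))
    warning("no zero-inhibitor level in the design")
  grid <- expand.grid(s = s_levels, i = i_levels)
  v0 <- inhibited_velocity(grid$s, grid$i, params)
  nz <- .apply_noise(v0, noise)
  rep_idx <- rep(seq_len(nrow(grid)), times = noise$replicates)
  data <- data.frame(grid$s[rep_idx], grid$i[rep_idx], nz$v)
  names(data) <- c(paste0("conc_", species), "inhibitor_conc",
                   "velocity")
  velocity_dataset(data, velocity_unit = params$unit, enzyme = enzyme,
                   varied_species = species, inhibitor = inhibitor,
                   inhibitor_unit = params$ki_unit, truth = params)
}

#' Generate a stepped coupled-assay trace from known amounts
#'
#' Inverse of [amounts_from_trace()]: builds the plateau sequence
#' whose step absorbance changes decode exactly (noiselessly) to the
#' given metabolite amounts. Additive noise (in absorbance units) may
#' be applied to the plateaus.
#'
#' @param amounts named numeric vector, umol per metabolite, in the
#'   order the coupling enzymes are added.
#' @param noise a [noise_model()] (`"additive"` scale is in A340
#'   units; multiplicative noise is rejected as unphysical for
#'   absorbance plateaus).
#' @param baseline_a340 basal plateau before any coupling enzyme.
#' @param stoichiometry NAD(P)H per analyte, as in
#'   [amounts_from_trace()].
#' @inheritParams stepped_assay_trace
#' @return a [stepped_assay_trace()].
#' @export
gen_stepped_trace <- function(amounts,
                              direction = c("NADPH_formation",
                                            "NADH_consumption"),
                              noise = noise_model("none"),
                              baseline_a340 = 0.05,
                              epsilon = epsilon_nadh_340,
                              path_cm = 1, cuvette_volume_ml = 2,
                              extract_volume_added_ml = 0.5,
                              extract_total_volume_ml = 0.5,
                              stoichiometry = coupled_assay_stoichiometry()) {
  direction <- match.arg(direction)
  .check_nonneg(unname(amounts), "amounts")
  if (noise$kind == "multiplicative")
    stop("multiplicative noise is not supported for absorbance traces",
         call. = FALSE)
  if (direction == "NADH_consumption" && baseline_a340 <= 0)
    stop("a falling trace needs a positive baseline", call. = FALSE)
  labels <- names(amounts)
  if (is.null(labels) && length(amounts))
    stop("amounts must be named by metabolite", call. = FALSE)
  stoich <- ifelse(labels %in% names(stoichiometry),
                   stoichiometry[labels], 1)
  dilution <- extract_total_volume_ml / extract_volume_added_ml
  dc <- amounts * stoich / (cuvette_volume_ml * dilution)   # mM
  da <- dc * epsilon * path_cm
  sign <- if (direction == "NADPH_formation") 1 else -1
  plateaus <- baseline_a340 + sign * cumsum(c(0, da))
  if (noise$kind == "additive") {
    nz <- .apply_noise(plateaus + 1, noise)   # offset keeps pmax inert
    plateaus <- nz$v - 1
    plateaus <- if (sign > 0) cummax(plateaus) else cummin(plateaus)
  }
  steps <- data.frame(label = c("baseline", labels), a340 = plateaus)
  stepped_assay_trace(steps, direction = direction, epsilon = epsilon,
                      path_cm = path_cm,
                      cuvette_volume_ml = cuvette_volume_ml,
                      extract_volume_added_ml = extract_volume_added_ml,
                      extract_total_volume_ml = extract_total_volume_ml)
}
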