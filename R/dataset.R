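# Velocity datasets and their CSV dialect.
#
# A velocity dataset is a data.frame with one row per measured point:
# one or more `conc_<species>` columns (mM), an optional
# `inhibitor_conc` column, and a `velocity` column, plus metadata
# attributes (enzyme, varied species, velocity unit, effector, metal,
# inhibitor identity/unit, and the generator truth when synthetic).

.ds_attrs <- c("enzyme", "varied_species", "velocity_unit",
               "effector", "effector_mM", "metal",
               "inhibitor", "inhibitor_unit")

#' Construct a velocity dataset
#'
#' @param data data.frame with `conc_<species>` columns (mM), an
#'   optional `inhibitor_conc` column, and `velocity`.
#' @param velocity_unit `"umol_min_mg"` or `"per_s"`.
#' @param enzyme,effector,metal,inhibitor metadata labels (optional).
#' @param effector_mM effector concentration, mM.
#' @param varied_species which species column is the varied one;
#'   defaults to the first `conc_` column.
#' @param inhibitor_unit unit of `inhibitor_conc` (`"mM"` or `"uM"`).
#' @param truth optional generating parameter object (synthetic data).
#' @return object of class `velocity_dataset` (a data.frame).
#' @export
velocity_dataset <- function(data, velocity_unit = "umol_min_mg",
                             enzyme = NA_character_,
                             varied_species = NULL,
                             effector = NA_character_,
                             effector_mM = NA_real_,
                             metal = NA_character_,
                             inhibitor = NA_character_,
                             inhibitor_unit = "mM",
                             truth = NULL) {
  data <- as.data.frame(data)
  conc_cols <- grep("^conc_", names(data), value = TRUE)
  if (!length(conc_cols))
    stop("data needs at least one conc_<species> column", call. = FALSE)
  if (!"velocity" %in% names(data))
    stop("data needs a velocity column", call. = FALSE)
  if (!nrow(data)) stop("dataset must have >= 1 point", call. = FALSE)
  .check_nonneg(data$velocity, "velocity")
  for (cc in conc_cols) .check_nonneg(data[[cc]], cc)
  .check_unit(velocity_unit)
  if (is.null(varied_species))
    varied_species <- sub("^conc_", "", conc_cols[1])
  if (!paste0("conc_", varied_species) %in% conc_cols)
    stop("varied_species has no matching conc_ column", call. = FALSE)
  structure(data,
            class = c("velocity_dataset", "data.frame"),
            enzyme = enzyme, varied_species = varied_species,
            velocity_unit = velocity_unit, effector = effector,
            effector_mM = effector_mM, metal = metal,
            inhibitor = inhibitor, inhibitor_unit = inhibitor_unit,
            truth = truth)
}

#' Species concentration columns of a dataset
#' @param ds a [velocity_dataset()].
#' @return character vector of species names.
#' @export
dataset_species <- function(ds) {
  sub("^conc_", "", grep("^conc_", names(ds), value = TRUE))
}

.ds_conc <- function(ds, species) ds[[paste0("conc_", species)]]

#' Read / write the velocity-dataset CSV dialect
#'
#' One row per point with columns `enzyme, varied_species,
#' conc_<species>..., velocity, velocity_unit, effector, effector_mM,
#' metal, inhibitor, inhibitor_unit, inhibitor_conc`. Reading
#' validates velocities (non-negative, error reports the offending
#' row), requires a single known velocity unit, and restores the
#' metadata attributes; write-then-read is lossless.
#'
#' @param path CSV path.
#' @param ds a [velocity_dataset()].
#' @export
read_velocity_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("enzyme", "varied_species", "velocity", "velocity_unit")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(!is.finite(df$velocity) | df$velocity < 0)
  if (length(bad))
    stop("negative or non-numeric velocity at row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  units <- unique(df$velocity_unit)
  if (length(units) != 1)
    stop("mixed velocity units in one file: ",
         paste(units, collapse = ", "), call. = FALSE)
  .check_unit(units)
  conc_cols <- grep("^conc_", names(df), value = TRUE)
  keep <- c(conc_cols,
            intersect("inhibitor_conc", names(df)), "velocity")
  first <- function(col, default = NA)
    if (col %in% names(df)) df[[col]][1] else default
  velocity_dataset(df[keep],
                   velocity_unit = units,
                   enzyme = first("enzyme"),
                   varied_species = df$varied_species[1],
                   effector = first("effector"),
                   effector_mM = first("effector_mM", NA_real_),
                   metal = first("metal"),
                   inhibitor = first("inhibitor"),
                   inhibitor_unit = first("inhibitor_unit", "mM"))
}

#' @rdname read_velocity_csv
#' @export
write_velocity_csv <- function(ds, path) {
  stopifnot(inherits(ds, "velocity_dataset"))
  a <- attributes(ds)
  out <- data.frame(enzyme = a$enzyme,
                    varied_species = a$varied_species,
                    as.data.frame(ds)[grep("^conc_", names(ds))],
                    velocity = ds$velocity,
                    velocity_unit = a$velocity_unit,
                    effector = a$effector, effector_mM = a$effector_mM,
                    metal = a$metal, inhibitor = a$inhibitor,
                    inhibitor_unit = a$inhibitor_unit,
                    inhibitor_conc =
                      if ("inhibitor_conc" %in% names(ds))
                        ds$inhibitor_conc else NA_real_,
                    check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.velocity_dataset <- function(x, ...) {
  a <- attributes(x)
  cat(sprintf(
    "Velocity dataset: %d points, varied species '%s' [%s]\n",
    nrow(x), a$varied_species, a$velocity_unit))
  if (!is.na(a$enzyme)) cat("  enzyme:", a$enzyme, "\n")
  if (!is.na(a$inhibitor)) cat("  inhibitor:", a$inhibitor,
                               paste0("[", a$inhibitor_unit, "]"), "\n")
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}
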