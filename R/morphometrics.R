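#' Wing area from wingspan, hand length and secondary length
#'
#' Approximates the combined area of both wings as a central rectangle of
#' width `wingspan - 2 * hand_length` and depth `secondary_length`, plus the
#' two triangular hand sections (`hand_length * secondary_length / 2` each).
#' Algebraically this equals `secondary_length * (wingspan - hand_length)`.
#'
#' @param wingspan Wingspan in mm (wingtip to wingtip).
#' @param hand_length Hand length H in mm (the standard "wing length"
#'   measurement, carpal joint to wingtip).
#' @param secondary_length First secondary feather length S in mm.
#' @return Wing area in mm^2.
#' @examples
#' wing_area(400, 100, 50)  # 15000
#' @export
wing_area <- function(wingspan, hand_length, secondary_length) {
  if (any(hand_length < 0) || any(secondary_length <= 0) || any(wingspan <= 0)) {
    stop("Invalid measurement: wingspan and secondary length must be positive, hand length non-negative.",
         call. = FALSE)
  }
  area <- (wingspan - 2 * hand_length) * secondary_length +
    2 * (hand_length * secondary_length * 0.5)
  bad <- wingspan <= 2 * hand_length
  if (any(bad)) {
    if (any(area <= 0)) {
      stop("Invalid measurement: wingspan <= hand length gives non-positive wing area.",
           call. = FALSE)
    }
    warning("wingspan <= 2 * hand_length for ", sum(bad),
            " record(s): the central-rectangle term is non-positive.",
            call. = FALSE)
  }
  area
}

#' Wing loading: body mass per unit wing area
#'
#' @param mass Body mass in g.
#' @param area Wing area in mm^2.
#' @return Wing loading in g mm^-2. Typical gull values fall in roughly
#'   0.002-0.007 g mm^-2.
#' @examples
#' wing_loading(1000, 200000)  # 0.005
#' @export
wing_loading <- function(mass, area) {
  if (any(mass <= 0) || any(area <= 0)) {
    stop("Invalid measurement: mass and area must be strictly positive.", call. = FALSE)
  }
  mass / area
}

#' Aspect ratio: wingspan squared over wing area
#'
#' High values indicate long, narrow wings efficient for gliding; low values
#' indicate broad wings suited to maneuverability.
#'
#' @inheritParams wing_loading
#' @param wingspan Wingspan in mm.
#' @return Unitless aspect ratio.
#' @export
aspect_ratio <- function(wingspan, area) {
  if (any(wingspan <= 0) || any(area <= 0)) {
    stop("Invalid measurement: wingspan and area must be strictly positive.", call. = FALSE)
  }
  wingspan^2 / area
}

#' Z-standardize a numeric vector
#'
#' Centers to mean 0 and scales to unit standard deviation using the
#' population convention (divisor n). With the sample convention (n - 1) all
#' standardized values, and hence per-SD regression coefficients, change by a
#' factor sqrt(n / (n - 1)), about 1% at n = 50.
#'
#' @param x Numeric vector, length >= 2, non-constant.
#' @return Standardized vector with mean 0 and population SD 1.
#' @export
z_standardize <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2L) stop("Need at least 2 values to standardize.", call. = FALSE)
  if (anyNA(x)) stop("Missing values in `x`; standardize the complete analysis set.", call. = FALSE)
  s <- sqrt(mean((x - mean(x))^2))
  if (s < .Machine$double.eps * max(1, abs(mean(x)))) {
    stop("Degenerate input: `x` is constant, cannot standardize.", call. = FALSE)
  }
  (x - mean(x)) / s
}

#' Absolute latitude
#'
#' Unsigned distance of a range-centroid latitude from the equator, a proxy
#' for insolation.
#'
#' @param lat Latitude in degrees, in \[-90, 90\].
#' @return Degrees >= 0.
#' @export
absolute_latitude <- function(lat) {
  if (any(!is.na(lat) & (lat < -90 | lat > 90))) {
    stop("Latitude must lie in [-90, 90] degrees.", call. = FALSE)
  }
  abs(lat)
}

#' Midpoint of a wingspan range
#'
#' Field guides typically report wingspan as a range; the central value is
#' used as the species estimate.
#'
#' @param lo,hi Range endpoints in mm, `lo <= hi`.
#' @return Midpoint in mm.
#' @export
wingspan_midpoint <- function(lo, hi) {
  if (any(!is.na(lo) & !is.na(hi) & lo > hi)) {
    stop("Invalid wingspan range: lower bound exceeds upper bound.", call. = FALSE)
  }
  (lo + hi) / 2
}

#' Average subspecies records up to species
#'
#' Collapses rows sharing a parent species to a single row by taking the
#' arithmetic mean of each numeric column, excluding missing values pairwise
#' (a field that is missing in every subspecies stays missing).
#'
#' @param data A data frame of species/subspecies records with a `species`
#'   column; rows belonging to a subspecies carry the parent species name in
#'   a `parent_species` column (NA or absent means the row is already at
#'   species level).
#' @return A tibble with one row per species.
#' @export
aggregate_subspecies <- function(data) {
  if (nrow(data) == 0L) stop("Empty record set.", call. = FALSE)
  if (!"species" %in% names(data)) stop("`data` must have a `species` column.", call. = FALSE)
  if (!"parent_species" %in% names(data)) data$parent_species <- NA_character_
  data |>
    dplyr::mutate(.species = dplyr::coalesce(.data$parent_species, .data$species)) |>
    dplyr::group_by(.data$.species) |>
    dplyr::summarise(
      dplyr::across(dplyr::where(is.numeric),
                    ~ if (all(is.na(.x))) NA_real_ else mean(.x, na.rm = TRUE)),
      .groups = "drop"
    ) |>
    dplyr::rename(species = ".species")
}

#' Derive wing morphology from raw species measurements
#'
#' Adds wingspan (range midpoint), wing area, wing loading, aspect ratio and
#' absolute latitude to a species table. Standardized wing loading is
#' computed over the rows where wing loading is available (the analysis set),
#' so its mean over that set is exactly 0; rows with missing measurements
#' propagate NA.
#'
#' @param data A data frame with columns `species`, `hand_length`,
#'   `secondary_length`, `wingspan_min`, `wingspan_max`, `body_mass`,
#'   `latitude`, and optionally `mantle_kgs`, `wingtip_black`.
#' @return The input tibble with added columns `wingspan`, `wing_area`,
#'   `wing_loading`, `wing_loading_std`, `aspect_ratio`, `abs_latitude`.
#' @export
derive_morphology <- function(data) {
  required <- c("species", "hand_length", "secondary_length",
                "wingspan_min", "wingspan_max", "body_mass", "latitude")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    stop("Missing required column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- data |>
    tibble::as_tibble() |>
    dplyr::mutate(
      wingspan = wingspan_midpoint(.data$wingspan_min, .data$wingspan_max),
      wing_area = dplyr::if_else(
        is.na(.data$wingspan), NA_real_,
        .data$secondary_length * (.data$wingspan - .data$hand_length)
      ),
      wing_loading = .data$body_mass / .data$wing_area,
      abs_latitude = absolute_latitude(.data$latitude)
    )
  ok <- !is.na(out$wing_loading)
  if (sum(ok) >= 2L) {
    out$wing_loading_std <- NA_real_
    out$wing_loading_std[ok] <- z_standardize(out$wing_loading[ok])
  } else {
    out$wing_loading_std <- NA_real_
  }
  out$aspect_ratio <- ifelse(is.na(out$wing_area), NA_real_,
                             out$wingspan^2 / out$wing_area)
  out
}

#' Restrict a derived table to the complete cases of one analysis
#'
#' Filters to rows complete for the given variables and recomputes
#' standardized wing loading on that complete set, as each analysis
#' standardizes over its own sample.
#'
#' @param data A derived-morphology tibble (see [derive_morphology()]).
#' @param vars Character vector of columns that must be non-missing.
#' @return Filtered tibble with `wing_loading_std` recomputed.
#' @export
prepare_analysis <- function(data, vars = c("wing_loading", "abs_latitude", "mantle_kgs")) {
  keep <- complete.cases(data[, intersect(vars, names(data)), drop = FALSE])
  out <- data[keep, , drop = FALSE]
  if ("wing_loading" %in% names(out) && nrow(out) >= 2L) {
    out$wing_loading_std <- z_standardize(out$wing_loading)
  }
  out
}

#' Read a species measurement table
#'
#' @param path Path to a CSV with one row per species or subspecies
#'   (subspecies rows marked by a `parent_species` column). Expected columns:
#'   `species`, `hand_length`, `secondary_length`, `wingspan_min`,
#'   `wingspan_max`, `body_mass`, `latitude`, `mantle_kgs`, `wingtip_black`.
#' @return A tibble.
#' @export
read_species_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write a derived-morphology table
#'
#' @param data Tibble to write.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_morphology_csv <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}
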