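#' Per-islet measurement columns
#'
#' Fixed column order of the per-islet measurement table written by
#' [write_measurements()].
#' @export
islet_measurement_columns <- c(
  "animal_id", "series_index", "islet_id", "area_um2", "insulin_area_um2",
  "sst_area_um2", "otsu_threshold", "kapur_threshold", "equiv_diameter_um",
  "size_class", "touches_border")

#' Measure one segmented islet
#'
#' Converts a segmentation into physical per-islet quantities: total
#' islet area, insulin-positive and somatostatin-positive areas (pixel
#' counts scaled by the squared pixel size), the equivalent-circle
#' diameter \eqn{d = 2\sqrt{A/\pi}}, and the size class at the given
#' diameter cutoff.  Islets touching the image border are measured but
#' flagged so users can filter them.
#'
#' @param seg a `segmentation_result` from [segment_islet_region()].
#' @param regions the [islet_region_set()] the segmentation came from.
#' @param pixel_size_um physical pixel edge length, micrometers.
#' @param animal_id,series_index metadata copied into the record.
#' @param cutoff_um size-class cutoff in micrometers (default 100):
#'   islets with equivalent diameter strictly below it are "small".
#' @return A one-row data.frame with columns
#'   `r paste(islet_measurement_columns, collapse = ", ")`.
#' @export
measure_islet <- function(seg, regions, pixel_size_um,
                          animal_id = "unknown", series_index = 0L,
                          cutoff_um = 100) {
  stopifnot(inherits(seg, "segmentation_result"),
            inherits(regions, "islet_region_set"))
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  in_region <- regions$labels == seg$region_id
  n_px <- sum(in_region)
  if (n_px == 0L) stop("region ", seg$region_id, " has no pixels")
  px_area <- pixel_size_um^2
  area <- n_px * px_area
  d_eq <- 2 * sqrt(area / pi)
  border <- any(in_region[1L, ]) || any(in_region[nrow(in_region), ]) ||
    any(in_region[, 1L]) || any(in_region[, ncol(in_region)])
  data.frame(
    animal_id = animal_id,
    series_index = as.integer(series_index),
    islet_id = seg$region_id,
    area_um2 = area,
    insulin_area_um2 = sum(seg$insulin_mask) * px_area,
    sst_area_um2 = sum(seg$sst_mask) * px_area,
    otsu_threshold = if (is.null(seg$otsu_threshold)) NA_real_
                     else seg$otsu_threshold,
    kapur_threshold = if (is.null(seg$kapur_threshold)) NA_real_
                      else seg$kapur_threshold,
    equiv_diameter_um = d_eq,
    size_class = classify_islet_size(d_eq, cutoff_um),
    touches_border = border,
    stringsAsFactors = FALSE)
}

#' Classify islet size from equivalent diameter
#'
#' Binary size classification: "small" strictly below the cutoff,
#' "large" at or above it (a diameter of exactly 100 um is large under
#' the default cutoff).
#'
#' @param equiv_diameter_um equivalent-circle diameter(s), micrometers;
#'   a measurement data.frame with an `equiv_diameter_um` column is also
#'   accepted.
#' @param cutoff_um positive cutoff, micrometers (default 100).
#' @return Character vector, `"small"` or `"large"`.
#' @export
classify_islet_size <- function(equiv_diameter_um, cutoff_um = 100) {
  if (is.data.frame(equiv_diameter_um))
    equiv_diameter_um <- equiv_diameter_um$equiv_diameter_um
  if (!is.numeric(cutoff_um) || length(cutoff_um) != 1L || cutoff_um <= 0)
    stop("cutoff_um must be a positive scalar")
  ifelse(equiv_diameter_um < cutoff_um, "small", "large")
}

#' Measure all islets of a section
#'
#' Runs [segment_section()] and [measure_islet()] over every region of a
#' section.
#'
#' @param section a [fluorescence_section()].
#' @param regions an [islet_region_set()].
#' @param n_bins histogram bins for segmentation.
#' @param cutoff_um size-class cutoff, micrometers.
#' @return A data.frame with one row per islet (zero rows for an empty
#'   mask), columns as in [islet_measurement_columns].
#' @export
measure_section <- function(section, regions, n_bins = 256L,
                            cutoff_um = 100) {
  segs <- segment_section(section, regions, n_bins = n_bins)
  rows <- lapply(segs, measure_islet, regions = regions,
                 pixel_size_um = section$pixel_size_um,
                 animal_id = section$animal_id,
                 series_index = section$series_index,
                 cutoff_um = cutoff_um)
  if (length(rows) == 0L) return(empty_measurement_frame())
  do.call(rbind, rows)
}

empty_measurement_frame <- function() {
  df <- data.frame(animal_id = character(0), series_index = integer(0),
                   islet_id = integer(0), area_um2 = numeric(0),
                   insulin_area_um2 = numeric(0), sst_area_um2 = numeric(0),
                   otsu_threshold = numeric(0), kapur_threshold = numeric(0),
                   equiv_diameter_um = numeric(0), size_class = character(0),
                   touches_border = logical(0), stringsAsFactors = FALSE)
  df
}

#' Aggregate islet measurements to a per-animal summary
#'
#' Pools all measured islets of one animal (all sections of all series)
#' into the aggregate quantities reported for pancreas morphometry:
#' islet count, total and mean islet area, counts per size class, and
#' beta-/delta-cell percentages.  Percentages are *pooled*
#' (area-weighted): 100 x total hormone-positive area / total islet
#' area, not the mean of per-islet ratios.
#'
#' @param measurements data.frame of per-islet rows (see
#'   [measure_islet()]); all rows must share one `animal_id`.  May be
#'   empty, in which case counts are zero and percentages `NA`.
#' @param animal_id the animal the summary is for; inferred from the
#'   measurements when omitted.
#' @return A one-row data.frame: `animal_id`, `n_islets`,
#'   `total_islet_area_um2`, `mean_islet_area_um2`, `beta_cell_percent`,
#'   `delta_cell_percent`, `n_small_islets`, `n_large_islets`.
#' @export
summarize_pancreas <- function(measurements, animal_id = NULL) {
  if (nrow(measurements) > 0L) {
    ids <- unique(measurements$animal_id)
    if (length(ids) > 1L)
      stop("measurements mix animal_ids: ", paste(ids, collapse = ", "))
    if (is.null(animal_id)) animal_id <- ids
    if (!identical(as.character(ids), as.character(animal_id)))
      stop("measurements belong to animal ", ids, ", not ", animal_id)
  }
  if (is.null(animal_id)) animal_id <- NA_character_
  n <- nrow(measurements)
  tot <- sum(measurements$area_um2)
  data.frame(
    animal_id = as.character(animal_id),
    n_islets = n,
    total_islet_area_um2 = tot,
    mean_islet_area_um2 = if (n > 0L) tot / n else NA_real_,
    beta_cell_percent = if (n > 0L && tot > 0)
      100 * sum(measurements$insulin_area_um2) / tot else NA_real_,
    delta_cell_percent = if (n > 0L && tot > 0)
      100 * sum(measurements$sst_area_um2) / tot else NA_real_,
    n_small_islets = sum(measurements$size_class == "small"),
    n_large_islets = sum(measurements$size_class == "large"),
    stringsAsFactors = FALSE)
}

#' Per-section breakdown of islet measurements
#'
#' Emits one row per (animal, series) with the same pooled quantities as
#' [summarize_pancreas()], for analyses that treat each section as the
#' unit (e.g. means over sections).
#'
#' @param measurements per-islet data.frame, possibly spanning animals
#'   and series.
#' @return Data.frame with one row per animal/series combination.
#' @export
summarize_sections <- function(measurements) {
  if (nrow(measurements) == 0L)
    return(cbind(summarize_pancreas(empty_measurement_frame())[0, ],
                 series_index = integer(0)))
  parts <- split(measurements,
                 list(measurements$animal_id, measurements$series_index),
                 drop = TRUE)
  out <- do.call(rbind, lapply(parts, function(m) {
    s <- summarize_pancreas(m)
    s$series_index <- m$series_index[1L]
    s
  }))
  rownames(out) <- NULL
  out[order(out$animal_id, out$series_index), ]
}
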