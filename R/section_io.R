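#' Construct a fluorescence section
#'
#' Bundles the per-channel intensity planes of one immunofluorescence
#' section with its physical and bookkeeping metadata.  Channels follow the
#' fluorophore mapping used for dual-stained pancreas sections: red =
#' somatostatin, green = insulin, blue = optional nuclear stain (carried
#' but never analyzed).
#'
#' @param red,green numeric matrices of non-negative intensities
#'   (arbitrary units), identical dimensions.
#' @param blue optional numeric matrix, same dimensions, or `NULL`.
#' @param pixel_size_um physical pixel edge length in micrometers
#'   (default 0.65, the scan resolution the pipeline was designed around).
#' @param animal_id character identifier of the animal/preparation.
#' @param series_index non-negative integer; sections are typically cut in
#'   series with a fixed spacing.
#' @param section_spacing_um spacing between consecutive sections of a
#'   series in micrometers (metadata only; default 250).
#' @return An object of class `fluorescence_section`.
#' @export
fluorescence_section <- function(red, green, blue = NULL,
                                 pixel_size_um = 0.65,
                                 animal_id = "unknown",
                                 series_index = 0L,
                                 section_spacing_um = 250) {
  stopifnot(is.matrix(red), is.matrix(green))
  if (!identical(dim(red), dim(green)))
    stop("red and green channels must have identical dimensions")
  if (!is.null(blue) && !identical(dim(blue), dim(red)))
    stop("blue channel dimensions must match red/green")
  if (any(red < 0) || any(green < 0) || (!is.null(blue) && any(blue < 0)))
    stop("channel intensities must be non-negative")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      pixel_size_um <= 0)
    stop("pixel_size_um must be a positive scalar")
  structure(
    list(red = red, green = green, blue = blue,
         pixel_size_um = pixel_size_um,
         animal_id = as.character(animal_id),
         series_index = as.integer(series_index),
         section_spacing_um = section_spacing_um),
    class = "fluorescence_section")
}

#' @export
print.fluorescence_section <- function(x, ...) {
  cat(sprintf(
    "<fluorescence_section> %d x %d px (%.3g um/px), animal %s, series %d\n",
    nrow(x$red), ncol(x$red), x$pixel_size_um, x$animal_id, x$series_index))
  invisible(x)
}

#' Read a multi-channel section image
#'
#' Imports a fluorescence section from an RGB TIFF (one file, three
#' planes) or from separate grayscale TIFF planes (a character vector of
#' 2 or 3 paths), and splits it into red/green/blue channels.  Original
#' integer bit depth (8 or 16 bit) is preserved: intensities are returned
#' as integer-valued matrices on the native scale.
#'
#' @param path a single RGB TIFF path, or a character vector of grayscale
#'   plane paths in the order given by `channel_order`.
#' @param pixel_size_um physical pixel size in micrometers.
#' @param channel_order character vector naming the planes, a permutation
#'   of `c("red", "green", "blue")` (or its first two elements for
#'   two-plane input).  Default maps plane 1 to red (somatostatin),
#'   plane 2 to green (insulin), plane 3 to blue (nuclei).
#' @param animal_id,series_index,section_spacing_um metadata passed to
#'   [fluorescence_section()].
#' @return A `fluorescence_section`.
#' @export
read_section_image <- function(path, pixel_size_um = 0.65,
                               channel_order = c("red", "green", "blue"),
                               animal_id = "unknown", series_index = 0L,
                               section_spacing_um = 250) {
  channel_order <- match.arg(channel_order, c("red", "green", "blue"),
                             several.ok = TRUE)
  if (anyDuplicated(channel_order))
    stop("channel_order must not repeat channels")
  planes <- if (length(path) == 1L) {
    img <- read_image_native(path)
    if (length(dim(img)) < 3L || dim(img)[3L] < 2L)
      stop("format error: expected a multi-channel image with >= 2 planes: ",
           path)
    lapply(seq_len(dim(img)[3L]), function(k) img[, , k])
  } else {
    lapply(path, function(p) {
      img <- read_image_native(p)
      if (length(dim(img)) == 3L) {
        if (dim(img)[3L] != 1L)
          stop("format error: expected grayscale plane, got multi-channel: ", p)
        img <- img[, , 1L]
      }
      img
    })
  }
  if (length(planes) < length(channel_order))
    stop("format error: fewer image planes than channel_order entries")
  dims <- lapply(planes, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1L]])))
    stop("format error: image planes have mismatched dimensions")
  ch <- list(red = NULL, green = NULL, blue = NULL)
  for (k in seq_along(channel_order)) ch[[channel_order[k]]] <- planes[[k]]
  if (is.null(ch$red) || is.null(ch$green))
    stop("channel_order must assign both a red and a green plane")
  fluorescence_section(ch$red, ch$green, ch$blue,
                       pixel_size_um = pixel_size_um,
                       animal_id = animal_id, series_index = series_index,
                       section_spacing_um = section_spacing_um)
}

# Read a TIFF or PNG as integer intensities on the stored bit-depth scale
# (8-bit -> 0..255, 16-bit -> 0..65535).  Readers return intensities
# normalized to [0, 1]; rescaling by 2^bits - 1 and rounding recovers the
# stored integers exactly.  Returns a matrix (grayscale) or h x w x k
# array.
read_image_native <- function(path) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(img, "bits.per.sample")
    if (is.null(bits)) bits <- 8L
  } else if (ext == "png") {
    img <- png::readPNG(path, native = FALSE)
    bits <- as.integer(readBin(path, "raw", 25L)[25L])  # IHDR bit depth
    if (!bits %in% c(1L, 2L, 4L, 8L, 16L)) bits <- 8L
  } else {
    stop("unsupported image format (expected TIFF or PNG): ", path)
  }
  if (length(dim(img)) == 3L && dim(img)[3L] %in% c(2L, 4L)) {
    # drop an alpha plane if present
    img <- img[, , seq_len(dim(img)[3L] - 1L), drop = (dim(img)[3L] == 2L)]
  }
  out <- round(unclass(img) * (2^bits - 1))
  attributes(out) <- list(dim = dim(img))
  storage.mode(out) <- "double"
  out
}

# Write integer intensities as a 16-bit TIFF (grayscale matrix or
# h x w x 3 RGB array).  Values must lie in [0, 65535]; the file
# round-trips bit-for-bit through read_image_native().
write_image_16bit <- function(img, path) {
  if (any(img < 0) || any(img > 65535))
    stop("intensities out of 16-bit range")
  tiff::writeTIFF(round(img) / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Label islet regions from a mask image
#'
#' Imports an islet perimeter mask aligned pixel-for-pixel with a section
#' and identifies the individual islet regions.  Binary masks (any nonzero
#' pixel = inside an islet) are labeled by connected-component analysis
#' under the chosen connectivity; already-labeled masks keep their
#' partition but are relabeled to consecutive ids in raster order.
#'
#' @param path mask image path (TIFF or PNG), or a numeric matrix already
#'   in memory.
#' @param section the matching [fluorescence_section()]; used to check
#'   alignment.
#' @param connectivity 8 (default; diagonally touching pixels belong to
#'   one islet) or 4.
#' @param labeled if `TRUE`, treat distinct nonzero values as distinct
#'   regions (each must still be one connected component); if `FALSE`
#'   (default) the mask is binarized first.
#' @return An `islet_region_set`: list with `labels` (integer matrix,
#'   0 = background), `region_ids`, and `connectivity`.
#' @export
read_islet_masks <- function(path, section, connectivity = 8,
                             labeled = FALSE) {
  mask <- if (is.matrix(path)) path else {
    img <- read_image_native(path)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    img
  }
  if (!identical(dim(mask), dim(section$red)))
    stop("alignment error: mask dimensions ", paste(dim(mask), collapse = "x"),
         " do not match section ", paste(dim(section$red), collapse = "x"))
  islet_region_set(mask, connectivity = connectivity, labeled = labeled)
}

#' Connected-component islet regions
#'
#' Core labeling used by [read_islet_masks()]: partitions the mask
#' foreground into connected components and assigns region ids 1, 2, ...
#' in raster-scan order (row-major) of each component's first pixel, so
#' output ordering is reproducible.
#'
#' @param mask numeric/logical matrix; nonzero = foreground.
#' @param connectivity 4 or 8.
#' @param labeled if `TRUE`, distinct nonzero input values must form
#'   disjoint single components and are preserved as separate regions;
#'   overlap (one component spanning two labels) is an error.
#' @return An `islet_region_set`.
#' @export
islet_region_set <- function(mask, connectivity = 8, labeled = FALSE) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  fg <- mask != 0
  comp <- label_components(fg, connectivity)
  if (labeled) {
    # a labeled mask must agree with the component partition
    for (id in sort(unique(mask[fg]))) {
      comps_in <- unique(comp[mask == id & fg])
      if (length(comps_in) > 1L)
        stop("labeled mask region ", id, " is not a single connected component")
    }
    split_labels <- tapply(mask[fg], comp[fg], function(v) length(unique(v)))
    if (any(split_labels > 1L))
      stop("labeled mask regions overlap: one connected component carries ",
           "multiple labels")
  }
  ids <- if (max(comp) > 0L) seq_len(max(comp)) else integer(0)
  structure(list(labels = comp, region_ids = ids,
                 connectivity = connectivity),
            class = "islet_region_set")
}

#' @export
print.islet_region_set <- function(x, ...) {
  cat(sprintf("<islet_region_set> %d region(s), connectivity %d, %d x %d px\n",
              length(x$region_ids), x$connectivity,
              nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

# Connected-component labeling of a logical matrix.  Components are found
# on the graph of 4- or 8-neighbour foreground adjacencies; ids are then
# remapped to raster-scan (row-major) order of each component's first
# pixel.  Returns an integer matrix, 0 = background.
label_components <- function(fg, connectivity = 8L) {
  stopifnot(is.logical(fg) || is.numeric(fg))
  fg <- fg != 0
  nr <- nrow(fg); nc <- ncol(fg)
  out <- matrix(0L, nr, nc)
  idx <- which(fg)
  if (length(idx) == 0L) return(out)
  fid <- matrix(0L, nr, nc)
  fid[idx] <- seq_along(idx)
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  edge_pairs <- function(dr, dc) {
    ok <- r + dr >= 1L & r + dr <= nr & cc + dc >= 1L & cc + dc <= nc
    nb <- fid[cbind(r[ok] + dr, cc[ok] + dc)]
    keep <- nb > 0L
    cbind(fid[idx[ok][keep]], nb[keep])
  }
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  edges <- do.call(rbind, lapply(offs, function(o) edge_pairs(o[1L], o[2L])))
  memb <- if (is.null(edges) || nrow(edges) == 0L) {
    seq_along(idx)
  } else {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
    igraph::components(g)$membership[seq_along(idx)]
  }
  # raster order: row-major position of each component's first pixel
  raster_pos <- (r - 1L) * nc + cc
  first_pos <- tapply(raster_pos, memb, min)
  new_id <- integer(length(first_pos))
  new_id[order(first_pos)] <- seq_along(first_pos)
  out[idx] <- new_id[memb]
  out
}

#' Write measurement records to CSV
#'
#' Serializes per-islet measurements or per-animal summaries to a CSV
#' with a fixed column order; numeric fields keep at least 6 significant
#' digits so a read-back reproduces the records.  An empty record list
#' yields a header-only file.
#'
#' @param records a data.frame of islet measurements (see
#'   [measure_islet()]) or pancreas summaries (see
#'   [summarize_pancreas()]), or a list of single-row data.frames.
#' @param path output CSV path.
#' @return Invisibly, the written data.frame.
#' @export
write_measurements <- function(records, path) {
  if (is.list(records) && !is.data.frame(records))
    records <- do.call(rbind, records)
  if (is.null(records) || ncol(records) == 0L)
    records <- empty_measurement_frame()  # header-only file
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  ok <- tryCatch({
    utils::write.csv(format_measurements(records), path, row.names = FALSE,
                     quote = TRUE, na = "NA")
    TRUE
  }, error = function(e) stop("cannot write measurements to ", path, ": ",
                              conditionMessage(e)))
  invisible(records)
}

format_measurements <- function(df) {
  as.data.frame(lapply(df, function(col) {
    if (is.double(col)) {
      out <- vapply(col, function(v) {
        if (is.na(v)) NA_character_ else format(v, digits = 15L,
                                                scientific = FALSE)
      }, character(1))
      out
    } else col
  }), stringsAsFactors = FALSE, check.names = FALSE,
  row.names = NULL)
}

#' Read measurement records written by [write_measurements()]
#' @param path CSV path.
#' @return A data.frame.
#' @export
read_measurements <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
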