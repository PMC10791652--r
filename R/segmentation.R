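#' Mutual red/green bleed-through correction
#'
#' Corrects fluorophore crosstalk between the somatostatin (red) and
#' insulin (green) channels by subtracting each channel from the other.
#' Both corrected images are computed from the *original* arrays
#' (symmetric mutual subtraction, not sequential overwriting) and clamped
#' at zero, so each output retains only the signal that dominates in its
#' own channel.
#'
#' @param red,green non-negative numeric matrices of identical shape.
#' @return A list with elements `red` and `green`, the corrected arrays.
#' @examples
#' cross_channel_correct(matrix(c(5, 10)), matrix(c(3, 20)))
#' @export
cross_channel_correct <- function(red, green) {
  if (!identical(dim(red), dim(green)))
    stop("red and green arrays must have the same shape")
  if (any(red < 0) || any(green < 0))
    stop("intensities must be non-negative")
  list(red = pmax(red - green, 0), green = pmax(green - red, 0))
}

#' Build an equal-width intensity histogram over a pixel set
#'
#' Histograms one region's intensity values into `n_bins` equal-width
#' bins spanning the region's own min--max range (both ends inclusive).
#' This per-region, min--max binning is what makes the downstream
#' thresholds adaptive to each islet.  A constant region yields a
#' degenerate single-bin histogram flagged as such.
#'
#' @param values numeric vector of intensities (a region's pixels).
#' @param n_bins number of bins (default 256, the classic formulation).
#' @return An `intensity_histogram`: list with integer `counts`
#'   (length `n_bins`), `bin_edges` (length `n_bins + 1`), `n_bins`, and
#'   logical `degenerate`.
#' @export
build_histogram <- function(values, n_bins = 256L) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("cannot histogram an empty region")
  if (anyNA(values)) stop("intensities must be finite")
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L) stop("n_bins must be positive")
  lo <- min(values); hi <- max(values)
  if (lo == hi) {
    h <- list(counts = length(values), bin_edges = c(lo, lo + 1),
              n_bins = 1L, degenerate = TRUE)
    return(structure(h, class = "intensity_histogram"))
  }
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  bin <- findInterval(values, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  structure(list(counts = counts, bin_edges = edges, n_bins = n_bins,
                 degenerate = FALSE),
            class = "intensity_histogram")
}

#' @export
print.intensity_histogram <- function(x, ...) {
  cat(sprintf("<intensity_histogram> %d bins over [%g, %g], %d pixels%s\n",
              x$n_bins, x$bin_edges[1L], x$bin_edges[length(x$bin_edges)],
              sum(x$counts), if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

bin_centers <- function(h) {
  (h$bin_edges[-1L] + h$bin_edges[-length(h$bin_edges)]) / 2
}

# Smallest index attaining the maximum, treating values within a 1e-9
# relative band of the maximum as tied.  Histogram objectives can be
# analytically equal across several splits (e.g. equal-mass classes);
# the band keeps the smallest-split tie-break stable against floating
# point summation order.
argmax_smallest <- function(x) {
  m <- max(x)
  which(x >= m - 1e-9 * max(1, abs(m)))[1L]
}

#' Otsu threshold (between-class variance maximization)
#'
#' Finds the histogram split maximizing the between-class variance
#' \eqn{\sigma_B^2(t) = \omega_0 \omega_1 (\mu_0 - \mu_1)^2}, where class
#' 0 collects bins \eqn{\le t} and class 1 the bins above, \eqn{\omega}
#' are class probability masses and \eqn{\mu} class means of bin centers.
#' Ties are broken by the smallest split, which favors the larger (more
#' sensitive) foreground.  The returned threshold is the upper *edge* of
#' the last class-0 bin; hormone-positive pixels are those with intensity
#' strictly greater than this edge.
#'
#' @param h an [build_histogram()] result.
#' @return The threshold edge (numeric scalar), or `NULL` for a
#'   degenerate histogram (fewer than two occupied bins).
#' @export
otsu_threshold <- function(h) {
  stopifnot(inherits(h, "intensity_histogram"))
  if (h$degenerate || sum(h$counts > 0) < 2L) return(NULL)
  p <- h$counts / sum(h$counts)
  ctr <- bin_centers(h)
  n <- h$n_bins
  w0 <- cumsum(p)[-n]
  m0 <- cumsum(p * ctr)[-n]
  mu_tot <- sum(p * ctr)
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, n - 1L)
  sigma_b[valid] <- w0[valid] * w1[valid] *
    (m0[valid] / w0[valid] - (mu_tot - m0[valid]) / w1[valid])^2
  t_star <- argmax_smallest(sigma_b)
  h$bin_edges[t_star + 1L]
}

#' Kapur threshold (maximum entropy)
#'
#' Finds the histogram split maximizing the summed Shannon entropies
#' \eqn{H_0(t) + H_1(t)} of the two intensity classes, with class
#' probabilities renormalized within each class and the convention
#' \eqn{0 \log 0 = 0}.  Natural logarithms are used (the base only
#' rescales the objective; the maximizer is unchanged).  Splits leaving
#' one class empty are invalid; ties are broken by the smallest split.
#' The returned threshold is the upper edge of the last class-0 bin, with
#' foreground = intensity strictly greater than that edge.
#'
#' @param h an [build_histogram()] result.
#' @return The threshold edge, or `NULL` when the histogram is
#'   degenerate or admits no valid split.
#' @export
kapur_threshold <- function(h) {
  stopifnot(inherits(h, "intensity_histogram"))
  if (h$degenerate || sum(h$counts > 0) < 2L) return(NULL)
  p <- h$counts / sum(h$counts)
  n <- h$n_bins
  s <- ifelse(p > 0, -p * log(p), 0)  # -p ln p, with 0 ln 0 := 0
  S0 <- cumsum(s)[-n]
  P0 <- cumsum(p)[-n]
  S_tot <- sum(s)
  P1 <- 1 - P0
  valid <- P0 > 0 & P1 > 0
  if (!any(valid)) return(NULL)
  obj <- rep(-Inf, n - 1L)
  # H_c = (1/P_c) * sum_c(-p ln p) + ln P_c, the class entropy after
  # renormalizing bin probabilities by the class mass
  obj[valid] <- S0[valid] / P0[valid] + log(P0[valid]) +
    (S_tot - S0[valid]) / P1[valid] + log(P1[valid])
  t_star <- argmax_smallest(obj)
  h$bin_edges[t_star + 1L]
}

#' Segment one islet region into hormone-positive masks
#'
#' Applies the full per-islet segmentation: mutual bleed-through
#' correction of the whole section, extraction of the region's pixels,
#' then an Otsu threshold on the corrected green (insulin) values and a
#' Kapur threshold on the corrected red (somatostatin) values, each
#' computed from that region's own intensity histogram.  A region that is
#' constant in a channel gets no threshold and an empty mask for that
#' hormone, with a degenerate flag recorded.
#'
#' @param section a [fluorescence_section()].
#' @param regions an [islet_region_set()] aligned with the section.
#' @param region_id which region to segment.
#' @param n_bins histogram bins (default 256).
#' @param corrected optionally, a precomputed [cross_channel_correct()]
#'   result for the section, to avoid recorrecting when looping over
#'   regions.
#' @return A `segmentation_result`: list with `region_id`,
#'   `insulin_mask` and `sst_mask` (logical matrices, section-sized,
#'   `FALSE` outside the region), `otsu_threshold`, `kapur_threshold`
#'   (numeric or `NULL`), and `degenerate_flags` (character vector,
#'   subset of `c("constant_green", "constant_red")`).
#' @export
segment_islet_region <- function(section, regions, region_id,
                                 n_bins = 256L, corrected = NULL) {
  stopifnot(inherits(section, "fluorescence_section"),
            inherits(regions, "islet_region_set"))
  if (!region_id %in% regions$region_ids)
    stop("unknown region_id: ", region_id)
  if (is.null(corrected))
    corrected <- cross_channel_correct(section$red, section$green)
  in_region <- regions$labels == region_id
  flags <- character(0)
  insulin_mask <- matrix(FALSE, nrow(in_region), ncol(in_region))
  sst_mask <- insulin_mask

  hg <- build_histogram(corrected$green[in_region], n_bins)
  t_otsu <- otsu_threshold(hg)
  if (is.null(t_otsu)) {
    flags <- c(flags, "constant_green")
  } else {
    insulin_mask <- in_region & corrected$green > t_otsu
  }

  hr <- build_histogram(corrected$red[in_region], n_bins)
  t_kapur <- kapur_threshold(hr)
  if (is.null(t_kapur)) {
    flags <- c(flags, "constant_red")
  } else {
    sst_mask <- in_region & corrected$red > t_kapur
  }

  structure(list(region_id = as.integer(region_id),
                 insulin_mask = insulin_mask, sst_mask = sst_mask,
                 otsu_threshold = if (is.null(t_otsu)) NULL else t_otsu,
                 kapur_threshold = if (is.null(t_kapur)) NULL else t_kapur,
                 degenerate_flags = flags),
            class = "segmentation_result")
}

#' Segment every islet region of a section
#'
#' Convenience loop over [segment_islet_region()] that performs the
#' bleed-through correction once for the whole section.
#'
#' @inheritParams segment_islet_region
#' @return A list of `segmentation_result`, one per region id.
#' @export
segment_section <- function(section, regions, n_bins = 256L) {
  corrected <- cross_channel_correct(section$red, section$green)
  lapply(regions$region_ids, function(id)
    segment_islet_region(section, regions, id, n_bins = n_bins,
                         corrected = corrected))
}
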