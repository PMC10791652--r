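# Independent oracles used across the suite.  These deliberately use
# naive per-split / per-pixel algorithms, not the package's vectorized
# formulations.

# Exhaustive Otsu: evaluate the between-class variance at every split
# with direct sums; smallest split within a 1e-9 relative band of the
# maximum wins.
oracle_otsu <- function(counts, edges) {
  p <- counts / sum(counts)
  n <- length(counts)
  ctr <- (edges[-1L] + edges[-(n + 1L)]) / 2
  vals <- rep(-Inf, n - 1L)
  for (t in seq_len(n - 1L)) {
    w0 <- sum(p[1:t]); w1 <- sum(p[(t + 1L):n])
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(p[1:t] * ctr[1:t]) / w0
    m1 <- sum(p[(t + 1L):n] * ctr[(t + 1L):n]) / w1
    vals[t] <- w0 * w1 * (m0 - m1)^2
  }
  m <- max(vals)
  edges[which(vals >= m - 1e-9 * max(1, abs(m)))[1L] + 1L]
}

# Exhaustive Kapur: summed class entropies at every split, skipping
# splits that leave a class empty; same tie rule.
oracle_kapur <- function(counts, edges) {
  p <- counts / sum(counts)
  n <- length(counts)
  vals <- rep(-Inf, n - 1L)
  for (t in seq_len(n - 1L)) {
    P0 <- sum(p[1:t]); P1 <- sum(p[(t + 1L):n])
    if (P0 == 0 || P1 == 0) next
    q0 <- p[1:t]; q0 <- q0[q0 > 0] / P0
    q1 <- p[(t + 1L):n]; q1 <- q1[q1 > 0] / P1
    vals[t] <- -sum(q0 * log(q0)) - sum(q1 * log(q1))
  }
  if (all(!is.finite(vals))) return(NULL)
  m <- max(vals)
  edges[which(vals >= m - 1e-9 * max(1, abs(m)))[1L] + 1L]
}

# Histogram variance bookkeeping for the decomposition identity.
variance_parts <- function(counts, edges, t) {
  p <- counts / sum(counts)
  n <- length(counts)
  ctr <- (edges[-1L] + edges[-(n + 1L)]) / 2
  mu <- sum(p * ctr)
  total <- sum(p * (ctr - mu)^2)
  w0 <- sum(p[1:t]); w1 <- sum(p[(t + 1L):n])
  m0 <- if (w0 > 0) sum(p[1:t] * ctr[1:t]) / w0 else 0
  m1 <- if (w1 > 0) sum(p[(t + 1L):n] * ctr[(t + 1L):n]) / w1 else 0
  within <- (if (w0 > 0) sum(p[1:t] * (ctr[1:t] - m0)^2) else 0) +
    (if (w1 > 0) sum(p[(t + 1L):n] * (ctr[(t + 1L):n] - m1)^2) else 0)
  between <- w0 * w1 * (m0 - m1)^2
  c(total = total, within = within, between = between)
}

# Queue-based flood fill, the brute-force reference for connected
# component labeling.  Labels in raster (row-major) discovery order.
oracle_flood_fill <- function(mask, connectivity = 8L) {
  fg <- mask != 0
  nr <- nrow(fg); nc <- ncol(fg)
  lab <- matrix(0L, nr, nc)
  offs <- if (connectivity == 8L)
    list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L),
         c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))
  else list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  nxt <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!fg[i, j] || lab[i, j] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(i, j)); lab[i, j] <- nxt
    while (length(queue) > 0L) {
      q <- queue[[1L]]; queue <- queue[-1L]
      for (o in offs) {
        ni <- q[1L] + o[1L]; nj <- q[2L] + o[2L]
        if (ni >= 1L && ni <= nr && nj >= 1L && nj <= nc &&
            fg[ni, nj] && lab[ni, nj] == 0L) {
          lab[ni, nj] <- nxt
          queue[[length(queue) + 1L]] <- c(ni, nj)
        }
      }
    }
  }
  lab
}

# Random histograms for the oracle-equivalence battery.
random_histogram <- function(n_bins, n_mass) {
  counts <- stats::rmultinom(1L, n_mass,
                             prob = stats::runif(n_bins)^2)[, 1L]
  width <- stats::runif(1L, 0.1, 10)
  lo <- stats::runif(1L, -100, 100)
  edges <- lo + width * (0:n_bins)
  structure(list(counts = counts, bin_edges = edges,
                 n_bins = as.integer(n_bins),
                 degenerate = FALSE),
            class = "intensity_histogram")
}

byte_equal_dirs <- function(a, b) {
  fa <- sort(list.files(a, full.names = TRUE))
  fb <- sort(list.files(b, full.names = TRUE))
  length(fa) == length(fb) && all(basename(fa) == basename(fb)) &&
    all(mapply(function(x, y)
      identical(readBin(x, "raw", file.size(x)),
                readBin(y, "raw", file.size(y))), fa, fb))
}

small_params <- function(...) {
  islet_image_params(image_size_px = c(192L, 192L), n_islets = 2L,
                     diameter_meanlog = log(45), diameter_sdlog = 0.2, ...)
}
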