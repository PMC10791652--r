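test_that("cross-channel correction is symmetric, clamped and shape-checked", {
  out <- cross_channel_correct(matrix(c(5, 10)), matrix(c(3, 20)))
  expect_equal(as.numeric(out$red), c(2, 0))
  expect_equal(as.numeric(out$green), c(0, 10))

  r <- matrix(runif(20, 0, 100), 4, 5)
  # zero green leaves red untouched
  out2 <- cross_channel_correct(r, matrix(0, 4, 5))
  expect_equal(out2$red, r)
  expect_true(all(out2$green == 0))
  # identical channels annihilate both
  out3 <- cross_channel_correct(r, r)
  expect_true(all(out3$red == 0) && all(out3$green == 0))
  # both outputs come from the ORIGINAL arrays, not sequentially
  a <- matrix(c(10, 0), 1, 2); b <- matrix(c(4, 7), 1, 2)
  out4 <- cross_channel_correct(a, b)
  expect_equal(as.numeric(out4$red), c(6, 0))
  expect_equal(as.numeric(out4$green), c(0, 7))
  expect_error(cross_channel_correct(matrix(0, 2, 2), matrix(0, 3, 3)),
               "shape")
})

test_that("histograms tally pixels exactly and flag constant regions", {
  h <- build_histogram(0:255, 256L)
  expect_true(all(h$counts == 1L))
  expect_equal(h$bin_edges[c(1, 257)], c(0, 255))

  hc <- build_histogram(rep(7, 50))
  expect_true(hc$degenerate)
  expect_equal(sum(hc$counts), 50L)

  withr::local_seed(5)
  vals <- c(rnorm(600, 40, 6), rnorm(400, 160, 12))
  h2 <- build_histogram(vals, 64L)
  expect_equal(sum(h2$counts), 1000L)
  # direct tally oracle: count values per bin by explicit comparison
  tally <- vapply(seq_len(64L), function(i) {
    lo <- h2$bin_edges[i]; hi <- h2$bin_edges[i + 1L]
    if (i < 64L) sum(vals >= lo & vals < hi) else sum(vals >= lo & vals <= hi)
  }, numeric(1))
  expect_equal(h2$counts, as.integer(tally))
  expect_error(build_histogram(numeric(0)), "empty")
})

test_that("thresholds reproduce exhaustive-search oracles on fixed cases", {
  # 8-bin case, expected split computed by the per-split oracles
  h <- structure(list(counts = c(5L, 10L, 2L, 0L, 3L, 8L, 7L, 1L),
                      bin_edges = as.numeric(0:8), n_bins = 8L,
                      degenerate = FALSE),
                 class = "intensity_histogram")
  expect_equal(otsu_threshold(h), oracle_otsu(h$counts, h$bin_edges))
  expect_equal(otsu_threshold(h), 3)   # frozen from the oracle
  expect_equal(kapur_threshold(h), oracle_kapur(h$counts, h$bin_edges))
  expect_equal(kapur_threshold(h), 3)  # frozen from the oracle

  # uniform 4-bin histogram: entropy maximized at the middle split,
  # tie-broken to the smaller side
  hu <- structure(list(counts = rep(1L, 4L), bin_edges = as.numeric(0:4),
                       n_bins = 4L, degenerate = FALSE),
                  class = "intensity_histogram")
  expect_equal(kapur_threshold(hu), oracle_kapur(hu$counts, hu$bin_edges))
  expect_equal(kapur_threshold(hu), 2)  # frozen from the oracle
})

test_that("two-spike histograms tie-break to the smallest split for both methods", {
  v <- c(rep(10, 50), rep(200, 50))
  h <- build_histogram(v, 256L)
  # every split between the spikes is optimal; the smallest is the first
  # edge above the low spike
  expect_equal(otsu_threshold(h), h$bin_edges[2L])
  expect_equal(kapur_threshold(h), h$bin_edges[2L])
  # that threshold separates exactly the high spike as foreground
  expect_equal(sum(v > otsu_threshold(h)), 50L)
})

test_that("degenerate histograms yield null thresholds with a flag", {
  hc <- build_histogram(rep(42, 10))
  expect_true(hc$degenerate)
  expect_null(otsu_threshold(hc))
  expect_null(kapur_threshold(hc))
})

test_that("thresholds equal exhaustive oracles over a random battery", {
  withr::local_seed(101)
  for (i in 1:150) {
    h <- random_histogram(sample(8:128, 1L), sample(c(50L, 1000L), 1L))
    if (sum(h$counts > 0) < 2L) next
    expect_identical(otsu_threshold(h), oracle_otsu(h$counts, h$bin_edges))
    expect_identical(kapur_threshold(h), oracle_kapur(h$counts, h$bin_edges))
  }
})

test_that("total variance decomposes into within- plus between-class at every split", {
  withr::local_seed(17)
  for (i in 1:20) {
    h <- random_histogram(32L, 500L)
    for (t in seq_len(31L)) {
      parts <- variance_parts(h$counts, h$bin_edges, t)
      expect_equal(parts[["within"]] + parts[["between"]], parts[["total"]],
                   tolerance = 1e-9)
    }
  }
})

test_that("thresholds are shift-equivariant under min-max binning", {
  withr::local_seed(23)
  vals <- c(rnorm(300, 30, 5), rnorm(200, 120, 15))
  for (shift in c(13.5, 200)) {
    h0 <- build_histogram(vals, 128L)
    h1 <- build_histogram(vals + shift, 128L)
    expect_equal(otsu_threshold(h1), otsu_threshold(h0) + shift,
                 tolerance = 1e-9)
    expect_equal(kapur_threshold(h1), kapur_threshold(h0) + shift,
                 tolerance = 1e-9)
  }
})

test_that("per-islet segmentation recovers exact masks on separable images", {
  p <- small_params(noise_sd = 0, bleedthrough_alpha = 0,
                    background_level = 10, insulin_level = 200)
  sim <- generate_islet_image(p, seed = 2)
  regions <- islet_region_set(sim$mask, labeled = TRUE)
  for (id in regions$region_ids) {
    seg <- segment_islet_region(sim$section, regions, id)
    in_region <- regions$labels == id
    expect_identical(seg$insulin_mask, sim$truth$true_insulin_mask & in_region)
    expect_identical(seg$sst_mask, sim$truth$true_sst_mask & in_region)
    # masks are confined to their region
    expect_true(!any(seg$insulin_mask & !in_region))
    expect_true(!any(seg$sst_mask & !in_region))
  }
})

test_that("constant regions segment to empty masks with degenerate flags", {
  red <- matrix(7, 30, 30); green <- matrix(7, 30, 30)
  sec <- fluorescence_section(red, green)
  mask <- matrix(0L, 30L, 30L); mask[5:15, 5:15] <- 1L
  regions <- islet_region_set(mask)
  seg <- segment_islet_region(sec, regions, 1L)
  expect_setequal(seg$degenerate_flags, c("constant_green", "constant_red"))
  expect_null(seg$otsu_threshold)
  expect_null(seg$kapur_threshold)
  expect_true(!any(seg$insulin_mask) && !any(seg$sst_mask))
  expect_error(segment_islet_region(sec, regions, 99L), "unknown region_id")
})

test_that("noisy default islets are recovered within 5% insulin pixel error", {
  sim <- generate_islet_image(small_params(), seed = 1)
  regions <- islet_region_set(sim$mask, labeled = TRUE)
  for (id in regions$region_ids) {
    seg <- segment_islet_region(sim$section, regions, id)
    truth_px <- sum(sim$truth$true_insulin_mask & regions$labels == id)
    got_px <- sum(seg$insulin_mask)
    expect_lt(abs(got_px - truth_px) / truth_px, 0.05)
  }
})
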