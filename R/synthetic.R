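# Run code under a fixed RNG seed, restoring the caller's RNG state.
# All generator randomness flows through this single stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Parameters for the synthetic islet image generator
#'
#' Describes a dual-channel pancreas-section mimic: disk-shaped islets
#' placed without overlap on a flat background, an interior concentric
#' insulin-positive region covering a set fraction of each islet's area,
#' peripheral somatostatin-positive blobs, symmetric red/green
#' bleed-through, a constant background offset, and additive Gaussian
#' noise.  Defaults are the generator's documented study conditions:
#' 512 x 512 px at 0.65 um/px, 5 islets with lognormal diameters around
#' 70 um, beta area fraction 0.65, insulin/somatostatin signal levels
#' 180/150 over background 20 with noise sd 10 (signal-to-noise ~ 18 for
#' the insulin channel) and 10% bleed-through.
#'
#' @param image_size_px integer pair (rows, cols).
#' @param n_islets number of islets to place (>= 0).
#' @param diameter_meanlog,diameter_sdlog lognormal parameters of the
#'   islet diameter in micrometers.
#' @param beta_area_fraction fraction of each islet's area occupied by
#'   the interior insulin-positive disk, in \[0, 1\].
#' @param delta_blob_count,delta_blob_radius_um number and radius of the
#'   peripheral somatostatin-positive blobs per islet.
#' @param background_level,insulin_level,sst_level intensities
#'   (arbitrary units on a 16-bit scale).
#' @param noise_sd standard deviation of the per-pixel additive Gaussian
#'   noise.
#' @param bleedthrough_alpha fraction of each channel's true signal
#'   leaking into the other channel, in \[0, 1).
#' @param pixel_size_um physical pixel size, micrometers.
#' @return A validated `islet_image_params` list.
#' @export
islet_image_params <- function(image_size_px = c(512L, 512L),
                               n_islets = 5L,
                               diameter_meanlog = log(70),
                               diameter_sdlog = 0.25,
                               beta_area_fraction = 0.65,
                               delta_blob_count = 6L,
                               delta_blob_radius_um = 5,
                               background_level = 20,
                               insulin_level = 180,
                               sst_level = 150,
                               noise_sd = 10,
                               bleedthrough_alpha = 0.1,
                               pixel_size_um = 0.65) {
  p <- list(image_size_px = as.integer(image_size_px),
            n_islets = as.integer(n_islets),
            diameter_meanlog = diameter_meanlog,
            diameter_sdlog = diameter_sdlog,
            beta_area_fraction = beta_area_fraction,
            delta_blob_count = as.integer(delta_blob_count),
            delta_blob_radius_um = delta_blob_radius_um,
            background_level = background_level,
            insulin_level = insulin_level,
            sst_level = sst_level,
            noise_sd = noise_sd,
            bleedthrough_alpha = bleedthrough_alpha,
            pixel_size_um = pixel_size_um)
  stopifnot(length(p$image_size_px) == 2L, all(p$image_size_px > 0L),
            p$n_islets >= 0L,
            p$beta_area_fraction >= 0, p$beta_area_fraction <= 1,
            p$delta_blob_count >= 0L, p$delta_blob_radius_um > 0,
            p$background_level >= 0, p$insulin_level >= 0, p$sst_level >= 0,
            p$noise_sd >= 0,
            p$bleedthrough_alpha >= 0, p$bleedthrough_alpha < 1,
            p$pixel_size_um > 0)
  structure(p, class = "islet_image_params")
}

disk_mask <- function(nr, nc, cr, cc, radius) {
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  (rows - cr)^2 + (cols - cc)^2 <= radius^2
}

#' Generate a synthetic dual-channel islet section with ground truth
#'
#' Renders the image described by an [islet_image_params()] object under
#' a fixed seed: islet disks are placed by bounded rejection sampling
#' (no overlap, fully inside the frame), each with a concentric interior
#' insulin region of the requested area fraction and peripheral
#' somatostatin blobs confined to the annulus outside the insulin core.
#' The observed channels are
#' `red = true_sst + alpha * true_insulin + background + noise` and
#' symmetrically for green, clamped to \[0, 65535\] and rounded to
#' integer intensities so the written TIFF round-trips exactly.
#' The same call with the same seed is bit-identical.
#'
#' @param params an [islet_image_params()].
#' @param seed integer RNG seed.
#' @param animal_id,series_index metadata for the resulting section.
#' @return A list with `section` (a [fluorescence_section()]), `mask`
#'   (integer labeled islet mask), and `truth` (a
#'   `synthetic_ground_truth`: `true_islet_labels`, `true_insulin_mask`,
#'   `true_sst_mask`, per-islet radii/areas/beta fractions, size-class
#'   counts, and a parameter echo).
#' @export
generate_islet_image <- function(params = islet_image_params(), seed = 1L,
                                 animal_id = "synthetic",
                                 series_index = 0L) {
  stopifnot(inherits(params, "islet_image_params"))
  with_seed(seed, {
    nr <- params$image_size_px[1L]; nc <- params$image_size_px[2L]
    labels <- matrix(0L, nr, nc)
    insulin_true <- matrix(FALSE, nr, nc)
    sst_true <- matrix(FALSE, nr, nc)
    centers <- matrix(numeric(0), 0, 2)
    radii_px <- numeric(0)
    attempts <- 0L
    k <- 0L
    while (k < params$n_islets) {
      if (attempts >= 10000L)
        stop("infeasible islet placement: could not fit ", params$n_islets,
             " non-overlapping islets of the requested size in a ",
             nr, "x", nc, " frame within 10000 attempts")
      attempts <- attempts + 1L
      d_um <- stats::rlnorm(1, params$diameter_meanlog, params$diameter_sdlog)
      r_px <- d_um / 2 / params$pixel_size_um
      if (2 * r_px + 4 >= min(nr, nc)) next  # diameter must respect bounds
      cr <- stats::runif(1, r_px + 2, nr - r_px - 1)
      cc <- stats::runif(1, r_px + 2, nc - r_px - 1)
      if (nrow(centers) > 0L) {
        dist2 <- (centers[, 1L] - cr)^2 + (centers[, 2L] - cc)^2
        if (any(dist2 <= (radii_px + r_px + 2)^2)) next
      }
      k <- k + 1L
      centers <- rbind(centers, c(cr, cc))
      radii_px <- c(radii_px, r_px)
      islet <- disk_mask(nr, nc, cr, cc, r_px)
      labels[islet] <- k
      # interior insulin core: concentric disk with the target area share
      r_in <- r_px * sqrt(params$beta_area_fraction)
      core <- disk_mask(nr, nc, cr, cc, r_in)
      insulin_true <- insulin_true | (islet & core)
      # peripheral somatostatin blobs, clipped to the islet annulus
      if (params$delta_blob_count > 0L) {
        blob_r <- params$delta_blob_radius_um / params$pixel_size_um
        ang <- stats::runif(params$delta_blob_count, 0, 2 * pi)
        rad <- (r_in + r_px) / 2
        for (b in seq_len(params$delta_blob_count)) {
          bcr <- cr + rad * sin(ang[b]); bcc <- cc + rad * cos(ang[b])
          blob <- disk_mask(nr, nc, bcr, bcc, blob_r)
          sst_true <- sst_true | (blob & islet & !core)
        }
      }
    }
    g_true <- params$insulin_level * insulin_true
    r_true <- params$sst_level * sst_true
    a <- params$bleedthrough_alpha
    bg <- params$background_level
    red <- r_true + a * g_true + bg
    green <- g_true + a * r_true + bg
    if (params$noise_sd > 0) {
      red <- red + stats::rnorm(nr * nc, 0, params$noise_sd)
      green <- green + stats::rnorm(nr * nc, 0, params$noise_sd)
    }
    red <- matrix(pmin(pmax(round(red), 0), 65535), nr, nc)
    green <- matrix(pmin(pmax(round(green), 0), 65535), nr, nc)

    px_area <- params$pixel_size_um^2
    islet_areas <- as.numeric(tabulate(labels[labels > 0L],
                                       nbins = params$n_islets)) * px_area
    beta_frac <- vapply(seq_len(params$n_islets), function(i) {
      sum(insulin_true[labels == i]) / sum(labels == i)
    }, numeric(1))
    d_eq <- 2 * sqrt(islet_areas / pi)
    truth <- structure(
      list(true_islet_labels = labels,
           true_insulin_mask = insulin_true,
           true_sst_mask = sst_true,
           n_islets = params$n_islets,
           radii_px = radii_px,
           islet_areas_um2 = islet_areas,
           true_beta_fraction_per_islet = beta_frac,
           true_beta_percent_pooled = if (params$n_islets > 0L)
             100 * sum(insulin_true & labels > 0L) / sum(labels > 0L)
           else NA_real_,
           equiv_diameters_um = d_eq,
           counts_by_class = c(small = sum(d_eq < 100),
                               large = sum(d_eq >= 100)),
           params = params, seed = seed),
      class = "synthetic_ground_truth")
    section <- fluorescence_section(
      red, green, blue = matrix(0, nr, nc),
      pixel_size_um = params$pixel_size_um,
      animal_id = animal_id, series_index = series_index)
    list(section = section, mask = labels, truth = truth)
  })
}

#' Generate synthetic secretion samples with known truth
#'
#' Draws lognormal secreted concentrations around per-condition means
#' with a common coefficient of variation, mimicking static-incubation
#' hormone secretion tables.  Lysate (residual) content is generated
#' jointly from a per-condition true stimulation index, so
#' [stimulation_index()] has a stated truth: at `cv = 0` the index
#' equals `stim_index_percent` exactly.
#'
#' @param n_per_group replicates per condition.
#' @param group_means named numeric vector, condition -> mean secreted
#'   ng/ml.  Defaults to a basal group at 1.9 ng/ml and a stimulated
#'   group at 2.7-fold of it.
#' @param cv coefficient of variation of the lognormal draw (default
#'   0.26, i.e. the spread of a basal group at 1.9 +/- 0.5 ng/ml).
#' @param stim_index_percent named vector of true stimulation indices
#'   (percent of total content) per condition, or a single value
#'   recycled; `NA` omits content for that condition.
#' @param seed RNG seed.
#' @return A data.frame with columns `condition`, `replicate`,
#'   `secreted_ng_ml`, `content_ng_ml`, `animal_or_prep_id`.
#' @export
generate_secretion_data <- function(n_per_group = 6L,
                                    group_means = c(basal = 1.9,
                                                    p116_2mM = 1.9 * 2.7),
                                    cv = 0.26,
                                    stim_index_percent = 10,
                                    seed = 1L) {
  stopifnot(all(group_means >= 0), cv >= 0, n_per_group >= 1L)
  if (is.null(names(group_means)))
    stop("group_means must be a named vector (condition -> mean)")
  if (length(stim_index_percent) == 1L)
    stim_index_percent <- stats::setNames(
      rep(stim_index_percent, length(group_means)), names(group_means))
  with_seed(seed, {
    rows <- lapply(names(group_means), function(cond) {
      m <- group_means[[cond]]
      secreted <- if (cv == 0 || m == 0) rep(m, n_per_group) else {
        sdlog <- sqrt(log(1 + cv^2))
        stats::rlnorm(n_per_group, log(m) - sdlog^2 / 2, sdlog)
      }
      idx <- stim_index_percent[[cond]]
      content <- if (is.na(idx)) rep(NA_real_, n_per_group)
                 else secreted * (100 / idx - 1)
      data.frame(condition = cond, replicate = seq_len(n_per_group),
                 secreted_ng_ml = secreted, content_ng_ml = content,
                 animal_or_prep_id = sprintf("prep%02d", seq_len(n_per_group)),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Evaluate the four-parameter logistic curve
#' @param d dose(s), same unit as `ec50`.
#' @param bottom,top,ec50,hill curve parameters.
#' @return Response value(s).
#' @export
four_pl <- function(d, bottom, top, ec50, hill) {
  bottom + (top - bottom) / (1 + (ec50 / d)^hill)
}

#' Generate dose--response data from a known 4PL truth
#'
#' @param doses_uM dose vector, micromolar; default eight two-fold steps
#'   from 125 to 16000 uM, bracketing an EC50 of 950 uM so both
#'   asymptotes are sampled (a recovery simulation must exercise the
#'   estimator, not a plateau-truncated design).
#' @param bottom,top,ec50,hill true curve (defaults: fold scale from 1
#'   to 2.7 with EC50 950 uM, hill 1).
#' @param reps replicates per dose.
#' @param sigma additive Gaussian noise sd on the response scale.
#' @param seed RNG seed.
#' @return A data.frame with `dose_uM` and `response`.
#' @export
generate_dose_response <- function(doses_uM = 125 * 2^(0:7),
                                   bottom = 1, top = 2.7, ec50 = 950,
                                   hill = 1, reps = 4L, sigma = 0.1,
                                   seed = 1L) {
  stopifnot(all(doses_uM > 0), ec50 > 0, reps >= 1L, sigma >= 0)
  with_seed(seed, {
    d <- rep(doses_uM, each = reps)
    mu <- four_pl(d, bottom, top, ec50, hill)
    resp <- if (sigma > 0) mu + stats::rnorm(length(d), 0, sigma) else mu
    data.frame(dose_uM = d, response = resp)
  })
}

#' Generate a synthetic fura-2 trace with a known ratio step
#'
#' Constant baseline ratio with a step of known amplitude during a
#' response window, plus Gaussian noise on both raw channels.
#'
#' @param n_frames trace length.
#' @param baseline_ratio ratio before stimulation.
#' @param delta true step amplitude of the ratio.
#' @param response_start first frame of the response plateau.
#' @param f380_level raw F380 intensity level.
#' @param noise_sd channel noise sd.
#' @param seed RNG seed.
#' @return A list with `trace` (a [ca_trace()]), `baseline_window`,
#'   `response_window`, and `true_delta`.
#' @export
generate_ca_trace <- function(n_frames = 150L, baseline_ratio = 0.8,
                              delta = 0.4, response_start = 76L,
                              f380_level = 500, noise_sd = 5, seed = 1L) {
  stopifnot(response_start > 1L, response_start <= n_frames)
  with_seed(seed, {
    ratio <- rep(baseline_ratio, n_frames)
    ratio[response_start:n_frames] <- baseline_ratio + delta
    f380 <- f380_level + stats::rnorm(n_frames, 0, noise_sd)
    f340 <- ratio * f380_level + stats::rnorm(n_frames, 0, noise_sd)
    list(trace = ca_trace(f340, f380),
         baseline_window = seq_len(response_start - 1L),
         response_window = response_start:n_frames,
         true_delta = delta)
  })
}
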