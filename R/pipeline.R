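#' Read a pipeline run configuration
#'
#' Configurations are YAML key-value files; every tunable that affects
#' an output value is surfaced here and echoed into the run manifest so
#' each run is self-describing.  Missing keys take the documented
#' defaults (pixel size 0.65 um, connectivity 8, 256 histogram bins,
#' 100 um size cutoff, stimulation-index mode "total").
#'
#' @param path YAML file path, or a named list already in memory.
#' @return A complete config list.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  defaults <- list(pixel_size_um = 0.65, connectivity = 8L, n_bins = 256L,
                   size_cutoff_um = 100, index_mode = "total", seed = 1L,
                   n_sections = 1L, animal_id = "synthetic",
                   basal_condition = "basal", fix_bottom = NULL)
  for (k in names(defaults))
    if (is.null(cfg[[k]])) cfg[k] <- list(defaults[[k]])
  cfg
}

write_manifest <- function(cfg, out_dir, extra = list()) {
  # filesystem locations do not affect output values; omitting them (and
  # any clock) keeps identical-config runs byte-identical
  cfg <- cfg[setdiff(names(cfg), c("in_dir", "out_dir", "samples"))]
  manifest <- c(list(package = "isletquant",
                     version = as.character(utils::packageVersion("isletquant"))),
                cfg[order(names(cfg))], extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
}

#' Simulate a synthetic islet image dataset on disk
#'
#' Generates `n_sections` sections per the image parameters in the
#' config, writing for each a 16-bit RGB section TIFF, a 16-bit labeled
#' islet mask TIFF, and a ground-truth JSON, plus a manifest echoing the
#' full configuration and seed.  Per-section seeds are `seed + series`,
#' so the whole dataset is reproducible from one integer; reruns with an
#' identical config are byte-identical.
#'
#' @param config a YAML path or list (see [read_run_config()]); image
#'   parameters may be given under a `params` sub-list
#'   (see [islet_image_params()]).  Requires `out_dir`.
#' @return Invisibly, a data.frame listing the written file triples.
#' @export
run_simulate <- function(config) {
  cfg <- read_run_config(config)
  if (is.null(cfg$out_dir)) stop("config must name an out_dir")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- do.call(islet_image_params, as.list(cfg$params))
  files <- lapply(seq_len(cfg$n_sections), function(i) {
    sim <- generate_islet_image(params, seed = cfg$seed + i - 1L,
                                animal_id = cfg$animal_id,
                                series_index = i - 1L)
    stem <- sprintf("%s_s%02d", cfg$animal_id, i - 1L)
    img_path <- file.path(cfg$out_dir, paste0("section_", stem, ".tiff"))
    msk_path <- file.path(cfg$out_dir, paste0("mask_", stem, ".tiff"))
    tru_path <- file.path(cfg$out_dir, paste0("truth_", stem, ".json"))
    s <- sim$section
    rgb <- array(0, c(nrow(s$red), ncol(s$red), 3L))
    rgb[, , 1L] <- s$red; rgb[, , 2L] <- s$green; rgb[, , 3L] <- s$blue
    write_image_16bit(rgb, img_path)
    write_image_16bit(sim$mask, msk_path)
    tr <- sim$truth
    jsonlite::write_json(
      list(n_islets = tr$n_islets,
           islet_areas_um2 = tr$islet_areas_um2,
           true_beta_fraction_per_islet = tr$true_beta_fraction_per_islet,
           true_beta_percent_pooled = tr$true_beta_percent_pooled,
           equiv_diameters_um = tr$equiv_diameters_um,
           counts_by_class = as.list(tr$counts_by_class),
           seed = tr$seed),
      tru_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    data.frame(section = img_path, mask = msk_path, truth = tru_path,
               stringsAsFactors = FALSE)
  })
  write_manifest(cfg, cfg$out_dir,
                 extra = list(mode = "simulate", params = unclass(params)))
  invisible(do.call(rbind, files))
}

#' Measure an islet image dataset
#'
#' Runs the full morphometry pipeline over `section_*` / `mask_*` image
#' pairs in the input directory (the naming convention written by
#' [run_simulate()]): channel splitting, bleed-through correction,
#' per-islet Otsu/Kapur segmentation, area and diameter morphometry, and
#' size classification.  Outputs are a per-islet CSV, a per-section CSV,
#' a per-animal summary CSV, and a manifest; identical inputs and config
#' give byte-identical outputs.  Any image/mask dimension mismatch
#' aborts the run, naming the offending pair, and removes partial
#' outputs.
#'
#' @param config YAML path or list with `in_dir` and `out_dir`; optional
#'   `pixel_size_um`, `connectivity`, `n_bins`, `size_cutoff_um`.
#' @return Invisibly, a list with `islets`, `sections` and `animals`
#'   data.frames.
#' @export
run_measure <- function(config) {
  cfg <- read_run_config(config)
  if (is.null(cfg$in_dir) || is.null(cfg$out_dir))
    stop("config must name in_dir and out_dir")
  sections <- sort(list.files(cfg$in_dir, "^section_.*\\.tiff?$",
                              full.names = TRUE))
  out_files <- file.path(cfg$out_dir,
                         c("per_islet.csv", "per_section.csv",
                           "per_animal.csv", "manifest.json"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  on_fail <- function(e) {
    unlink(out_files)
    stop(e)
  }
  tryCatch({
    rows <- lapply(sections, function(img_path) {
      msk_path <- sub("(^|/)section_", "\\1mask_", img_path)
      if (!file.exists(msk_path))
        stop("no mask image for ", basename(img_path))
      stem <- sub("\\.tiff?$", "", sub("^section_", "", basename(img_path)))
      series <- suppressWarnings(
        as.integer(sub(".*_s([0-9]+)$", "\\1", stem)))
      animal <- sub("_s[0-9]+$", "", stem)
      section <- read_section_image(img_path,
                                    pixel_size_um = cfg$pixel_size_um,
                                    animal_id = animal,
                                    series_index = if (is.na(series)) 0L
                                                   else series)
      regions <- tryCatch(
        read_islet_masks(msk_path, section,
                         connectivity = cfg$connectivity),
        error = function(e) stop("pair ", basename(img_path), " / ",
                                 basename(msk_path), ": ",
                                 conditionMessage(e)))
      measure_section(section, regions, n_bins = cfg$n_bins,
                      cutoff_um = cfg$size_cutoff_um)
    })
    islets <- if (length(rows) > 0L) do.call(rbind, rows)
              else empty_measurement_frame()
    sections_df <- summarize_sections(islets)
    animals <- if (nrow(islets) > 0L) {
      do.call(rbind, lapply(split(islets, islets$animal_id),
                            summarize_pancreas))
    } else summarize_pancreas(islets, animal_id = cfg$animal_id)
    rownames(animals) <- NULL
    write_measurements(islets, out_files[1L])
    write_measurements(sections_df, out_files[2L])
    write_measurements(animals, out_files[3L])
    write_manifest(cfg, cfg$out_dir,
                   extra = list(mode = "measure",
                                n_sections_processed = length(sections)))
    invisible(list(islets = islets, sections = sections_df,
                   animals = animals))
  }, error = on_fail)
}

#' Analyze a secretion assay table
#'
#' Applies the assay normalizations to a table of secretion samples:
#' fold over the basal condition, stimulation index per sample (in the
#' configured mode), per-condition summaries, and — when the table
#' carries a `dose_uM` column — a four-parameter logistic dose--response
#' fit.
#'
#' @param config YAML path or list with `samples` (a data.frame or CSV
#'   path with columns `condition`, `secreted_ng_ml`, optionally
#'   `content_ng_ml`, `dose_uM`), optional `basal_condition`,
#'   `index_mode`, `fix_bottom`, and optional `out_dir` for CSV output.
#' @return A list with `samples` (augmented table), `conditions`
#'   (per-condition means/sd), and `fit` (a [fit_dose_response()] result
#'   or `NULL`).
#' @export
run_assay <- function(config) {
  cfg <- read_run_config(config)
  samples <- cfg$samples
  if (is.character(samples)) samples <- utils::read.csv(samples)
  if (!is.data.frame(samples)) stop("config must provide a samples table")
  samples <- fold_over_basal(samples, cfg$basal_condition)
  if (!is.null(samples$content_ng_ml) && any(!is.na(samples$content_ng_ml)))
    samples$stim_index_percent <- ifelse(
      is.na(samples$content_ng_ml), NA_real_,
      stimulation_index(samples$secreted_ng_ml,
                        ifelse(is.na(samples$content_ng_ml), 1,
                               samples$content_ng_ml),
                        mode = cfg$index_mode))
  conditions <- do.call(rbind, lapply(split(samples, samples$condition),
    function(g) data.frame(
      condition = g$condition[1L], n = nrow(g),
      mean_secreted_ng_ml = mean(g$secreted_ng_ml),
      sd_secreted_ng_ml = stats::sd(g$secreted_ng_ml),
      mean_fold = mean(g$fold_over_basal),
      mean_stim_index = if (is.null(g$stim_index_percent)) NA_real_
                        else mean(g$stim_index_percent),
      stringsAsFactors = FALSE)))
  rownames(conditions) <- NULL
  fit <- NULL
  if (!is.null(samples$dose_uM)) {
    keep <- !is.na(samples$dose_uM) & samples$dose_uM > 0
    fit <- fit_dose_response(samples$dose_uM[keep],
                             samples$fold_over_basal[keep],
                             fix_bottom = cfg$fix_bottom)
  }
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_measurements(samples, file.path(cfg$out_dir, "assay_samples.csv"))
    write_measurements(conditions,
                       file.path(cfg$out_dir, "assay_conditions.csv"))
    write_manifest(cfg[setdiff(names(cfg), "samples")], cfg$out_dir,
                   extra = list(mode = "assay"))
  }
  list(samples = samples, conditions = conditions, fit = fit)
}
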