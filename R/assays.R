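#' Fold change over the basal (non-stimulated) condition
#'
#' Normalizes secreted hormone concentrations to the mean of the basal
#' group, the standard presentation for static islet secretion assays:
#' each sample's fold is its concentration divided by the basal mean, so
#' the basal samples themselves average to 1.  Folds are scale-invariant
#' (multiplying every concentration by a constant changes nothing).
#'
#' @param samples data.frame with at least `condition` and
#'   `secreted_ng_ml` columns (see [generate_secretion_data()]).
#' @param basal_condition the condition label of the non-stimulated
#'   group (default `"basal"`).
#' @return The input data.frame with an added `fold_over_basal` column.
#' @export
fold_over_basal <- function(samples, basal_condition = "basal") {
  stopifnot(is.data.frame(samples),
            all(c("condition", "secreted_ng_ml") %in% names(samples)))
  basal <- samples$secreted_ng_ml[samples$condition == basal_condition]
  if (length(basal) == 0L)
    stop("no samples with basal condition '", basal_condition, "'")
  m <- mean(basal)
  if (!is.finite(m) || m <= 0)
    stop("basal mean is not positive; fold over basal is undefined")
  samples$fold_over_basal <- samples$secreted_ng_ml / m
  samples
}

#' Stimulation index: secretion as a percentage of hormone content
#'
#' Expresses secreted hormone relative to the preparation's hormone
#' content, normalizing secretion for the amount of tissue.  In
#' `"total"` mode (default) the denominator is the total content,
#' i.e. secreted plus residual lysate content:
#' \eqn{100 \cdot s / (s + c)}.  In `"lysate"` mode the denominator is
#' the lysate content alone: \eqn{100 \cdot s / c}.
#'
#' @param secreted non-negative secreted concentration(s).
#' @param residual_content non-negative lysate (residual) hormone
#'   content, same length.
#' @param mode `"total"` or `"lysate"`.
#' @return Numeric percentage(s); in `"total"` mode always in
#'   \[0, 100\].
#' @export
stimulation_index <- function(secreted, residual_content,
                              mode = c("total", "lysate")) {
  mode <- match.arg(mode)
  if (any(secreted < 0) || any(residual_content < 0))
    stop("concentrations must be non-negative")
  if (any(secreted + residual_content == 0))
    stop("secreted and content both zero: stimulation index undefined")
  if (mode == "total") 100 * secreted / (secreted + residual_content)
  else {
    if (any(residual_content == 0))
      stop("lysate content is zero: lysate-mode index undefined")
    100 * secreted / residual_content
  }
}

#' Fit a four-parameter logistic dose--response curve
#'
#' Least-squares fit of
#' \deqn{r(d) = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}
#'   {1 + (\mathrm{EC}_{50}/d)^{\mathrm{hill}}}}
#' with the EC50 parameterized on the log scale for stable optimization.
#' The EC50 standard error comes from the local curvature of the
#' objective (delta method on the fitted log-EC50).  Degenerate data
#' (constant responses) return a non-converged result rather than an
#' error.
#'
#' @param doses_uM positive dose vector, micromolar.
#' @param responses response vector, same length (e.g. fold over basal).
#' @param fix_bottom optionally pin the lower asymptote (e.g. 1 on the
#'   fold scale, where the basal response defines the unit).
#' @return A `dose_response_fit`: list with `ec50`, `se_ec50`, `hill`,
#'   `bottom`, `top`, `converged`, `extrapolated` (EC50 outside the
#'   dose support), and the underlying `fit` object (or `NULL`).
#' @export
fit_dose_response <- function(doses_uM, responses, fix_bottom = NULL) {
  stopifnot(length(doses_uM) == length(responses), all(doses_uM > 0))
  n_distinct <- length(unique(doses_uM))
  needed <- if (is.null(fix_bottom)) 4L else 3L
  if (n_distinct < needed)
    stop("need >= ", needed, " distinct doses for this fit")
  failed <- function() structure(
    list(ec50 = NA_real_, se_ec50 = NA_real_, hill = NA_real_,
         bottom = if (is.null(fix_bottom)) NA_real_ else fix_bottom,
         top = NA_real_, converged = FALSE, extrapolated = NA, fit = NULL),
    class = "dose_response_fit")
  if (stats::sd(responses) == 0) return(failed())

  ld <- log(doses_uM)
  # starts: asymptotes from the data range, EC50 near the half-response
  lo <- min(responses); hi <- max(responses)
  half <- (lo + hi) / 2
  lec0 <- ld[which.min(abs(responses - half))]
  df <- data.frame(ld = ld, resp = responses)
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-13, ptol = 1e-13,
                                     maxiter = 500)
  fit <- tryCatch({
    if (is.null(fix_bottom)) {
      minpack.lm::nlsLM(
        resp ~ bottom + (top - bottom) / (1 + exp(hill * (lec - ld))),
        data = df,
        start = list(bottom = lo, top = hi, lec = lec0, hill = 1),
        control = ctrl)
    } else {
      b <- fix_bottom
      minpack.lm::nlsLM(
        resp ~ b + (top - b) / (1 + exp(hill * (lec - ld))),
        data = df,
        start = list(top = hi, lec = lec0, hill = 1),
        control = ctrl)
    }
  }, error = function(e) NULL)
  if (is.null(fit) || !fit$convInfo$isConv) return(failed())
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(cf)))
  ec50 <- exp(cf[["lec"]])
  structure(
    list(ec50 = ec50,
         se_ec50 = ec50 * unname(se["lec"]),  # delta method on log-EC50
         hill = cf[["hill"]],
         bottom = if (is.null(fix_bottom)) cf[["bottom"]] else fix_bottom,
         top = cf[["top"]],
         converged = TRUE,
         extrapolated = ec50 < min(doses_uM) || ec50 > max(doses_uM),
         fit = fit),
    class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<dose_response_fit> not converged\n")
  } else {
    cat(sprintf(
      "<dose_response_fit> EC50 = %.4g +/- %.3g uM, hill %.3g, [%.3g, %.3g]%s\n",
      x$ec50, x$se_ec50, x$hill, x$bottom, x$top,
      if (isTRUE(x$extrapolated)) " (extrapolated)" else ""))
  }
  invisible(x)
}

#' Delta-Ct normalization of qPCR cycle thresholds
#'
#' Normalizes a target gene's Ct to a reference gene (e.g. beta-actin):
#' \eqn{\Delta Ct = Ct_{target} - Ct_{ref}} and relative expression
#' \eqn{2^{-\Delta Ct}}, which halves for every additional cycle.
#' Technical replicates should be averaged on the Ct scale before
#' calling (mean-then-subtract).
#'
#' @param ct_target,ct_reference finite Ct value(s); vectorized
#'   elementwise.
#' @return A list with `delta_ct` and `relative_expression`.
#' @export
delta_ct <- function(ct_target, ct_reference) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference)))
    stop("Ct values must be finite")
  d <- ct_target - ct_reference
  list(delta_ct = d, relative_expression = 2^(-d))
}

#' Relative expression as percent of a control group
#'
#' @param rel_expression relative expression(s), `2^(-delta Ct)`.
#' @param rel_control the control group's relative expression.
#' @return `100 * rel_expression / rel_control`.
#' @export
percent_of_control <- function(rel_expression, rel_control) {
  if (any(rel_control <= 0)) stop("control expression must be positive")
  100 * rel_expression / rel_control
}

#' Construct a fura-2 calcium trace
#'
#' Background-corrected F340 and F380 intensity time series from
#' ratiometric Ca2+ imaging, sampled at fixed intervals over square
#' regions of interest.
#'
#' @param f340,f380 equal-length numeric vectors of background-corrected
#'   intensities; `f380` must be strictly positive for the ratio to be
#'   valid.
#' @param time_step_s sampling interval, seconds (default 2).
#' @param roi_side_um ROI square side length, micrometers (default 13).
#' @return A `ca_trace` object.
#' @export
ca_trace <- function(f340, f380, time_step_s = 2, roi_side_um = 13) {
  if (length(f340) != length(f380))
    stop("f340 and f380 must have equal length")
  if (time_step_s <= 0) stop("time_step_s must be positive")
  structure(list(f340 = as.numeric(f340), f380 = as.numeric(f380),
                 time_step_s = time_step_s, roi_side_um = roi_side_um),
            class = "ca_trace")
}

#' Delta ratio of a fura-2 trace
#'
#' Computes the ratio series \eqn{F340/F380} and the delta ratio: mean
#' ratio over a response window minus mean ratio over a baseline window.
#' The response window is the post-application window (a mean, not a
#' peak, following the usual presentation of agonist-evoked Ca2+
#' responses).
#'
#' @param trace a [ca_trace()].
#' @param baseline_window,response_window integer index vectors into the
#'   trace.
#' @return A list with `ratio` (full series) and `delta_ratio`.
#' @export
ca_delta_ratio <- function(trace, baseline_window, response_window) {
  stopifnot(inherits(trace, "ca_trace"))
  n <- length(trace$f340)
  w <- c(baseline_window, response_window)
  if (any(w < 1L) || any(w > n))
    stop("window indices outside the trace (length ", n, ")")
  if (any(trace$f380[w] <= 0))
    stop("f380 must be strictly positive within the analysis windows")
  ratio <- trace$f340 / trace$f380
  list(ratio = ratio,
       delta_ratio = mean(ratio[response_window]) -
         mean(ratio[baseline_window]))
}
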