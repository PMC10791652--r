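test_that("fold over basal normalizes to the basal mean and is scale invariant", {
  df <- data.frame(condition = c("basal", "basal", "stim"),
                   secreted_ng_ml = c(1, 3, 4))
  out <- fold_over_basal(df)
  expect_equal(out$fold_over_basal, c(0.5, 1.5, 2))
  expect_equal(mean(out$fold_over_basal[out$condition == "basal"]), 1)

  # printed-condition case: basal mean 1.9 ng/ml, stimulated 2.7-fold
  df2 <- data.frame(condition = c("basal", "p116_2mM"),
                    secreted_ng_ml = c(1.9, 1.9 * 2.7))
  expect_equal(fold_over_basal(df2)$fold_over_basal[2], 2.7)

  # all equal to basal mean -> all folds 1
  df3 <- data.frame(condition = c("basal", "x", "y"),
                    secreted_ng_ml = rep(2.5, 3))
  expect_equal(fold_over_basal(df3)$fold_over_basal, rep(1, 3))

  # scale invariance
  for (c_scale in c(0.1, 7)) {
    scaled <- df; scaled$secreted_ng_ml <- scaled$secreted_ng_ml * c_scale
    expect_equal(fold_over_basal(scaled)$fold_over_basal,
                 out$fold_over_basal)
  }
  expect_error(fold_over_basal(data.frame(condition = "stim",
                                          secreted_ng_ml = 1)), "basal")
  expect_error(fold_over_basal(data.frame(condition = "basal",
                                          secreted_ng_ml = 0)),
               "not positive")
})

test_that("stimulation index respects bounds, boundaries and monotonicity", {
  expect_equal(stimulation_index(1, 9), 10)
  expect_equal(stimulation_index(5, 0), 100)
  expect_equal(stimulation_index(0, 5), 0)
  expect_error(stimulation_index(0, 0), "undefined")
  withr::local_seed(3)
  s <- runif(50, 0, 10); c0 <- runif(50, 0, 10) + 0.01
  idx <- stimulation_index(s, c0)
  expect_true(all(idx >= 0 & idx <= 100))
  # increasing secreted raises, increasing content lowers the index
  expect_true(all(stimulation_index(s + 1, c0) > idx))
  expect_true(all(stimulation_index(s + 0.01, c0 + 1) <
                    stimulation_index(s + 0.01, c0)))
  # lysate mode uses content alone as denominator
  expect_equal(stimulation_index(1, 4, mode = "lysate"), 25)
})

test_that("noise-free 4PL data are recovered to near machine precision", {
  d <- generate_dose_response(sigma = 0)
  fit <- fit_dose_response(d$dose_uM, d$response)
  expect_true(fit$converged)
  expect_lt(abs(fit$ec50 - 950) / 950, 1e-6)
  expect_lt(abs(fit$hill - 1), 1e-6)
  expect_lt(abs(fit$bottom - 1), 1e-6)
  expect_lt(abs(fit$top - 2.7) / 2.7, 1e-6)
  expect_false(fit$extrapolated)
  # same with the lower asymptote pinned to the fold unit
  fitb <- fit_dose_response(d$dose_uM, d$response, fix_bottom = 1)
  expect_lt(abs(fitb$ec50 - 950) / 950, 1e-6)
})

test_that("degenerate dose-response data yield an honest non-converged result", {
  fit <- fit_dose_response(c(1, 10, 100, 1000), rep(2, 4))
  expect_false(fit$converged)
  expect_true(is.na(fit$ec50))
  expect_error(fit_dose_response(c(1, 1, 10), c(1, 2, 3)), "distinct doses")
})

test_that("noisy EC50 estimates land within three standard errors of truth", {
  d <- generate_dose_response(sigma = 0.1, seed = 42)
  fit <- fit_dose_response(d$dose_uM, d$response, fix_bottom = 1)
  expect_true(fit$converged)
  expect_lt(abs(fit$ec50 - 950), 3 * fit$se_ec50)
})

test_that("delta-Ct halves relative expression per cycle, exactly", {
  out <- delta_ct(25, 20)
  expect_equal(out$delta_ct, 5)
  expect_equal(out$relative_expression, 0.03125)
  expect_equal(delta_ct(20, 20)$relative_expression, 1)
  # halving property over a range of Ct gaps
  d <- delta_ct(20 + 0:10, 20)
  expect_equal(d$relative_expression[-1] / d$relative_expression[-11],
               rep(0.5, 10))
  # technical replicates averaged on the Ct scale before subtraction
  expect_equal(delta_ct(mean(c(24.9, 25.0, 25.1)), 20)$delta_ct, 5)
  expect_equal(percent_of_control(0.5, 0.25), 200)
  expect_error(delta_ct(NA, 20), "finite")
})

test_that("fura-2 delta ratio subtracts baseline from response window means", {
  tr <- ca_trace(c(100, 200), c(100, 100))
  out <- ca_delta_ratio(tr, baseline_window = 1L, response_window = 2L)
  expect_equal(out$ratio, c(1, 2))
  expect_equal(out$delta_ratio, 1)
  # identical windows -> zero delta
  expect_equal(ca_delta_ratio(tr, 1:2, 1:2)$delta_ratio, 0)
  expect_error(ca_delta_ratio(tr, 1L, 3L), "outside")
  expect_error(ca_delta_ratio(ca_trace(c(1, 1), c(1, 0)), 1L, 2L),
               "strictly positive")

  # seeded synthetic step: recovered delta within noise SE of truth
  g <- generate_ca_trace(seed = 9)
  got <- ca_delta_ratio(g$trace, g$baseline_window, g$response_window)
  se <- 2 * 5 / 500 / sqrt(min(lengths(g[c("baseline_window",
                                           "response_window")])))
  expect_lt(abs(got$delta_ratio - g$true_delta), 3 * se)
})

test_that("secretion generator hits stated means, folds and indices", {
  # cv 0: samples equal their group means; fold equals the design ratio
  d0 <- generate_secretion_data(n_per_group = 4, cv = 0, seed = 1)
  expect_true(all(d0$secreted_ng_ml[d0$condition == "basal"] == 1.9))
  f <- fold_over_basal(d0)
  expect_equal(unique(f$fold_over_basal[f$condition == "p116_2mM"]), 2.7)
  # content generated jointly: stimulation index equals its stated truth
  expect_equal(stimulation_index(d0$secreted_ng_ml, d0$content_ng_ml),
               rep(10, nrow(d0)))
  # CLT check at cv 0.3, n 8: standardized group-mean errors behave like
  # z-scores across seeds (unit spread, no drift, no wild outliers)
  z <- unlist(lapply(1:20, function(seed) {
    dn <- generate_secretion_data(n_per_group = 8, cv = 0.3, seed = seed)
    vapply(unique(dn$condition), function(cond) {
      x <- dn$secreted_ng_ml[dn$condition == cond]
      mu <- c(basal = 1.9, p116_2mM = 1.9 * 2.7)[[cond]]
      (mean(x) - mu) / (mu * 0.3 / sqrt(8))
    }, numeric(1))
  }))
  expect_lt(abs(mean(z)), 3 / sqrt(length(z)))
  expect_lt(max(abs(z)), 4.5)
  expect_gte(sum(abs(z) <= 3), length(z) - 1L)
})
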