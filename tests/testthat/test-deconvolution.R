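test_that("a noiseless single pseudo-Voigt is recovered to 1e-3 relative", {
  axis <- default_axis()
  truth <- pv_band(1300, 24, 0.3, 2)
  spec <- pseudo_voigt(axis, truth)
  fit <- fit_peak_sum(spec, axis, list(pv_band(1305, 18, 0.5, 1)))
  b <- fit$bands[[1]]
  expect_lt(abs(b$center - truth$center) / truth$center, 1e-3)
  expect_lt(abs(b$fwhm - truth$fwhm) / truth$fwhm, 1e-3)
  expect_lt(abs(b$eta - truth$eta) / truth$eta, 1e-3)
  expect_lt(abs(b$amplitude - truth$amplitude) / truth$amplitude, 1e-3)
  expect_true(fit$converged)
})

test_that("fitting never worsens the initialisation residual", {
  axis <- default_axis()
  set.seed(1)
  spec <- pseudo_voigt(axis, pv_band(1400, 30, 0.7, 1.5)) +
    rnorm(length(axis), 0, 0.05)
  init <- list(pv_band(1395, 20, 0.2, 0.5))
  fit <- fit_peak_sum(spec, axis, init)
  rms0 <- sqrt(mean((spec - sum_bands(axis, init))^2))
  expect_lte(fit$residual_rms, rms0)
})

test_that("two separated noisy bands are located within 1 cm-1", {
  axis <- default_axis()
  set.seed(2)
  spec <- pseudo_voigt(axis, pv_band(1200, 20, 0.4, 2)) +
    pseudo_voigt(axis, pv_band(1600, 26, 0.6, 1.4)) +
    rnorm(length(axis), 0, 0.01)
  fit <- fit_peak_sum(spec, axis,
                      list(pv_band(1205, 18, 0.5, 1), pv_band(1595, 18, 0.5, 1)))
  centers <- sort(vapply(fit$bands, `[[`, numeric(1), "center"))
  expect_lt(abs(centers[1] - 1200), 1)
  expect_lt(abs(centers[2] - 1600), 1)
})

test_that("self-projection returns unit scales and orthogonal samples return zero", {
  axis <- default_axis()
  ref <- fit_peak_sum(sum_bands(axis, albumin_reference_bands()), axis,
                      albumin_reference_bands())
  self <- project_reference(ref$fitted, ref)
  expect_equal(unname(self$scale_amplitudes),
               rep(1, length(ref$bands)), tolerance = 1e-6)
  # sample supported far away from every albumin band
  far <- pseudo_voigt(axis, pv_band(1895, 10, 0.5, 1))
  far[axis < 1850] <- 0
  off <- project_reference(far, ref)
  # Lorentzian tails reach everywhere, so the scales are tiny, not exact zeros
  expect_lt(max(off$scale_amplitudes), 0.01)
  expect_error(project_reference(far[-1], ref), "different axes")
})

test_that("mixture deconvolution recovers the albumin share and the EV spectrum", {
  axis <- default_axis()
  alb <- sum_bands(axis, albumin_reference_bands())
  tmpl <- default_group_templates()
  bt <- read_band_table()
  set.seed(3)
  for (g in c("SEC", "TEIR")) {
    ev <- sum_bands(axis, tmpl[[g]])
    rows <- bt[bt$method == g & bt$modality == "AFM-IR", ]
    evb <- lapply(rows$wn_mid, pv_band, fwhm = 18, eta = 0.5, amplitude = 1)
    mix <- ev + 0.4 * alb + rnorm(length(axis), 0, 0.02)
    d <- deconvolute(mix, alb, axis, ev_bands = evb)
    true_share <- sum(abs(0.4 * alb)) / sum(abs(mix))
    expect_lt(abs(d$fraction_removed - true_share), 0.05)
    rel_rms <- sqrt(mean((d$ev_estimate - ev)^2)) / sqrt(mean(ev^2))
    expect_lt(rel_rms, 0.10)
    expect_equal(d$ev_estimate + d$contribution, mix)
    expect_true(all(d$scale_amplitudes >= 0))
  }
})

test_that("albumin-free and pure-albumin limits behave", {
  axis <- default_axis()
  alb <- sum_bands(axis, albumin_reference_bands())
  tmpl <- default_group_templates()
  bt <- read_band_table()
  rows <- bt[bt$method == "SEC" & bt$modality == "AFM-IR", ]
  evb <- lapply(rows$wn_mid, pv_band, fwhm = 18, eta = 0.5, amplitude = 1)
  ev <- sum_bands(axis, tmpl$SEC)
  d0 <- deconvolute(ev, alb, axis, ev_bands = evb)
  expect_lt(sqrt(sum(d0$contribution^2) / sum(ev^2)), 0.1)
  dp <- deconvolute(alb, alb, axis)
  expect_lt(sqrt(sum(dp$ev_estimate^2) / sum(alb^2)), 0.1)
})

test_that("estimated albumin share is monotone in the true mixing fraction", {
  axis <- default_axis()
  alb <- sum_bands(axis, albumin_reference_bands())
  tmpl <- default_group_templates()
  bt <- read_band_table()
  rows <- bt[bt$method == "UC" & bt$modality == "AFM-IR", ]
  evb <- lapply(rows$wn_mid, pv_band, fwhm = 18, eta = 0.5, amplitude = 1)
  ev <- sum_bands(axis, tmpl$UC)
  set.seed(4)
  fracs <- rep(c(0, 0.2, 0.4, 0.6), each = 5)
  est <- vapply(seq_along(fracs), function(i) {
    mix <- ev + fracs[i] * alb + rnorm(length(axis), 0, 0.02)
    deconvolute(mix, alb, axis, ev_bands = evb)$fraction_removed
  }, numeric(1))
  means <- tapply(est, fracs, mean)
  expect_true(all(diff(means) > 0))
})

test_that("group-average deconvolution runs on a generated set", {
  cfg <- generator_config(n_per_group = 5, seed = 41)
  pre <- preprocess_pipeline(generate_dataset(cfg))
  ref <- total_intensity_normalize(
    lieber_baseline(sum_bands(pre$axis, cfg$albumin_bands), pre$axis)$corrected)
  res <- deconvolute_groups(pre, ref)
  expect_named(res, unique(pre$labels))
  for (r in res) {
    expect_true(all(r$scale_amplitudes >= 0))
    expect_true(r$fraction_removed >= 0 && r$fraction_removed <= 1)
  }
  # the high-corona group sheds a larger albumin share than the low one
  expect_gt(res$UC$fraction_removed, res$SEC$fraction_removed)
})
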