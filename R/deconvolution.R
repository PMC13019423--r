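# Albumin corona deconvolution: fit the albumin reference spectrum as a sum
# of pseudo-Voigt lineshapes, project that model into each EV spectrum by
# nonnegative per-band rescaling, and subtract it to estimate the pure EV
# spectrum.

.pack_params <- function(bands) {
  unlist(lapply(bands, function(b) c(b$center, b$fwhm, b$eta, b$amplitude)))
}

.unpack_params <- function(par, template) {
  lapply(seq_along(template), function(k) {
    v <- par[(4 * (k - 1) + 1):(4 * k)]
    pv_band(v[1], max(v[2], 1e-6), min(max(v[3], 0), 1), max(v[4], 0),
            template[[k]]$assignment)
  })
}

#' Fit a sum of pseudo-Voigt bands to a spectrum
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) over
#' `(center, fwhm, eta, amplitude)` for every band: centres may move at most
#' `center_window` cm-1 from their initialisation, FWHMs stay positive,
#' `eta` stays in `[0, 1]` and amplitudes stay nonnegative. The result never
#' has a worse residual than the initialisation.
#'
#' @param spectrum numeric intensity vector (baseline-corrected).
#' @param axis wavenumber axis.
#' @param initial_bands nonempty list of [pv_band()] starting values.
#' @param center_window half-width of the centre box constraint, cm-1.
#' @param max_iter optimizer iteration cap.
#' @return Object of class `peak_fit` with `bands` (fitted), `residual_rms`,
#'   `n_evaluations`, `converged`, `fitted` (model spectrum on `axis`).
#' @export
fit_peak_sum <- function(spectrum, axis, initial_bands, center_window = 10,
                         max_iter = 200) {
  if (!length(initial_bands)) stop("initial_bands must be nonempty")
  if (length(spectrum) != length(axis)) stop("spectrum/axis length mismatch")
  p0 <- .pack_params(initial_bands)
  k <- length(initial_bands)
  lower <- rep(c(-Inf, 1e-3, 0, 0), k)
  upper <- rep(c(Inf, Inf, 1, Inf), k)
  idx_c <- 4 * (seq_len(k) - 1) + 1
  lower[idx_c] <- p0[idx_c] - center_window
  upper[idx_c] <- p0[idx_c] + center_window
  resid_fun <- function(par) {
    sum_bands(axis, .unpack_params(par, initial_bands)) - spectrum
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                       fn = resid_fun,
                       control = minpack.lm::nls.lm.control(maxiter = max_iter)),
    error = function(e) NULL)
  rms0 <- sqrt(mean(resid_fun(p0)^2))
  if (is.null(fit)) {
    bands <- initial_bands
    rms <- rms0
    nev <- 0L
    converged <- FALSE
  } else {
    bands <- .unpack_params(fit$par, initial_bands)
    rms <- sqrt(mean(resid_fun(fit$par)^2))
    nev <- fit$niter
    converged <- fit$info %in% 1:4
    if (rms > rms0) {       # keep the better of start and fit
      bands <- initial_bands; rms <- rms0; converged <- FALSE
    }
  }
  structure(list(bands = bands, residual_rms = rms, n_evaluations = nev,
                 converged = converged,
                 fitted = sum_bands(axis, bands), axis = axis),
            class = "peak_fit")
}

#' Project a fitted reference model into a sample spectrum
#'
#' Holds the fitted centres, widths and shapes fixed and solves a
#' nonnegative least-squares problem for per-band amplitude multipliers
#' minimising the residual between the sample and the scaled band sum.
#' A multiplier of 1 reproduces the reference fit's band unchanged.
#'
#' An albumin band overlapping a sample's own vibrational band is not
#' identifiable from the sample alone: the plain projection would soak up
#' sample intensity into the reference. Supplying `ev_bands` — candidate
#' sample bands, e.g. the assignment-table positions for the sample's
#' isolation method — adds them as nuisance regressors in the same
#' nonnegative fit, so sample intensity near its own band positions is
#' explained by the sample's bands and only the reference-shaped remainder
#' is attributed to the contaminant.
#'
#' @param sample_spectrum numeric vector on the reference fit's axis.
#' @param reference_fit a [fit_peak_sum()] result.
#' @param scale_mode `"per-band"` (one nonnegative multiplier per reference
#'   band, the default) or `"global"` (a single shared multiplier).
#' @param ev_bands optional list of [pv_band()] nuisance bands for the
#'   sample's own spectrum.
#' @return List with `scale_amplitudes` (>= 0, one per reference band or one
#'   shared) and `contribution` (the scaled reference band sum only).
#' @export
project_reference <- function(sample_spectrum, reference_fit,
                              scale_mode = c("per-band", "global"),
                              ev_bands = NULL) {
  scale_mode <- match.arg(scale_mode)
  axis <- reference_fit$axis
  if (length(sample_spectrum) != length(axis))
    stop("sample and reference fit are on different axes")
  shapes <- vapply(reference_fit$bands, function(b) pseudo_voigt(axis, b),
                   numeric(length(axis)))
  nuisance <- if (length(ev_bands))
    vapply(ev_bands, function(b)
      pseudo_voigt(axis, pv_band(b$center, b$fwhm, b$eta, 1, b$assignment)),
      numeric(length(axis)))
  else NULL
  k <- length(reference_fit$bands)
  if (scale_mode == "global") {
    design <- cbind(rowSums(shapes), nuisance)
    nn <- pracma::lsqnonneg(design, sample_spectrum)
    scales <- rep(nn$x[1], k)
    contribution <- nn$x[1] * design[, 1]
  } else {
    design <- cbind(shapes, nuisance)
    nn <- pracma::lsqnonneg(design, sample_spectrum)
    scales <- nn$x[seq_len(k)]
    contribution <- drop(shapes %*% scales)
  }
  list(scale_amplitudes = scales, contribution = contribution)
}

#' Deconvolute the albumin contribution out of a spectrum
#'
#' Fits the albumin reference as a pseudo-Voigt band sum, projects it into
#' the sample with nonnegative per-band rescaling, and subtracts it, so
#' `ev_estimate + contribution == sample` pointwise.
#'
#' @param sample_spectrum sample intensities (preprocessed like the
#'   reference).
#' @param reference_spectrum albumin reference intensities on the same axis.
#' @param axis shared wavenumber axis.
#' @param initial_reference_bands starting band list for the reference fit;
#'   defaults to [albumin_reference_bands()].
#' @param scale_mode see [project_reference()].
#' @param ev_bands optional nuisance bands for the sample's own spectrum,
#'   passed to [project_reference()].
#' @return Object of class `deconvolution_result` with `reference_fit`,
#'   `contribution`, `ev_estimate`, `scale_amplitudes`, `fraction_removed`
#'   (`sum|contribution| / sum|sample|`).
#' @export
deconvolute <- function(sample_spectrum, reference_spectrum, axis,
                        initial_reference_bands = albumin_reference_bands(),
                        scale_mode = "per-band", ev_bands = NULL) {
  ref_fit <- fit_peak_sum(reference_spectrum, axis, initial_reference_bands)
  pr <- project_reference(sample_spectrum, ref_fit, scale_mode, ev_bands)
  structure(list(reference_fit = ref_fit,
                 contribution = pr$contribution,
                 ev_estimate = sample_spectrum - pr$contribution,
                 scale_amplitudes = pr$scale_amplitudes,
                 fraction_removed = sum(abs(pr$contribution)) /
                   sum(abs(sample_spectrum))),
            class = "deconvolution_result")
}

#' Group-average deconvolution of a spectra set
#'
#' Computes each group's average spectrum and removes the fitted albumin
#' contribution from it. When the group name has AFM-IR rows in the
#' assignment table, those band positions are used as the group's nuisance
#' bands in the projection.
#'
#' @param set a preprocessed [spectra_set()].
#' @param reference_spectrum albumin reference on the set's axis.
#' @param band_table assignment table supplying per-group nuisance band
#'   positions; `NULL` disables nuisance bands.
#' @param fwhm,eta lineshape defaults for the nuisance bands.
#' @param ... passed to [deconvolute()].
#' @return Named list of `deconvolution_result`, one per group.
#' @export
deconvolute_groups <- function(set, reference_spectrum,
                               band_table = read_band_table(),
                               fwhm = 18, eta = 0.5, ...) {
  groups <- unique(set$labels)
  out <- lapply(groups, function(g) {
    avg <- colMeans(set$intensities[set$labels == g, , drop = FALSE])
    ev_bands <- NULL
    if (!is.null(band_table)) {
      rows <- band_table[band_table$method == g &
                           band_table$modality == "AFM-IR", , drop = FALSE]
      if (nrow(rows))
        ev_bands <- lapply(rows$wn_mid, pv_band, fwhm = fwhm, eta = eta,
                           amplitude = 1)
    }
    deconvolute(avg, reference_spectrum, set$axis, ev_bands = ev_bands, ...)
  })
  names(out) <- groups
  out
}
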