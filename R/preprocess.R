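# Preprocessing: Lieber-Mahadevan-Jansen iterative polynomial baseline
# correction, total-intensity normalisation, and mean-centering.

#' Iterative polynomial baseline correction
#'
#' The Lieber & Mahadevan-Jansen modified polyfit: fit a least-squares
#' polynomial of the given order to the working spectrum, clamp every working
#' value above the fit down to the fit, and repeat until the fit changes by
#' less than `tol` in max norm (or `max_iter` is reached). Peaks are clamped
#' away; the slowly varying background that remains is the baseline.
#'
#' @param spectrum numeric intensity vector.
#' @param axis wavenumber axis (only its geometry matters; defaults to an
#'   index grid).
#' @param order polynomial order (default 5).
#' @param max_iter iteration cap.
#' @param tol absolute convergence tolerance on the fitted baseline; defaults
#'   to `1e-6 * max(|spectrum|)`.
#' @return List of class `baseline_fit` with `baseline`, `corrected`
#'   (`spectrum - baseline`), `iterations_used`, `converged`.
#' @export
lieber_baseline <- function(spectrum, axis = seq_along(spectrum), order = 5,
                            max_iter = 100, tol = NULL) {
  p <- length(spectrum)
  if (order < 0) stop("order must be >= 0")
  if (p <= order + 1) stop("axis length must exceed order + 1")
  if (is.null(tol)) tol <- 1e-6 * max(abs(spectrum), 1e-300)
  # orthonormal polynomial basis: projection is Q %*% (t(Q) %*% y)
  u <- (axis - mean(axis)) / max(abs(axis - mean(axis)), 1)
  basis <- qr.Q(qr(outer(u, 0:order, `^`)))
  work <- spectrum
  fit <- drop(basis %*% crossprod(basis, work))
  converged <- FALSE
  iters <- 1L
  if (max(abs(work - pmin(work, fit))) == 0 &&
      max(abs(fit - drop(basis %*% crossprod(basis, pmin(work, fit))))) < tol) {
    converged <- TRUE
  }
  while (!converged && iters < max_iter) {
    work <- pmin(work, fit)
    new_fit <- drop(basis %*% crossprod(basis, work))
    iters <- iters + 1L
    if (max(abs(new_fit - fit)) < tol) converged <- TRUE
    fit <- new_fit
  }
  structure(list(baseline = fit, corrected = spectrum - fit,
                 iterations_used = iters, converged = converged),
            class = "baseline_fit")
}

#' Total-intensity normalisation
#'
#' Divides a spectrum by the sum of its absolute intensities, so the output's
#' absolute intensities sum to one. Absolute values make the normaliser
#' strictly positive even when baseline correction leaves small negative
#' excursions.
#'
#' @param spectrum numeric vector with at least one nonzero value.
#' @return Normalised spectrum.
#' @export
total_intensity_normalize <- function(spectrum) {
  s <- sum(abs(spectrum))
  if (s == 0) stop("zero total intensity")
  spectrum / s
}

#' Column mean-centering
#'
#' @param x numeric matrix with at least two rows.
#' @return List with `centered` (matrix with zero column means) and `means`.
#' @export
mean_center <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("mean-centering needs n >= 2 rows")
  mu <- colMeans(x)
  list(centered = sweep(x, 2L, mu), means = mu)
}

#' Preprocess a spectra set
#'
#' Applies [lieber_baseline()] then [total_intensity_normalize()] to every
#' row, in that order, and records the parameters in the set's provenance.
#' Mean-centering is not persisted here; PCA and PLS centre internally.
#'
#' @param set a [spectra_set()].
#' @param order,max_iter,tol passed to [lieber_baseline()].
#' @return The preprocessed [spectra_set()].
#' @export
preprocess_pipeline <- function(set, order = 5, max_iter = 100, tol = NULL) {
  mat <- set$intensities
  for (i in seq_len(nrow(mat))) {
    bl <- lieber_baseline(mat[i, ], set$axis, order = order,
                          max_iter = max_iter, tol = tol)
    mat[i, ] <- total_intensity_normalize(bl$corrected)
  }
  spectra_set(set$axis, mat, set$labels, set$sample_ids,
              c(set$provenance,
                list(preprocess = list(baseline_order = order,
                                       max_iter = max_iter,
                                       normalization = "total_intensity"))))
}
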