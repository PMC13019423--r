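#' Construct a pseudo-Voigt band
#'
#' A pseudo-Voigt band is the standard phenomenological model of a vibrational
#' absorption band: a linear mixture of a Lorentzian and a Gaussian profile
#' sharing one centre and one full width at half maximum (FWHM).
#'
#' @param center band centre, in wavenumbers (cm-1).
#' @param fwhm full width at half maximum, cm-1; must be positive.
#' @param eta mixing fraction in `[0, 1]`: 1 is a pure Lorentzian, 0 a pure
#'   Gaussian.
#' @param amplitude peak height in (arbitrary) intensity units; nonnegative.
#' @param assignment optional free-text vibrational assignment.
#' @return An object of class `pv_band`.
#' @export
pv_band <- function(center, fwhm = 18, eta = 0.5, amplitude = 1,
                    assignment = NA_character_) {
  stopifnot(is.numeric(center), length(center) == 1L, is.finite(center))
  if (!is.numeric(fwhm) || length(fwhm) != 1L || !is.finite(fwhm) || fwhm <= 0)
    stop("fwhm must be a single positive number")
  if (!is.numeric(eta) || length(eta) != 1L || is.na(eta) || eta < 0 || eta > 1)
    stop("eta must lie in [0, 1]")
  if (!is.numeric(amplitude) || length(amplitude) != 1L || is.na(amplitude) ||
      amplitude < 0)
    stop("amplitude must be nonnegative")
  structure(
    list(center = as.numeric(center), fwhm = as.numeric(fwhm),
         eta = as.numeric(eta), amplitude = as.numeric(amplitude),
         assignment = as.character(assignment)),
    class = "pv_band"
  )
}

#' @export
print.pv_band <- function(x, ...) {
  cat(sprintf("pseudo-Voigt band: center %.1f cm-1, fwhm %.1f, eta %.2f, amplitude %.3g%s\n",
              x$center, x$fwhm, x$eta, x$amplitude,
              if (is.na(x$assignment)) "" else paste0(" [", x$assignment, "]")))
  invisible(x)
}

#' Evaluate a pseudo-Voigt profile
#'
#' Computes `amplitude * (eta * L(x) + (1 - eta) * G(x))` where `L` and `G`
#' are unit-height Lorentzian and Gaussian profiles sharing the band's centre
#' and FWHM, so the value at the centre is exactly `amplitude` and the value
#' at `center +- fwhm/2` is `amplitude / 2` for any `eta`.
#'
#' @param x wavenumbers (cm-1) at which to evaluate; must be finite.
#' @param band a [pv_band()].
#' @return Numeric vector of intensities, same length as `x`.
#' @export
pseudo_voigt <- function(x, band) {
  if (!inherits(band, "pv_band")) band <- do.call(pv_band, band)
  if (any(!is.finite(x))) stop("x contains non-finite wavenumbers")
  hw <- band$fwhm / 2
  u <- (x - band$center) / hw
  lor <- 1 / (1 + u^2)
  gau <- exp(-log(2) * u^2)
  band$amplitude * (band$eta * lor + (1 - band$eta) * gau)
}

#' Sum of pseudo-Voigt bands on an axis
#'
#' @param axis numeric wavenumber axis (cm-1).
#' @param bands list of [pv_band()] objects; an empty list gives the zero
#'   spectrum.
#' @return Numeric vector of summed intensities on `axis`.
#' @export
sum_bands <- function(axis, bands) {
  if (length(axis) == 0L) stop("axis must be nonempty")
  out <- numeric(length(axis))
  for (b in bands) out <- out + pseudo_voigt(axis, b)
  out
}

#' Default wavenumber axis
#'
#' The instrument's quantum-cascade-laser sweep covers 950-1920 cm-1; the
#' default grid samples it every 2 cm-1.
#'
#' @param from,to axis limits, cm-1.
#' @param step grid spacing, cm-1.
#' @return Strictly increasing numeric vector.
#' @export
default_axis <- function(from = 950, to = 1920, step = 2) {
  if (from >= to || step <= 0) stop("need from < to and step > 0")
  seq(from, to, by = step)
}
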