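# Band-assignment table: mid-IR assignments of the EV samples per isolation
# method (TEIR, UC, SEC) and modality (FTIR, AFM-IR), plus the albumin
# reference bands. The packaged fixture is read from inst/extdata.

#' Read a band-assignment table
#'
#' The table is a delimited file with columns `method`, `modality`,
#' `wavenumber`, `assignment`. Wavenumber cells may be single values
#' (`"1743"`) or ranges (`"1550-1575"`); ranges are parsed into low/high
#' bounds and summarised by their midpoint.
#'
#' @param path path to a CSV file; defaults to the packaged assignment table.
#' @return A data.frame of class `band_table` with columns `method`,
#'   `modality`, `wavenumber` (the printed cell), `wn_low`, `wn_high`,
#'   `wn_mid`, `assignment`.
#' @export
read_band_table <- function(path = system.file("extdata", "band_assignments.csv",
                                               package = "evspec")) {
  if (!file.exists(path)) stop("band table file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("method", "modality", "wavenumber", "assignment")
  if (!all(need %in% names(df)))
    stop("band table must have columns: ", paste(need, collapse = ", "))
  bounds <- t(vapply(seq_len(nrow(df)), function(i) {
    parse_wavenumber_cell(df$wavenumber[i], i + 1L)  # +1: header line
  }, numeric(2)))
  df$wn_low <- bounds[, 1]
  df$wn_high <- bounds[, 2]
  df$wn_mid <- (df$wn_low + df$wn_high) / 2
  class(df) <- c("band_table", "data.frame")
  df
}

# "a-b" (either order, hyphen or en dash) -> sorted c(low, high); "a" -> c(a, a)
parse_wavenumber_cell <- function(cell, row) {
  parts <- strsplit(trimws(cell), "[-–]")[[1]]
  vals <- suppressWarnings(as.numeric(parts))
  if (length(vals) < 1L || length(vals) > 2L || any(is.na(vals)))
    stop(sprintf("unparseable wavenumber %s in band table row %d", sQuote(cell), row))
  range(vals)
}

#' Albumin reference band model
#'
#' Serum albumin's mid-IR spectrum is dominated by intense Amide I
#' (1650 cm-1) and Amide II (1550 cm-1) bands, with CH2/CH3 scissoring
#' (1450 cm-1) and a symmetric phosphate stretch (1070 cm-1, buffer) also
#' present. Amplitudes are ordered 1650 > 1550 > the rest.
#'
#' @param fwhm band FWHM (cm-1) used for all four bands.
#' @param eta Gaussian/Lorentzian mixing fraction.
#' @return List of [pv_band()] objects.
#' @export
albumin_reference_bands <- function(fwhm = 32, eta = 0.5) {
  list(
    pv_band(1650, fwhm, eta, amplitude = 3.0, assignment = "Amide I - albumin"),
    pv_band(1550, fwhm, eta, amplitude = 2.0, assignment = "Amide II - albumin"),
    pv_band(1450, fwhm, eta, amplitude = 0.9, assignment = "CH2 and CH3 scissoring"),
    pv_band(1070, fwhm, eta, amplitude = 1.1,
            assignment = "PO2- symmetric stretching (buffer phosphate)")
  )
}

#' Match fitted or detected peaks against a band-assignment table
#'
#' Each peak wavenumber is assigned the table entry whose midpoint is nearest,
#' provided the distance is within `tolerance`; otherwise it is labelled
#' `"unassigned"`.
#'
#' @param peaks numeric vector of peak positions (cm-1), or a `peak_fit` from
#'   [fit_peak_sum()] whose band centres are used.
#' @param band_table a [read_band_table()] result.
#' @param tolerance maximum centre-to-entry distance (cm-1) for a match.
#' @param modality optionally restrict the table to one modality
#'   (e.g. `"AFM-IR"`); `NULL` uses all rows.
#' @return data.frame with columns `wavenumber`, `matched_wavenumber`,
#'   `assignment`.
#' @export
assign_peaks <- function(peaks, band_table = read_band_table(), tolerance = 5,
                         modality = NULL) {
  if (inherits(peaks, "peak_fit"))
    peaks <- vapply(peaks$bands, function(b) b$center, numeric(1))
  if (tolerance <= 0) stop("tolerance must be positive")
  tab <- band_table
  if (!is.null(modality)) tab <- tab[tab$modality == modality, , drop = FALSE]
  out <- data.frame(wavenumber = peaks, matched_wavenumber = NA_real_,
                    assignment = "unassigned", stringsAsFactors = FALSE)
  for (i in seq_along(peaks)) {
    d <- abs(tab$wn_mid - peaks[i])
    j <- which.min(d)
    if (length(j) == 1L && d[j] <= tolerance) {
      out$matched_wavenumber[i] <- tab$wn_mid[j]
      out$assignment[i] <- tab$assignment[j]
    }
  }
  out
}
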