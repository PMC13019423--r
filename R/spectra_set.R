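#' Construct a spectra set
#'
#' The central container of the workflow: an n x p intensity matrix on a
#' shared, strictly increasing wavenumber axis, with one group label and one
#' unique sample id per row.
#'
#' @param axis strictly increasing numeric wavenumber axis (cm-1).
#' @param intensities numeric matrix, rows = samples, columns = `length(axis)`.
#' @param labels character/factor vector of group labels, one per row.
#' @param sample_ids unique character ids, one per row; autogenerated if `NULL`.
#' @param provenance free-text metadata list recording how the set was made.
#' @return Object of class `spectra_set` with elements `axis`, `intensities`,
#'   `labels`, `sample_ids`, `provenance`.
#' @export
spectra_set <- function(axis, intensities, labels,
                        sample_ids = NULL, provenance = list()) {
  axis <- as.numeric(axis)
  if (length(axis) < 1L || any(!is.finite(axis)) || any(axis <= 0))
    stop("axis values must be finite and positive")
  if (length(axis) > 1L && any(diff(axis) <= 0))
    stop("axis not increasing")
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (ncol(intensities) != length(axis))
    stop("intensity column count (", ncol(intensities),
         ") does not match axis length (", length(axis), ")")
  if (any(!is.finite(intensities)))
    stop("intensities contain non-finite values")
  labels <- as.character(labels)
  if (length(labels) != nrow(intensities))
    stop("labels length (", length(labels), ") does not match row count (",
         nrow(intensities), ")")
  if (is.null(sample_ids))
    sample_ids <- sprintf("s%03d", seq_len(nrow(intensities)))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(intensities))
    stop("sample_ids length does not match row count")
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup))
    stop("duplicate sample_id: ", paste(unique(dup), collapse = ", "))
  rownames(intensities) <- sample_ids
  structure(list(axis = axis, intensities = intensities, labels = labels,
                 sample_ids = sample_ids, provenance = provenance),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("spectra_set: %d spectra x %d wavenumbers (%.0f-%.0f cm-1)\n",
              nrow(x$intensities), length(x$axis), min(x$axis), max(x$axis)))
  if (length(x$labels)) {
    tab <- table(x$labels)
    cat("  groups:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Subset a spectra set by row
#'
#' @param set a `spectra_set`.
#' @param idx logical or integer row index.
#' @return A `spectra_set` with the selected rows.
#' @export
subset_spectra <- function(set, idx) {
  spectra_set(set$axis, set$intensities[idx, , drop = FALSE],
              set$labels[idx], set$sample_ids[idx], set$provenance)
}

#' Write a spectra set to delimited text
#'
#' Layout: an optional `#`-prefixed comment line stating the axis unit, then a
#' header row `sample_id,group,<wavenumbers...>`, then one row per spectrum.
#' Intensities are written with 15 significant digits so a write/read
#' round-trip reproduces the matrix to within float formatting.
#'
#' @param set a [spectra_set()].
#' @param path output file path.
#' @param delim field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_spectra <- function(set, path, delim = ",") {
  con <- tryCatch(file(path, open = "wb"), error = function(e)
    stop("cannot open path for writing: ", path))
  on.exit(close(con))
  fmt <- function(v) formatC(v, digits = 15, format = "g")
  lines <- c(
    "# wavenumber axis in cm-1; rows are samples",
    paste(c("sample_id", "group", fmt(set$axis)), collapse = delim)
  )
  n <- nrow(set$intensities)
  if (n > 0) {
    body <- vapply(seq_len(n), function(i) {
      paste(c(set$sample_ids[i], set$labels[i], fmt(set$intensities[i, ])),
            collapse = delim)
    }, character(1))
    lines <- c(lines, body)
  }
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a spectra set from delimited text
#'
#' Inverse of [write_spectra()]. Errors name the offending row or column:
#' ragged rows, duplicate sample ids, a non-increasing wavenumber header, and
#' non-numeric intensities are each reported distinctly.
#'
#' @param path input file path.
#' @param delim field delimiter.
#' @return A [spectra_set()].
#' @export
read_spectra <- function(path, delim = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no header row in ", path)
  split1 <- strsplit(lines, delim, fixed = TRUE)
  hdr <- split1[[1]]
  if (length(hdr) < 3L) stop("header must contain sample_id, group and wavenumbers")
  axis <- suppressWarnings(as.numeric(hdr[-(1:2)]))
  if (any(is.na(axis))) stop("non-numeric wavenumber in header column ",
                             which(is.na(axis))[1] + 2L)
  if (length(axis) > 1L && any(diff(axis) <= 0)) stop("axis not increasing")
  body <- split1[-1]
  n <- length(body)
  p <- length(axis)
  mat <- matrix(NA_real_, n, p)
  ids <- character(n)
  labels <- character(n)
  for (i in seq_len(n)) {
    row <- body[[i]]
    if (length(row) != p + 2L)
      stop(sprintf("ragged row %d: expected %d fields, found %d",
                   i + 1L, p + 2L, length(row)))
    ids[i] <- row[1]
    labels[i] <- row[2]
    vals <- suppressWarnings(as.numeric(row[-(1:2)]))
    if (any(is.na(vals)))
      stop(sprintf("non-numeric intensity at row %d, column %d",
                   i + 1L, which(is.na(vals))[1] + 2L))
    mat[i, ] <- vals
  }
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate sample_id: ", paste(unique(dup), collapse = ", "))
  spectra_set(axis, mat, labels, ids,
              provenance = list(source = path))
}

#' Resample spectra onto a new wavenumber axis
#'
#' Row-wise linear interpolation; the target axis must lie within the source
#' span (no extrapolation). Resampling onto the source axis is the identity.
#'
#' @param set a [spectra_set()].
#' @param target_axis strictly increasing numeric axis within the source span.
#' @return A [spectra_set()] on `target_axis`.
#' @export
resample_spectra <- function(set, target_axis) {
  target_axis <- as.numeric(target_axis)
  if (any(diff(target_axis) <= 0)) stop("target axis not increasing")
  if (min(target_axis) < min(set$axis) || max(target_axis) > max(set$axis))
    stop("target axis outside the source span; extrapolation is not supported")
  if (length(target_axis) == length(set$axis) &&
      all(target_axis == set$axis)) return(set)
  out <- t(apply(set$intensities, 1L, function(y)
    stats::approx(set$axis, y, xout = target_axis, method = "linear")$y))
  if (nrow(set$intensities) == 1L) out <- matrix(out, nrow = 1L)
  spectra_set(target_axis, out, set$labels, set$sample_ids,
              c(set$provenance, list(resampled = TRUE)))
}
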