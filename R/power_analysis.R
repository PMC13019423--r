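# Sample-size adequacy: resampling stability of LOO classification accuracy
# versus per-group n, and permutation-based empirical power.

# Draw a dataset with n per group: fresh generator draw for a
# generator_config source, subsample without replacement for a spectra_set.
.draw_dataset <- function(source, n, seed) {
  if (inherits(source, "generator_config")) {
    cfg <- source
    cfg$n_per_group <- n
    cfg$seed <- seed
    generate_dataset(cfg)
  } else if (inherits(source, "spectra_set")) {
    counts <- table(source$labels)
    if (any(counts < n))
      stop("n = ", n, " exceeds the available per-group count (",
           min(counts), ")")
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    set.seed(seed)
    idx <- unlist(lapply(split(seq_along(source$labels), source$labels),
                         function(ix) sample(ix, n)))
    subset_spectra(source, sort(idx))
  } else stop("source must be a generator_config or spectra_set")
}

.child_seed <- function(seed, i, j = 0L) {
  (seed * 7919L + i * 104729L + j * 131L) %% 2147483647L
}

#' Resampling stability of classification accuracy versus sample size
#'
#' For each per-group size in `n_grid`, draws `reps` datasets (fresh
#' generator draws, or subsamples of a real set), preprocesses each, and
#' records the LOO PLS-DA accuracy at the LOO-selected component count;
#' reports the mean and SD per n, and the smallest n whose mean accuracy is
#' within `stable_tol` of the largest-n mean.
#'
#' @param source a [generator_config()] or [spectra_set()].
#' @param n_grid per-group sample sizes.
#' @param reps replicates per size.
#' @param seed integer seed; every replicate's randomness derives from it.
#' @param a_max largest PLS component count tried.
#' @param stable_tol stability band around the largest-n mean accuracy.
#' @param preprocess whether to run [preprocess_pipeline()] on each draw.
#' @return data.frame of class `stability_curve` with columns `n`,
#'   `mean_accuracy`, `sd_accuracy`; the stable n is attached as attribute
#'   `"stable_n"`.
#' @export
stability_curve <- function(source, n_grid = c(10, 20, 30, 40), reps = 50,
                            seed = 1, a_max = 10, stable_tol = 0.02,
                            preprocess = TRUE) {
  acc <- matrix(NA_real_, length(n_grid), reps)
  for (i in seq_along(n_grid)) {
    for (r in seq_len(reps)) {
      set <- .draw_dataset(source, n_grid[i], .child_seed(seed, i, r))
      if (preprocess) set <- preprocess_pipeline(set)
      acc[i, r] <- loo_cv(set$intensities, set$labels, a_max)$accuracy
    }
  }
  out <- data.frame(n = n_grid, mean_accuracy = rowMeans(acc),
                    sd_accuracy = apply(acc, 1L, stats::sd))
  ref <- out$mean_accuracy[which.max(n_grid)]
  stable <- out$n[abs(out$mean_accuracy - ref) <= stable_tol]
  attr(out, "stable_n") <- if (length(stable)) min(stable) else NA_real_
  class(out) <- c("stability_curve", "data.frame")
  out
}

#' Permutation-based empirical power
#'
#' Fraction of replicate datasets of size `n` per group whose PLS-DA
#' permutation test rejects at level `alpha`.
#'
#' @param source a [generator_config()] or [spectra_set()].
#' @param n per-group sample size.
#' @param alpha significance level in (0, 1).
#' @param reps number of replicates (>= 20).
#' @param n_perm permutations per replicate.
#' @param seed integer seed.
#' @param a_max largest PLS component count tried.
#' @param preprocess whether to preprocess each draw.
#' @return Power fraction in `[0, 1]`, with the per-replicate p-values
#'   attached as attribute `"p_values"`.
#' @export
empirical_power <- function(source, n = 30, alpha = 0.05, reps = 50,
                            n_perm = 199, seed = 1, a_max = 10,
                            preprocess = TRUE) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (reps < 20) stop("reps must be >= 20")
  pvals <- numeric(reps)
  for (r in seq_len(reps)) {
    set <- .draw_dataset(source, n, .child_seed(seed, 1L, r))
    if (preprocess) set <- preprocess_pipeline(set)
    pvals[r] <- permutation_test(set$intensities, set$labels,
                                 n_perm = n_perm,
                                 seed = .child_seed(seed, 2L, r),
                                 a_max = a_max)$p_value
  }
  power <- mean(pvals < alpha)
  attr(power, "p_values") <- pvals
  power
}

#' Write a power/stability report
#'
#' CSV with one row per n (`n`, `mean_accuracy`, `sd_accuracy`, `power`) and
#' a JSON sidecar carrying the run metadata; identical inputs write
#' byte-identical files.
#'
#' @param curve a [stability_curve()] data.frame (power column optional).
#' @param path CSV output path; metadata goes to `<path>.json`.
#' @param meta named list of metadata (alpha, reps, n_perm, seed, ...).
#' @return `path`, invisibly.
#' @export
power_report <- function(curve, path, meta = list()) {
  df <- as.data.frame(curve)
  con <- file(path, open = "wb")
  cols <- names(df)
  lines <- paste(cols, collapse = ",")
  if (nrow(df))
    lines <- c(lines, apply(df, 1L, function(r)
      paste(formatC(as.numeric(r), digits = 12, format = "g"), collapse = ",")))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  close(con)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
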