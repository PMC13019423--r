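# End-to-end workflow: outlier QC on mean-centered raw
# spectra, preprocessing of the survivors, PCA/HCA exploration, PLS-DA with
# permutation testing, and albumin deconvolution of the group means.

#' Run the full analysis pipeline
#'
#' Stages, in order: generate (or accept) the dataset; QC outliers with
#' reduced T2/Q on the raw spectra; Lieber baseline correction and
#' total-intensity normalisation of the survivors; PCA with biplot summary,
#' PC1-PC2 nearest-centroid discrimination and Ward clustering cut at the
#' number of groups; PLS-DA evaluation; pseudo-Voigt albumin deconvolution
#' of the group averages.
#'
#' @param config a [generator_config()]; its seed freezes the dataset.
#' @param set optionally, an existing [spectra_set()] to analyse instead of
#'   generating one.
#' @param n_perm permutations for the PLS-DA test.
#' @param perm_seed seed for the permutation stream.
#' @param a_max largest PLS component count tried.
#' @param qc_rule outlier flagging rule, see [flag_outliers()].
#' @param run_deconvolution whether to run the albumin deconvolution stage.
#' @return List of class `pipeline_result` with elements `raw`, `qc`,
#'   `preprocessed`, `pca`, `biplot`, `pc12_accuracy`, `tree`, `cut`,
#'   `plsda`, `deconvolution`, `config`.
#' @export
run_pipeline <- function(config = generator_config(), set = NULL,
                         n_perm = 999, perm_seed = 1, a_max = 10,
                         qc_rule = "union", run_deconvolution = TRUE) {
  problems <- validate_config(config)
  if (length(problems))
    stop("invalid config:\n  ", paste(problems, collapse = "\n  "))
  raw <- if (is.null(set)) generate_dataset(config) else set

  qc <- qc_spectra(raw, rule = qc_rule)
  keep <- !qc$report$flagged
  survivors <- subset_spectra(raw, keep)

  pre <- preprocess_pipeline(survivors)

  n_groups <- length(unique(pre$labels))
  a_pca <- choose_qc_components(pre$intensities)
  pca <- fit_pca(pre$intensities, max(a_pca, 2))
  bip <- biplot_summary(pca, pre$labels, pre$axis, c(1, 2))
  acc12 <- pairwise_score_discrimination(pca, pre$labels, c(1, 2))
  tree <- hca(pre$intensities, labels = pre$labels)
  cut <- cut_tree(tree, n_groups)

  pls <- plsda_evaluate(pre, n_perm = n_perm, seed = perm_seed, a_max = a_max)

  deconv <- NULL
  if (run_deconvolution) {
    ref_raw <- sum_bands(raw$axis, config$albumin_bands)
    ref <- total_intensity_normalize(
      lieber_baseline(ref_raw, raw$axis)$corrected)
    deconv <- deconvolute_groups(pre, ref,
                                 initial_reference_bands = config$albumin_bands)
  }

  structure(list(raw = raw, qc = qc, preprocessed = pre, pca = pca,
                 biplot = bip, pc12_accuracy = acc12, tree = tree, cut = cut,
                 plsda = pls, deconvolution = deconv, config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("EV spectra pipeline result\n")
  cat(sprintf("  spectra: %d raw, %d after QC (%d flagged)\n",
              nrow(x$raw$intensities), nrow(x$preprocessed$intensities),
              sum(x$qc$report$flagged)))
  cat(sprintf("  PC1-PC2 nearest-centroid accuracy: %.3f\n", x$pc12_accuracy))
  cat(sprintf("  dendrogram cut (k = %d) purity: %.3f\n", x$cut$k, x$cut$purity))
  cat(sprintf("  PLS-DA: accuracy %.3f, R2 %.3f, Q2 %.3f, p = %.4g (A = %d)\n",
              x$plsda$accuracy, x$plsda$r2, x$plsda$q2,
              x$plsda$permutation_p, x$plsda$optimal_a))
  invisible(x)
}

#' The frozen reference profile
#'
#' The packaged default generator configuration (40 spectra per isolation
#' method, frozen seed) used by the acceptance checks and the analysis
#' scripts.
#'
#' @return A [generator_config()].
#' @export
reproduce_profile <- function() generator_config()
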