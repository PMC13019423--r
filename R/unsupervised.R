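# Unsupervised exploration: biplot extraction of top-contributing
# wavenumbers, leave-one-out nearest-centroid discrimination in a score
# plane, and agglomerative clustering with a k-cluster cut.

#' Summarise a PCA score pair as biplot data
#'
#' Restricts loadings to the chosen component pair, ranks wavenumbers by the
#' Euclidean magnitude of their loading 2-vectors, and computes per-group
#' score means and covariances (the variance ellipses).
#'
#' @param model a [fit_pca()] model.
#' @param labels per-row group labels.
#' @param axis wavenumber axis naming the loading rows.
#' @param pc_pair two retained component indices.
#' @return List of class `biplot_summary` with `scores` (n x 2), `loadings`
#'   (p x 2), `top_bands` (data.frame wavenumber/magnitude, nonincreasing),
#'   and `ellipses` (per-group list of `center`, `cov`).
#' @export
biplot_summary <- function(model, labels, axis, pc_pair = c(1, 2)) {
  A <- ncol(model$loadings)
  if (any(pc_pair < 1) || any(pc_pair > A))
    stop("pc_pair must index retained components (1..", A, ")")
  ld <- model$loadings[, pc_pair, drop = FALSE]
  sc <- model$scores[, pc_pair, drop = FALSE]
  mag <- sqrt(rowSums(ld^2))
  ord <- order(mag, decreasing = TRUE)
  ellipses <- lapply(split(seq_along(labels), labels), function(idx) {
    s <- sc[idx, , drop = FALSE]
    list(center = colMeans(s), cov = stats::cov(s))
  })
  structure(list(scores = sc, loadings = ld,
                 top_bands = data.frame(wavenumber = axis[ord],
                                        magnitude = mag[ord]),
                 ellipses = ellipses),
            class = "biplot_summary")
}

#' Leave-one-out nearest-centroid accuracy in a score plane
#'
#' Operationalises "percent discrimination" of a component pair: each sample
#' is assigned to the group whose centroid (computed with the sample held
#' out) is nearest in the 2-D score plane, and the accuracy is the fraction
#' assigned to its own group.
#'
#' @param model a [fit_pca()] model.
#' @param labels per-row group labels (>= 2 groups, each with >= 2 members).
#' @param pc_pair two retained component indices.
#' @return Accuracy fraction in `[0, 1]`.
#' @export
pairwise_score_discrimination <- function(model, labels, pc_pair = c(1, 2)) {
  labels <- as.character(labels)
  groups <- unique(labels)
  if (length(groups) < 2) stop("need at least two groups")
  if (any(table(labels) < 2)) stop("every group needs at least 2 members")
  sc <- model$scores[, pc_pair, drop = FALSE]
  n <- nrow(sc)
  sums <- rowsum(sc, labels)           # group sums, rows ordered by group name
  counts <- as.vector(table(labels)[rownames(sums)])
  correct <- 0L
  for (i in seq_len(n)) {
    cent <- sums
    cnt <- counts
    gi <- match(labels[i], rownames(sums))
    cent[gi, ] <- cent[gi, ] - sc[i, ]
    cnt[gi] <- cnt[gi] - 1L
    cent <- cent / cnt
    d2 <- rowSums(sweep(cent, 2L, sc[i, ])^2)
    if (rownames(sums)[which.min(d2)] == labels[i]) correct <- correct + 1L
  }
  correct / n
}

#' Agglomerative hierarchical clustering
#'
#' Thin wrapper over [stats::hclust()] on a distance matrix, keeping the
#' labels with the tree so cuts can be scored for purity. Default Ward
#' linkage on Euclidean distances.
#'
#' @param x numeric matrix (rows clustered), e.g. preprocessed spectra or PC
#'   scores.
#' @param linkage one of `"ward"`, `"average"`, `"complete"`, `"single"`.
#' @param metric one of `"euclidean"`, `"manhattan"`, `"maximum"`.
#' @param labels optional per-row group labels stored for purity scoring.
#' @return List of class `hca_tree` with the `hclust` object and labels.
#' @export
hca <- function(x, linkage = c("ward", "average", "complete", "single"),
                metric = c("euclidean", "manhattan", "maximum"),
                labels = NULL) {
  linkage <- match.arg(linkage)
  metric <- match.arg(metric)
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need n >= 2 rows to cluster")
  method <- if (linkage == "ward") "ward.D2" else linkage
  hc <- stats::hclust(stats::dist(x, method = metric), method = method)
  structure(list(hclust = hc, labels = labels, n = nrow(x)),
            class = "hca_tree")
}

#' Cut a dendrogram into k clusters and score purity
#'
#' Cuts at the `(n - k)`-th merge via [stats::cutree()]. Purity is the
#' fraction of samples whose cluster's majority label equals their own label
#' (1 when labels are absent is not defined; labels are required).
#'
#' @param tree an [hca()] tree.
#' @param k cluster count, `1 <= k <= n`.
#' @param labels per-sample labels; defaults to those stored in the tree.
#' @return List of class `dendrogram_cut` with `k`, `assignments`, `purity`,
#'   and `cluster_majority` (majority label per cluster).
#' @export
cut_tree <- function(tree, k, labels = tree$labels) {
  if (k < 1 || k > tree$n) stop("k must lie in [1, n]")
  assignments <- stats::cutree(tree$hclust, k = k)
  majority <- NULL
  purity <- NA_real_
  if (!is.null(labels)) {
    labels <- as.character(labels)
    majority <- vapply(split(labels, assignments), function(l)
      names(sort(table(l), decreasing = TRUE))[1], character(1))
    purity <- mean(labels == majority[as.character(assignments)])
  }
  structure(list(k = k, assignments = assignments, purity = purity,
                 cluster_majority = majority),
            class = "dendrogram_cut")
}

#' Serialise a dendrogram to Newick
#'
#' Writes the agglomeration tree with merge heights as branch lengths, for
#' use with standard tree tooling.
#'
#' @param tree an [hca()] tree.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(tree, path) {
  phy <- ape::as.phylo(tree$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}
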