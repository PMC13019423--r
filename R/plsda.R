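# PLS-DA: NIPALS PLS2 regression against one-hot class membership, with
# leave-one-out cross-validation, label-permutation testing, VIP scores and
# coefficient-based importance.

.one_hot <- function(labels, class_order) {
  Y <- matrix(0, length(labels), length(class_order),
              dimnames = list(NULL, class_order))
  Y[cbind(seq_along(labels), match(labels, class_order))] <- 1
  Y
}

# Orthonormal basis of the row space of the centered matrix; PLS predictions
# and LOO accuracies are invariant to this rotation, which shrinks the
# feature dimension from p to at most n - 1 for the heavy resampling loops.
.row_space_projection <- function(X) {
  n <- nrow(X); p <- ncol(X)
  if (p <= n) return(list(Xp = X, V = NULL))
  mu <- colMeans(X)
  sv <- svd(sweep(X, 2L, mu), nu = 0)
  keep <- sv$d > sv$d[1] * 1e-12
  list(Xp = sweep(X, 2L, mu) %*% sv$v[, keep, drop = FALSE], V = sv$v[, keep, drop = FALSE])
}

#' Fit a PLS-DA model
#'
#' NIPALS PLS2 regression of the one-hot class membership on the spectra,
#' deflating X only. Class order is first-appearance order of the labels;
#' each weight vector's largest-magnitude element is made positive.
#'
#' @param x numeric matrix, rows = samples.
#' @param labels per-row class labels (>= 2 classes), or an already-built
#'   numeric response matrix.
#' @param n_components number of latent components `A <= min(n - 1, p)`.
#' @return Object of class `plsda_model` with `x_weights`, `x_loadings`,
#'   `y_loadings`, `x_scores`, `coefficients` (p x g), `x_mean`, `y_mean`,
#'   `class_order`, `ssy`, `n_components`.
#' @export
fit_pls <- function(x, labels, n_components) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (is.matrix(labels)) {
    Y <- labels
    class_order <- colnames(Y)
    if (is.null(class_order)) class_order <- paste0("class", seq_len(ncol(Y)))
  } else {
    labels <- as.character(labels)
    class_order <- unique(labels)
    if (length(class_order) < 2) stop("need at least two classes")
    Y <- .one_hot(labels, class_order)
  }
  if (n_components < 1 || n_components > min(n - 1, p))
    stop("n_components must lie in [1, min(n - 1, p)]")
  if (all(apply(x, 2L, stats::var) == 0)) stop("X has no variance")
  f <- cpp_pls_fit(x, Y, as.integer(n_components))
  f$x_mean <- drop(f$x_mean)
  f$y_mean <- drop(f$y_mean)
  f$class_order <- class_order
  colnames(f$coefficients) <- class_order
  class(f) <- "plsda_model"
  f
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf("PLS-DA model: %d components, %d features, classes: %s\n",
              x$n_components, nrow(x$coefficients),
              paste(x$class_order, collapse = ", ")))
  invisible(x)
}

#' Predict continuous class scores and labels
#'
#' Continuous prediction is `(x - x_mean) %*% coefficients + y_mean`; the
#' label is the argmax over classes, ties broken toward the earlier class in
#' `class_order`.
#'
#' @param model a [fit_pls()] model.
#' @param x matrix of new rows on the model's columns.
#' @return List with `scores` (n x g matrix) and `labels`.
#' @export
predict_class <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != nrow(model$coefficients)) stop("column mismatch")
  sc <- sweep(x, 2L, model$x_mean) %*% model$coefficients
  sc <- sweep(sc, 2L, model$y_mean, `+`)
  labs <- model$class_order[apply(sc, 1L, which.max)]
  list(scores = sc, labels = labs)
}

#' Leave-one-out cross-validation over component counts
#'
#' For each `A <= a_max`, every sample is predicted from a model fitted to
#' the other `n - 1`; accuracy and PRESS accumulate per A. `Q2(A) = 1 -
#' PRESS/TSS` with TSS from the centered full-data response. The optimal A
#' is the smallest one achieving the maximum LOO accuracy.
#'
#' @param x data matrix.
#' @param labels class labels.
#' @param a_max largest component count tried (capped at `min(n - 2, p)`).
#' @return List with `optimal_a`, `accuracy` (at the optimal A),
#'   `accuracy_per_a`, `q2_per_a`, `q2` (at the optimal A).
#' @export
loo_cv <- function(x, labels, a_max = 10) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  n <- nrow(x)
  if (n < 3) stop("need n >= 3 for leave-one-out")
  counts <- table(labels)
  if (any(counts < 2))
    stop("class(es) ", paste(names(counts)[counts < 2], collapse = ", "),
         " would vanish from a training fold; collect more samples per class")
  class_order <- unique(labels)
  a_max <- min(a_max, n - 2, ncol(x))
  proj <- .row_space_projection(x)
  res <- cpp_pls_loo(proj$Xp, as.integer(match(labels, class_order) - 1L),
                     length(class_order), as.integer(a_max))
  Y <- .one_hot(labels, class_order)
  tss <- sum(sweep(Y, 2L, colMeans(Y))^2)
  q2 <- 1 - res$press / tss
  acc <- drop(res$accuracy)
  optimal_a <- which.max(acc)  # first maximum = smallest A (parsimony)
  list(optimal_a = optimal_a, accuracy = acc[optimal_a],
       accuracy_per_a = acc, q2_per_a = drop(q2), q2 = q2[optimal_a])
}

#' Label-permutation test of PLS-DA discrimination
#'
#' The observed statistic is the LOO accuracy at the optimal component count
#' of the true labels. Each permutation shuffles the labels, re-selects the
#' component count by LOO on the shuffled labels, and records that accuracy.
#' `p = (1 + #\{perm >= observed\}) / (1 + n_perm)` (add-one correction, so p
#' is never zero).
#'
#' @param x data matrix.
#' @param labels class labels.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed governing the shuffle stream.
#' @param a_max largest component count tried.
#' @return List with `p_value`, `observed`, `perm_accuracy`, `n_perm`.
#' @export
permutation_test <- function(x, labels, n_perm = 999, seed = 1, a_max = 10) {
  if (n_perm < 99) stop("n_perm must be >= 99")
  x <- as.matrix(x)
  labels <- as.character(labels)
  obs <- loo_cv(x, labels, a_max)
  n <- nrow(x)
  class_order <- unique(labels)
  cls0 <- match(labels, class_order) - 1L
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)
  perms <- vapply(seq_len(n_perm), function(j) cls0[sample.int(n)],
                  integer(n))
  a_max_eff <- min(a_max, n - 2, ncol(x))
  proj <- .row_space_projection(x)
  perm_acc <- drop(cpp_perm_acc(proj$Xp, perms, length(class_order),
                                as.integer(a_max_eff)))
  p <- (1 + sum(perm_acc >= obs$accuracy)) / (1 + n_perm)
  list(p_value = p, observed = obs$accuracy, perm_accuracy = perm_acc,
       n_perm = n_perm, optimal_a = obs$optimal_a)
}

#' Variable importance in projection (VIP)
#'
#' `VIP_j = sqrt(p * sum_a ssy_a w_ja^2 / sum_a ssy_a)` with unit-norm weight
#' vectors and `ssy_a` the response variance captured by component a; the
#' squared scores average to one over features.
#'
#' @param model a [fit_pls()] model.
#' @return Numeric p-vector of VIP scores.
#' @export
vip_scores <- function(model) {
  W <- model$x_weights
  ssy <- model$ssy
  if (sum(ssy) <= 0) stop("zero explained response variance")
  p <- nrow(W)
  sqrt(p * drop(W^2 %*% ssy) / sum(ssy))
}

#' Coefficient-based feature relevance
#'
#' Per class, the squared regression coefficients divided by the number of
#' components; averaged over classes to a single overall relevance per
#' feature in the multi-group case.
#'
#' @param model a [fit_pls()] model.
#' @return Numeric p-vector.
#' @export
coef_importance <- function(model) {
  rowMeans(model$coefficients^2) / model$n_components
}

#' Full PLS-DA performance evaluation
#'
#' Bundles leave-one-out cross-validation, the permutation test, training
#' `R2` at the optimal component count, VIP scores and coefficient
#' importance into one report.
#'
#' @param x data matrix or a [spectra_set()] (its intensities are used).
#' @param labels class labels; defaults to the set's labels.
#' @param n_perm number of permutations.
#' @param seed RNG seed for the permutation stream.
#' @param a_max largest component count tried.
#' @return Object of class `plsda_performance` with `accuracy`, `r2`, `q2`,
#'   `permutation_p`, `n_permutations`, `optimal_a`, `vip`,
#'   `coef_importance`, `model`.
#' @export
plsda_evaluate <- function(x, labels = NULL, n_perm = 999, seed = 1,
                           a_max = 10) {
  if (inherits(x, "spectra_set")) {
    if (is.null(labels)) labels <- x$labels
    x <- x$intensities
  }
  x <- as.matrix(x)
  labels <- as.character(labels)
  cv <- loo_cv(x, labels, a_max)
  model <- fit_pls(x, labels, cv$optimal_a)
  Y <- .one_hot(labels, model$class_order)
  fitted <- predict_class(model, x)$scores
  rss <- sum((Y - fitted)^2)
  tss <- sum(sweep(Y, 2L, colMeans(Y))^2)
  pt <- permutation_test(x, labels, n_perm = n_perm, seed = seed,
                         a_max = a_max)
  structure(list(accuracy = cv$accuracy, r2 = 1 - rss / tss, q2 = cv$q2,
                 permutation_p = pt$p_value, n_permutations = n_perm,
                 optimal_a = cv$optimal_a, vip = vip_scores(model),
                 coef_importance = coef_importance(model), model = model),
            class = "plsda_performance")
}

#' @export
print.plsda_performance <- function(x, ...) {
  cat(sprintf(
    "PLS-DA performance: accuracy %.3f, R2 %.3f, Q2 %.3f, p = %.4g (A = %d, %d permutations)\n",
    x$accuracy, x$r2, x$q2, x$permutation_p, x$optimal_a, x$n_permutations))
  invisible(x)
}
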