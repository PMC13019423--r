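# PCA model and QC statistics: reduced Hotelling T2 (score outliers) and
# reduced Q residuals (off-model outliers), each divided by its 95% limit so
# the decision boundary of the T2-vs-Q graph is 1.

#' Fit a PCA model
#'
#' Singular value decomposition of the column-centered matrix. Loadings are
#' the top right singular vectors with the sign convention that each
#' loading's largest-magnitude element is positive; eigenvalues are the score
#' variances with divisor `n - 1`. All nonzero eigenvalues (including the
#' discarded ones) are retained in the model for the Q-residual limit.
#'
#' @param x numeric matrix, rows = samples.
#' @param n_components number of retained components `A`,
#'   `1 <= A <= min(n - 1, p)`.
#' @return Object of class `pca_model` with `mean`, `loadings` (p x A),
#'   `eigenvalues` (A), `all_eigenvalues`, `scores` (n x A),
#'   `explained_variance_ratio`, `n`.
#' @export
fit_pca <- function(x, n_components) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (n_components < 1 || n_components > min(n - 1, p))
    stop("n_components must lie in [1, min(n - 1, p)]")
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  sv <- svd(xc)
  all_eig <- sv$d^2 / (n - 1)
  A <- n_components
  loadings <- sv$v[, seq_len(A), drop = FALSE]
  # sign convention: largest-magnitude element of each loading positive
  for (a in seq_len(A)) {
    j <- which.max(abs(loadings[, a]))
    if (loadings[j, a] < 0) loadings[, a] <- -loadings[, a]
  }
  scores <- xc %*% loadings
  structure(list(mean = mu, loadings = loadings,
                 eigenvalues = all_eig[seq_len(A)],
                 all_eigenvalues = all_eig,
                 scores = scores,
                 explained_variance_ratio = all_eig[seq_len(A)] / sum(all_eig),
                 n = n),
            class = "pca_model")
}

#' Choose the number of QC components
#'
#' Smallest A whose cumulative explained variance reaches `var_explained`,
#' capped at `cap`.
#'
#' @param x data matrix.
#' @param var_explained target cumulative variance fraction.
#' @param cap maximum A.
#' @return Integer component count.
#' @export
choose_qc_components <- function(x, var_explained = 0.90, cap = 10) {
  n <- nrow(x); p <- ncol(x)
  full <- fit_pca(x, min(n - 1, p))
  cum <- cumsum(full$explained_variance_ratio)
  A <- which(cum >= var_explained)[1]
  if (is.na(A)) A <- length(cum)
  min(A, cap)
}

#' Reduced Hotelling T2
#'
#' Raw `T2_i = sum_a score_ia^2 / eigenvalue_a` over the retained components,
#' measuring how far each sample sits from the model centre within the score
#' space; divided by the `conf`-level limit `A (n - 1) / (n - A) *
#' qf(conf, A, n - A)` so values above 1 flag score outliers.
#'
#' @param model a [fit_pca()] model.
#' @param x data matrix on the model's columns (defaults to training scores).
#' @param conf confidence level of the limit.
#' @return Numeric vector of reduced T2 values.
#' @export
hotelling_t2_reduced <- function(model, x = NULL, conf = 0.95) {
  if (any(model$eigenvalues <= 0))
    stop("zero eigenvalue among retained components")
  scores <- if (is.null(x)) model$scores
  else sweep(as.matrix(x), 2L, model$mean) %*% model$loadings
  t2 <- drop(scores^2 %*% (1 / model$eigenvalues))
  A <- length(model$eigenvalues); n <- model$n
  if (n - A <= 0) stop("T2 limit undefined for A >= n")
  lim <- A * (n - 1) / (n - A) * stats::qf(conf, A, n - A)
  t2 / lim
}

#' Reduced Q residuals
#'
#' Raw `Q_i` is the squared norm of the part of each (centered) sample not
#' captured by the retained loadings; divided by the Jackson-Mudholkar
#' `conf`-level limit computed from the discarded eigenvalues, so values
#' above 1 flag residual outliers. When the retained components span the
#' whole model rank the residuals are identically zero and so are the
#' reduced values.
#'
#' @param model a [fit_pca()] model.
#' @param x data matrix (defaults to the training data reconstruction).
#' @param conf confidence level.
#' @return Numeric vector of reduced Q values.
#' @export
q_residuals_reduced <- function(model, x = NULL, conf = 0.95) {
  if (is.null(x)) {
    # training residual: total centered SS minus retained score SS, rowwise
    # requires the training matrix; reconstruct from scores is not enough, so
    # callers should pass x; for training data we store scores only, hence:
    stop("pass the data matrix x (training or new) explicitly")
  }
  xc <- sweep(as.matrix(x), 2L, model$mean)
  scores <- xc %*% model$loadings
  resid <- xc - scores %*% t(model$loadings)
  q <- rowSums(resid^2)
  A <- length(model$eigenvalues)
  disc <- model$all_eigenvalues[-seq_len(A)]
  disc <- disc[disc > .Machine$double.eps * max(model$all_eigenvalues)]
  if (!length(disc)) return(q * 0)
  th1 <- sum(disc); th2 <- sum(disc^2); th3 <- sum(disc^3)
  h0 <- 1 - 2 * th1 * th3 / (3 * th2^2)
  if (!is.finite(h0) || h0 <= 0) h0 <- 1e-3
  z <- stats::qnorm(conf)
  lim <- th1 * (z * sqrt(2 * th2 * h0^2) / th1 +
                  1 + th2 * h0 * (h0 - 1) / th1^2)^(1 / h0)
  q / lim
}

#' Flag outliers from reduced T2 and Q
#'
#' @param t2_reduced,q_reduced equal-length numeric vectors.
#' @param sample_ids optional ids for the report.
#' @param rule `"union"` (flag when either statistic exceeds 1, the default)
#'   or `"intersection"` (both must exceed 1).
#' @param threshold decision boundary on the reduced scale.
#' @return data.frame of class `outlier_report` with columns `sample_id`,
#'   `t2_reduced`, `q_reduced`, `flagged`.
#' @export
flag_outliers <- function(t2_reduced, q_reduced, sample_ids = NULL,
                          rule = c("union", "intersection"), threshold = 1) {
  rule <- match.arg(rule)
  if (length(t2_reduced) != length(q_reduced))
    stop("t2_reduced and q_reduced must have equal length")
  if (is.null(sample_ids)) sample_ids <- sprintf("s%03d", seq_along(t2_reduced))
  flagged <- if (rule == "union") t2_reduced > threshold | q_reduced > threshold
  else t2_reduced > threshold & q_reduced > threshold
  out <- data.frame(sample_id = sample_ids, t2_reduced = t2_reduced,
                    q_reduced = q_reduced, flagged = flagged,
                    stringsAsFactors = FALSE)
  class(out) <- c("outlier_report", "data.frame")
  out
}

#' QC a spectra set on mean-centered raw spectra
#'
#' Runs the full screen: choose A (>= `var_explained` cumulative variance,
#' capped), fit PCA on the raw intensities, compute reduced T2 and Q, flag.
#'
#' @param set a [spectra_set()].
#' @param var_explained cumulative-variance target for A.
#' @param conf confidence level of both limits.
#' @param rule flagging rule, see [flag_outliers()].
#' @param cap maximum number of components.
#' @return List with `report` (an `outlier_report`), `model`, `n_components`.
#' @export
qc_spectra <- function(set, var_explained = 0.90, conf = 0.95,
                       rule = "union", cap = 10) {
  x <- set$intensities
  A <- choose_qc_components(x, var_explained, cap)
  model <- fit_pca(x, A)
  t2 <- hotelling_t2_reduced(model, x, conf)
  q <- q_residuals_reduced(model, x, conf)
  list(report = flag_outliers(t2, q, set$sample_ids, rule),
       model = model, n_components = A)
}
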