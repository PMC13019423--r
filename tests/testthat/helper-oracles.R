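# Independent reference implementations used as oracles. These deliberately
# use different algorithms from the package code paths they check.

# PCA via eigendecomposition of the covariance matrix.
pca_cov_oracle <- function(x) {
  e <- eigen(stats::cov(x), symmetric = TRUE)
  list(eigenvalues = e$values, loadings = e$vectors)
}

# Textbook NIPALS PLS2 with explicit power iteration on (u, w, t, q),
# deflating X only; returns the regression coefficient matrix.
nipals_pls_oracle <- function(X, Y, A, tol = 1e-12, max_iter = 2000) {
  xm <- colMeans(X); ym <- colMeans(Y)
  Xd <- sweep(X, 2, xm); Yc <- sweep(Y, 2, ym)
  p <- ncol(X); g <- ncol(Y)
  W <- matrix(0, p, A); P <- matrix(0, p, A); Q <- matrix(0, g, A)
  for (a in seq_len(A)) {
    u <- Yc[, which.max(apply(Yc, 2, var))]
    w <- rep(0, p)
    for (it in seq_len(max_iter)) {
      w_new <- drop(crossprod(Xd, u)); w_new <- w_new / sqrt(sum(w_new^2))
      tvec <- drop(Xd %*% w_new)
      q <- drop(crossprod(Yc, tvec)) / sum(tvec^2)
      u <- drop(Yc %*% q) / sum(q^2)
      if (sum((w_new - w)^2) < tol^2) { w <- w_new; break }
      w <- w_new
    }
    tvec <- drop(Xd %*% w)
    tt <- sum(tvec^2)
    pl <- drop(crossprod(Xd, tvec)) / tt
    q <- drop(crossprod(Yc, tvec)) / tt
    j <- which.max(abs(w))
    if (w[j] < 0) { w <- -w; tvec <- -tvec; pl <- -pl; q <- -q }
    Xd <- Xd - tcrossprod(tvec, pl)
    W[, a] <- w; P[, a] <- pl; Q[, a] <- q
  }
  B <- W %*% solve(crossprod(P, W), t(Q))
  list(coefficients = B, W = W, P = P, Q = Q, x_mean = xm, y_mean = ym)
}

# O(n^3) naive agglomeration with average linkage on a distance matrix;
# returns the sorted merge heights.
average_linkage_heights_oracle <- function(x) {
  d <- as.matrix(stats::dist(x))
  clusters <- as.list(seq_len(nrow(x)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      h <- mean(d[clusters[[i]], clusters[[j]]])
      if (h < best[1]) best <- c(h, j, i)
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- clusters[-c(best[2], best[3])]
    clusters[[length(clusters) + 1]] <- merged
  }
  heights
}

one_hot_helper <- function(labels) {
  labels <- as.character(labels)
  classes <- unique(labels)
  Y <- matrix(0, length(labels), length(classes),
              dimnames = list(NULL, classes))
  Y[cbind(seq_along(labels), match(labels, classes))] <- 1
  Y
}

# Small noiseless generator configuration used by several unit tests.
tiny_config <- function(n = 4, seed = 42, noise_sd = 0, jitter = 0,
                        albumin = 0, baseline = 0) {
  generator_config(
    n_per_group = n,
    albumin_fraction_mean = c(TEIR = albumin, UC = albumin, SEC = albumin),
    albumin_fraction_sd = 0,
    baseline_coeff_scale = baseline,
    noise_sd = noise_sd,
    amplitude_jitter_cv = c(TEIR = jitter, UC = jitter, SEC = jitter),
    seed = seed)
}
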