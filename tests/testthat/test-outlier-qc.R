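test_that("full-rank PCA reconstructs the data and matches the covariance oracle", {
  set.seed(11)
  x <- matrix(rnorm(10 * 6), 10, 6)
  A <- min(nrow(x) - 1, ncol(x))
  m <- fit_pca(x, A)
  recon <- sweep(m$scores %*% t(m$loadings), 2, m$mean, `+`)
  expect_lt(max(abs(recon - x)), 1e-8)
  o <- pca_cov_oracle(x)
  expect_equal(m$all_eigenvalues[seq_len(A)], o$eigenvalues[seq_len(A)],
               tolerance = 1e-8)
  for (a in seq_len(A)) {
    align <- abs(sum(m$loadings[, a] * o$loadings[, a]))
    expect_equal(align, 1, tolerance = 1e-6)
  }
})

test_that("a single informative direction is recovered exactly", {
  set.seed(2)
  v <- rnorm(8); v <- v / sqrt(sum(v^2))
  x <- outer(rnorm(20), v)
  m <- fit_pca(x, 1)
  expect_equal(m$explained_variance_ratio[1], 1)
  expect_equal(abs(sum(m$loadings[, 1] * v)), 1, tolerance = 1e-8)
  expect_error(fit_pca(x, 25), "n_components")
})

test_that("Hotelling T2 is zero at the centre and rotation invariant", {
  set.seed(3)
  x <- matrix(rnorm(30 * 5), 30, 5)
  m <- fit_pca(x, 3)
  t2_mean <- hotelling_t2_reduced(m, matrix(m$mean, 1))
  expect_equal(unname(t2_mean), 0)
  rot <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
  xr <- x %*% rot
  mr <- fit_pca(xr, 3)
  expect_equal(hotelling_t2_reduced(mr, xr), hotelling_t2_reduced(m, x),
               tolerance = 1e-8)
  m0 <- m; m0$eigenvalues[3] <- 0
  expect_error(hotelling_t2_reduced(m0, x), "zero eigenvalue")
})

test_that("Q residuals vanish at full rank and catch off-model spikes", {
  set.seed(4)
  x <- matrix(rnorm(12 * 6), 12, 6)
  full <- fit_pca(x, min(nrow(x) - 1, ncol(x)))
  expect_equal(unname(q_residuals_reduced(full, x)), rep(0, nrow(x)))
  # structured data: 2 informative dims of 10, plus one spiked sample
  set.seed(5)
  scores2 <- matrix(rnorm(40 * 2, sd = c(4, 2)), 40, 2, byrow = TRUE)
  basis <- qr.Q(qr(matrix(rnorm(100), 10, 10)))[, 1:2]
  x2 <- scores2 %*% t(basis) + matrix(rnorm(400, sd = 0.05), 40, 10)
  x2[7, ] <- x2[7, ] + qr.Q(qr(cbind(basis, rnorm(10))))[, 3] * 3
  m2 <- fit_pca(x2, 2)
  q <- q_residuals_reduced(m2, x2)
  expect_equal(which.max(q), 7L)
  expect_gt(q[7], 1)
  # the mean row has zero residual
  expect_equal(unname(q_residuals_reduced(m2, matrix(m2$mean, 1))), 0)
})

test_that("training sum of squares decomposes into retained scores plus residuals", {
  set.seed(6)
  x <- matrix(rnorm(15 * 8), 15, 8)
  m <- fit_pca(x, 3)
  xc <- sweep(x, 2, m$mean)
  resid <- xc - m$scores %*% t(m$loadings)
  expect_equal(sum(xc^2), sum(m$scores^2) + sum(resid^2), tolerance = 1e-8)
})

test_that("false-flag rates on in-model Gaussian data sit near the 5% design level", {
  set.seed(17)
  t2_flags <- q_flags <- 0
  total <- 0
  for (rep in 1:20) {
    x <- matrix(rnorm(100 * 20), 100, 20)
    m <- fit_pca(x, 3)
    t2_flags <- t2_flags + sum(hotelling_t2_reduced(m, x) > 1)
    q_flags <- q_flags + sum(q_residuals_reduced(m, x) > 1)
    total <- total + 100
  }
  expect_gte(total, 2000)
  expect_lt(abs(t2_flags / total - 0.05), 0.02)
  expect_lt(abs(q_flags / total - 0.05), 0.02)
})

test_that("outlier flags follow the union rule and threshold monotonicity", {
  rep0 <- flag_outliers(c(0.5, 0.9), c(0.3, 0.2))
  expect_false(any(rep0$flagged))
  rep1 <- flag_outliers(c(0.5, 1.2), c(0.5, 0.5))
  expect_equal(rep1$flagged, c(FALSE, TRUE))
  rep2 <- flag_outliers(c(0.5, 1.2), c(0.5, 0.5), rule = "intersection")
  expect_false(any(rep2$flagged))
  set.seed(8)
  t2 <- abs(rnorm(100)); q <- abs(rnorm(100))
  counts <- vapply(c(0.5, 1, 2, 4), function(th)
    sum(flag_outliers(t2, q, threshold = th)$flagged), integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(flag_outliers(1:3, 1:2), "equal length")
})

test_that("qc_spectra flags a small, plausible fraction of a clean draw", {
  set <- generate_dataset(generator_config(n_per_group = 12, seed = 21))
  qc <- qc_spectra(set)
  expect_equal(nrow(qc$report), 36)
  expect_lt(mean(qc$report$flagged), 0.25)
  expect_true(all(qc$report$t2_reduced >= 0 & qc$report$q_reduced >= 0))
  expect_equal(qc$report$flagged,
               qc$report$t2_reduced > 1 | qc$report$q_reduced > 1)
})
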