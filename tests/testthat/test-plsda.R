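separable_toy <- function(n_per = 6, p = 4, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * p, 0, 0.2), n_per, p),
             matrix(rnorm(n_per * p, 3, 0.2), n_per, p))
  list(x = x, labels = rep(c("a", "b"), each = n_per))
}

test_that("a single informative column separates classes with one component", {
  set.seed(2)
  x <- matrix(rnorm(40, sd = 0.05), 10, 4)
  x[, 2] <- rep(c(0, 5), each = 5)
  labels <- rep(c("a", "b"), each = 5)
  m <- fit_pls(x, labels, 1)
  expect_equal(predict_class(m, x)$labels, labels)
})

test_that("PLS scores are mutually orthogonal", {
  set.seed(3)
  x <- matrix(rnorm(20 * 7), 20, 7)
  m <- fit_pls(x, rep(c("a", "b", "c"), length.out = 20), 4)
  G <- crossprod(m$x_scores)
  offdiag <- abs(G[upper.tri(G)])
  norms <- sqrt(diag(G))
  expect_lt(max(offdiag / tcrossprod(norms)[upper.tri(G)]), 1e-8)
})

test_that("coefficients match an independent power-iteration NIPALS oracle", {
  set.seed(4)
  for (g in 2:3) {
    n <- 12; p <- 5
    x <- matrix(rnorm(n * p), n, p)
    labels <- sample(letters[seq_len(g)], n, replace = TRUE)
    while (length(unique(labels)) < g)
      labels <- sample(letters[seq_len(g)], n, replace = TRUE)
    A <- 3
    m <- fit_pls(x, labels, A)
    Y <- one_hot_helper(labels)[, m$class_order, drop = FALSE]
    o <- nipals_pls_oracle(x, Y, A)
    expect_lt(max(abs(m$coefficients - o$coefficients)), 1e-6)
    expect_lt(max(abs(m$x_weights - o$W)), 1e-6)
  }
})

test_that("scores and VIP agree with the mixOmics implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(5)
  n <- 18; p <- 7
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:p)))
  labels <- rep(c("a", "b"), each = 9)
  m <- fit_pls(x, labels, 2)
  mo <- mixOmics::plsda(x, factor(labels), ncomp = 2, scale = FALSE)
  expect_lt(max(abs(abs(m$x_scores) - abs(unname(mo$variates$X)))), 1e-8)
  expect_lt(max(abs(vip_scores(m) - unname(mixOmics::vip(mo)[, 2]))), 1e-8)
})

test_that("prediction at the training mean returns the prior class deterministically", {
  toy <- separable_toy()
  m <- fit_pls(toy$x, toy$labels, 2)
  pred <- predict_class(m, matrix(m$x_mean, 1))
  expect_equal(unname(drop(pred$scores)), unname(m$y_mean))
  expect_equal(pred$labels, m$class_order[which.max(m$y_mean)])
  # consistent feature permutation leaves predictions unchanged
  perm <- c(3, 1, 4, 2)
  m2 <- fit_pls(toy$x[, perm], toy$labels, 2)
  expect_equal(predict_class(m2, toy$x[, perm])$labels,
               predict_class(m, toy$x)$labels)
})

test_that("LOO cross-validation is perfect on separable data and honest on noise", {
  toy <- separable_toy()
  cv <- loo_cv(toy$x, toy$labels, 3)
  expect_equal(cv$accuracy, 1)
  # pure noise from the null generator: Q2 near or below zero
  nul <- generate_null_dataset(generator_config(n_per_group = 7, seed = 31))
  cvn <- loo_cv(nul$intensities, nul$labels, 5)
  expect_lt(cvn$q2, 0.2)
  expect_lt(cvn$accuracy, 0.75)
  # an appended constant-plus-noise feature barely moves accuracy
  set.seed(6)
  x2 <- cbind(toy$x, rnorm(nrow(toy$x), 0, 1e-3))
  cv2 <- loo_cv(x2, toy$labels, 3)
  expect_equal(cv2$accuracy, cv$accuracy, tolerance = 0.1)
  expect_error(loo_cv(toy$x, c("z", toy$labels[-1]), 2), "more samples")
})

test_that("permutation p is floored, exact on separable data, and relabel invariant", {
  # wide enough that no label permutation can tie the perfect observed score
  toy <- separable_toy(n_per = 10, p = 10)
  pt <- permutation_test(toy$x, toy$labels, n_perm = 99, seed = 3)
  expect_equal(pt$p_value, 0.01)
  expect_gte(pt$p_value, 1 / (pt$n_perm + 1))
  relabel <- c(a = "Q", b = "R")[toy$labels]
  pt2 <- permutation_test(toy$x, relabel, n_perm = 99, seed = 3)
  expect_equal(pt2$p_value, pt$p_value)
  expect_error(permutation_test(toy$x, toy$labels, n_perm = 10), "99")
})

test_that("VIP satisfies its normalisation identity and flatness under exchangeability", {
  set.seed(7)
  x <- matrix(rnorm(30 * 9), 30, 9)
  m <- fit_pls(x, rep(c("a", "b", "c"), each = 10), 4)
  v <- vip_scores(m)
  expect_equal(sum(v^2), length(v), tolerance = 1e-8)
  # exchangeable design: every feature identically informative
  set.seed(8)
  cls <- rep(c(0, 1), each = 25)
  xe <- sapply(1:12, function(j) cls * 2 + rnorm(50, sd = 1))
  me <- fit_pls(xe, ifelse(cls == 0, "a", "b"), 2)
  ve <- vip_scores(me)
  expect_lt(max(abs(ve - 1)), 0.2)
})

test_that("coefficient importance is symmetric, null on dead features, and VIP-concordant", {
  toy <- separable_toy()
  m <- fit_pls(toy$x, toy$labels, 2)
  m_swap <- fit_pls(toy$x, c(a = "b", b = "a")[toy$labels], 2)
  expect_equal(coef_importance(m), coef_importance(m_swap), tolerance = 1e-8)
  # feature with zero coefficients
  m0 <- m
  m0$coefficients[2, ] <- 0
  expect_equal(coef_importance(m0)[2], 0)
  # concordance with VIP on a structured draw
  set <- generate_dataset(generator_config(n_per_group = 10, seed = 13))
  pre <- preprocess_pipeline(set)
  mm <- fit_pls(pre$intensities, pre$labels, 3)
  rho <- stats::cor(coef_importance(mm), vip_scores(mm), method = "spearman")
  expect_gt(rho, 0.5)
})

test_that("evaluation bundles coherent performance numbers", {
  set <- generate_dataset(generator_config(n_per_group = 8, seed = 23))
  pre <- preprocess_pipeline(set)
  perf <- plsda_evaluate(pre, n_perm = 99, seed = 2, a_max = 6)
  expect_gte(perf$r2, perf$q2)
  expect_true(perf$accuracy >= 0 && perf$accuracy <= 1)
  expect_true(perf$permutation_p > 0 && perf$permutation_p <= 1)
  expect_equal(sum(perf$vip^2), length(perf$vip), tolerance = 1e-6)
})
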