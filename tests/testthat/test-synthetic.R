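test_that("group templates carry one band per assignment-table entry", {
  tmpl <- default_group_templates()
  centers <- lapply(tmpl, function(bl) vapply(bl, `[[`, numeric(1), "center"))
  labels <- lapply(tmpl, function(bl) vapply(bl, `[[`, character(1), "assignment"))
  expect_true(any(centers$TEIR == 1743 &
                    labels$TEIR == "CO stretching-phospholipid"))
  expect_true(any(centers$SEC == 977 &
                    labels$SEC == "O-P-O symmetric stretching of phospholipids"))
  expect_true(any(centers$UC == 1665))
  bt <- read_band_table()
  for (g in names(tmpl))
    expect_length(tmpl[[g]],
                  sum(bt$method == g & bt$modality == "AFM-IR"))
})

test_that("generator is bit-identical under a fixed config and seed", {
  cfg <- tiny_config(n = 3, seed = 7, noise_sd = 0.3, jitter = 0.2,
                     albumin = 0.2, baseline = 0.2)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$intensities, b$intensities)
  expect_identical(attr(a, "ground_truth"), attr(b, "ground_truth"))
  n1 <- generate_null_dataset(cfg)
  n2 <- generate_null_dataset(cfg)
  expect_identical(n1$intensities, n2$intensities)
})

test_that("degenerate generator reproduces the group templates exactly", {
  cfg <- tiny_config(n = 2, seed = 1)
  set <- generate_dataset(cfg)
  for (g in c("TEIR", "UC", "SEC")) {
    tspec <- sum_bands(cfg$axis, cfg$group_templates[[g]])
    rows <- set$intensities[set$labels == g, , drop = FALSE]
    for (i in seq_len(nrow(rows))) expect_equal(unname(rows[i, ]), tspec)
  }
})

test_that("doubling template amplitudes doubles noiseless spectra", {
  cfg <- tiny_config(n = 2, seed = 1)
  cfg2 <- cfg
  cfg2$group_templates <- lapply(cfg$group_templates, function(bl)
    lapply(bl, function(b) pv_band(b$center, b$fwhm, b$eta, 2 * b$amplitude)))
  expect_equal(generate_dataset(cfg2)$intensities,
               2 * generate_dataset(cfg)$intensities)
})

test_that("generated sets are finite, balanced, and sized 3 n_per_group", {
  cfg <- generator_config(n_per_group = 5, seed = 3)
  set <- generate_dataset(cfg)
  expect_equal(nrow(set$intensities), 15)
  expect_equal(as.integer(table(set$labels)), rep(5L, 3))
  expect_true(all(is.finite(set$intensities)))
  expect_equal(anyDuplicated(set$sample_ids), 0L)
})

test_that("invalid configs are rejected with named problems", {
  expect_error(generator_config(n_per_group = 1), "n_per_group")
  cfg <- generator_config()
  cfg$group_templates$TEIR[[1]]$eta <- 1.5
  expect_match(paste(validate_config(cfg), collapse = " "), "eta")
  cfg2 <- generator_config()
  cfg2$seed <- NULL
  expect_match(paste(validate_config(cfg2), collapse = " "), "seed")
})

test_that("between-group contrast concentrates at the planted phosphate and glycosidic windows", {
  set <- generate_dataset(generator_config())
  pre <- preprocess_pipeline(set)
  gm <- rowsum(pre$intensities, pre$labels) / as.vector(table(pre$labels))
  bg_var <- apply(gm, 2, var)
  axis <- pre$axis
  win <- (axis >= 967 & axis <= 982) | (axis >= 1025 & axis <= 1040)
  # the single largest between-group difference sits in a planted window
  diffs <- apply(gm, 2, function(v) max(v) - min(v))
  expect_true(win[which.max(diffs)])
  # integrated between-group variance beats every equal-width outside window
  w <- sum(win)
  outside_max <- 0
  for (s in seq_len(length(axis) - w + 1)) {
    idx <- s:(s + w - 1)
    if (!any(win[idx])) outside_max <- max(outside_max, sum(bg_var[idx]))
  }
  expect_gt(sum(bg_var[win]), outside_max)
})

test_that("null generator has identical expected templates across groups", {
  cfg <- tiny_config(n = 2, seed = 5)
  nul <- generate_null_dataset(cfg)
  gm <- rowsum(nul$intensities, nul$labels) / 2
  expect_equal(gm["TEIR", ], gm["UC", ])
  expect_equal(gm["TEIR", ], gm["SEC", ])
})
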