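test_that("batch_normalize matches the RMS formula and unit-RMS postcondition", {
  tab <- feature_table(matrix(c(3, 4), 2, 1), group = c("case", "control"),
                       batch = c("B1", "B1"))
  out <- batch_normalize(tab)
  rms <- sqrt((9 + 16) / 2)
  expect_equal(out$intensities[, 1], c(S1 = 3, S2 = 4) / rms)

  tab2 <- tiny_table(p = 6, n_batches = 2, seed = 1)
  out2 <- batch_normalize(tab2)
  for (b in levels(out2$batch)) {
    rms_b <- sqrt(colMeans(out2$intensities[out2$batch == b, , drop = FALSE]^2))
    expect_equal(unname(rms_b), rep(1, 6), tolerance = 1e-12)
  }
  # constant marker within a batch maps to all ones
  tab3 <- feature_table(matrix(5, 4, 1), group = rep(c("case", "control"), 2),
                        batch = rep("B1", 4))
  expect_equal(unname(batch_normalize(tab3)$intensities[, 1]), rep(1, 4))
})

test_that("batch_normalize cancels per-batch rescaling and flags zero blocks", {
  tab <- tiny_table(p = 4, n_batches = 2, seed = 2)
  scaled <- tab
  scaled$intensities[scaled$batch == "B2", ] <-
    scaled$intensities[scaled$batch == "B2", ] * 7.5
  expect_equal(batch_normalize(scaled)$intensities,
               batch_normalize(tab)$intensities, tolerance = 1e-12)
  # applying twice equals applying once (second pass divides by 1)
  once <- batch_normalize(tab)
  expect_equal(batch_normalize(once)$intensities, once$intensities,
               tolerance = 1e-12)
  zero <- tab
  zero$intensities[zero$batch == "B1", 2] <- 0
  expect_error(batch_normalize(zero), "B1")
})

test_that("log_transform honors base/offset and rejects nonpositive input", {
  tab <- feature_table(matrix(c(1, 100, 10, 1000), 2, 2),
                       group = c("case", "control"), batch = c("B1", "B1"))
  out <- log_transform(tab, preprocess_config(log_base = 10))
  expect_equal(unname(out$intensities), matrix(c(0, 2, 1, 3), 2, 2))
  zero <- feature_table(matrix(c(0, 1), 2, 1), group = c("case", "control"),
                        batch = c("B1", "B1"))
  expect_error(log_transform(zero), "S1")
  expect_equal(unname(log_transform(zero,
                 preprocess_config(log_offset = 1))$intensities[, 1]),
               log10(c(1, 2)))
})

test_that("pareto_scale centers and divides by sqrt(sample sd)", {
  tab <- feature_table(matrix(c(1, 2, 3), 3, 1),
                       group = c("case", "control", "control"),
                       batch = rep("B1", 3))
  out <- pareto_scale(tab)
  expect_equal(unname(out$intensities[, 1]), c(-1, 0, 1))  # sd 1, sqrt 1
  expect_s3_class(out, "processed_table")

  tab2 <- tiny_table(p = 5, seed = 3)
  out2 <- pareto_scale(tab2)
  expect_equal(unname(colMeans(out2$intensities)), rep(0, 5),
               tolerance = 1e-12)
  # post-scaling column variance equals the raw column sd
  expect_equal(unname(apply(out2$intensities, 2, var)),
               unname(apply(tab2$intensities, 2, sd)), tolerance = 1e-10)

  const <- feature_table(matrix(c(2, 2, 2, 1, 5, 9), 3, 2),
                         group = c("case", "control", "control"),
                         batch = rep("B1", 3))
  outc <- pareto_scale(const)
  expect_equal(unname(outc$intensities[, 1]), rep(0, 3))
  expect_identical(unname(attr(outc, "zero_variance")), c(TRUE, FALSE))
  expect_error(pareto_scale(subset_one <- feature_table(
    matrix(1, 1, 1), group = "case", batch = "B1")), "2 samples")
})

test_that("preprocess applies steps in fixed order and records them", {
  tab <- tiny_table(p = 4, n_batches = 2, seed = 4)
  out <- preprocess(tab)
  expect_identical(attr(out, "steps"), c("batch_norm", "log", "pareto"))
  manual <- pareto_scale(log_transform(batch_normalize(tab)))
  expect_equal(out$intensities, manual$intensities, tolerance = 1e-14)

  off <- preprocess(tab, preprocess_config(apply_batch_norm = FALSE,
                                           apply_log = FALSE,
                                           apply_pareto = FALSE))
  expect_equal(off$intensities, tab$intensities)
  expect_null(attr(off, "steps"))
})

test_that("full pipeline is invariant to per-batch multiplicative rescaling", {
  tab <- tiny_table(p = 6, n_batches = 3, seed = 5)
  scaled <- tab
  for (b in levels(tab$batch)) {
    k <- c(B1 = 0.2, B2 = 3, B3 = 17)[[b]]
    scaled$intensities[scaled$batch == b, ] <-
      scaled$intensities[scaled$batch == b, ] * k
  }
  expect_equal(preprocess(scaled)$intensities, preprocess(tab)$intensities,
               tolerance = 1e-10)
})
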