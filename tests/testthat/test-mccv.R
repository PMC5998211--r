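# Small, fast MCCV configuration used throughout this file.
small_mccv <- function(seed = 1, N = 8, ...) {
  mccv_config(n_iterations = N, seed = seed,
              sbs = sbs_config(n_trees = 60, seed = seed), ...)
}

small_cohort <- function(seed = 1, n_informative = 2, n_markers = 12,
                         effect = 3) {
  eff <- if (n_informative > 0) rep(effect, n_informative) else NULL
  generate_cohort(synthetic_config(
    n_case = 12, n_control = 14, n_markers = n_markers,
    n_informative = n_informative, effect_log2fc = eff,
    noise_sd = 0.4, seed = seed))
}

test_that("mccv_run bookkeeping: N iterations, disjoint exhaustive splits", {
  tab <- small_cohort()
  res <- mccv_run(tab, small_mccv(N = 8))
  expect_length(res$iterations, 8)
  expect_length(res$test_auc, 8)
  for (it in res$iterations) {
    expect_identical(sort(c(it$train, it$test)), seq_len(26L))
    expect_length(intersect(it$train, it$test), 0)
  }
  expect_equal(res$mean_auc, mean(res$test_auc))
  # stratification: each side keeps both classes
  g <- tab$group
  for (it in res$iterations) {
    expect_gte(sum(g[it$train] == "case"), 2)
    expect_gte(sum(g[it$test] == "control"), 2)
  }
})

test_that("mccv_run is reproducible end to end and seed-sensitive", {
  tab <- small_cohort()
  r1 <- mccv_run(tab, small_mccv(seed = 5, N = 4))
  r2 <- mccv_run(tab, small_mccv(seed = 5, N = 4))
  expect_identical(r1$test_auc, r2$test_auc)
  expect_identical(r1$rank_frequency, r2$rank_frequency)
  expect_identical(r1$composite$points, r2$composite$points)
  r3 <- mccv_run(tab, small_mccv(seed = 6, N = 4))
  # a different base seed draws different splits (AUCs may coincide when the
  # classes are strongly separable, so compare the splits themselves)
  expect_false(identical(lapply(r1$iterations, `[[`, "train"),
                         lapply(r3$iterations, `[[`, "train")))
})

test_that("pareto constants depend only on the training rows (no leakage)", {
  tab <- small_cohort()
  cfg <- small_mccv(N = 1)
  sp <- metaboselect:::mccv_split(tab$group, 0.7, TRUE,
                                  (cfg$seed + 7919L) %% 2147483647L)
  norm <- log_transform(batch_normalize(tab))
  train_const <- attr(pareto_scale(
    metaboselect:::subset_samples(norm, sp$train)), "centers")
  # perturbing only test rows leaves the constants identical
  perturbed <- norm
  perturbed$intensities[sp$test, ] <- perturbed$intensities[sp$test, ] + 99
  train_const2 <- attr(pareto_scale(
    metaboselect:::subset_samples(perturbed, sp$train)), "centers")
  expect_identical(train_const, train_const2)
  # perturbing training rows changes them
  perturbed2 <- norm
  perturbed2$intensities[sp$train, ] <- perturbed2$intensities[sp$train, ] + 1
  expect_false(identical(train_const, attr(pareto_scale(
    metaboselect:::subset_samples(perturbed2, sp$train)), "centers")))
})

test_that("rank_frequency is counts/N and planted markers rise to the top", {
  tab <- small_cohort(n_informative = 2)
  res <- mccv_run(tab, small_mccv(N = 10))
  rf <- rank_frequency(res)
  expect_true(all(rf >= 0 & rf <= 1))
  counts <- table(unlist(lapply(res$iterations, `[[`, "selected")))
  expect_equal(unname(rf[names(counts)]), as.numeric(counts) / 10)
  expect_true(all(rf[setdiff(names(rf), names(counts))] == 0))
  pl <- attr(tab, "planted")$marker
  expect_gt(mean(rf[pl]), max(stats::quantile(rf[setdiff(names(rf), pl)], 0.9),
                              0.01))
})

test_that("validate-only mode skips selection and uses the fixed panel", {
  tab <- small_cohort()
  res <- mccv_run(tab, small_mccv(N = 3, select = FALSE))
  for (it in res$iterations) expect_identical(it$selected, tab$markers)
  expect_true(all(rank_frequency(res) == 1))
})

test_that("composite_roc vertically averages with the hand-derived value", {
  perfect <- structure(list(points = data.frame(fpr = c(0, 0, 1),
                                                tpr = c(0, 1, 1)),
                            auc = 1, positive_class = "case"),
                       class = "roc_curve")
  diagonal <- structure(list(points = data.frame(fpr = c(0, 1),
                                                 tpr = c(0, 1)),
                             auc = 0.5, positive_class = "case"),
                        class = "roc_curve")
  comp <- composite_roc(list(perfect, diagonal))
  pts <- comp$points
  expect_equal(pts$tpr[pts$fpr == 0.5], 0.75)
  expect_equal(pts$tpr[1], 0); expect_equal(pts$tpr[nrow(pts)], 1)
  expect_true(all(diff(pts$tpr) >= 0))
  expect_true(comp$auc >= 0 && comp$auc <= 1)
  # mean of identical diagonals is the diagonal at grid resolution
  same <- composite_roc(list(diagonal, diagonal))
  expect_equal(same$points$tpr, same$points$fpr, tolerance = 1e-12)
  expect_error(composite_roc(list()), "no valid ROC")
})

test_that("marker_table filters by rank frequency and carries directions", {
  tab <- small_cohort(n_informative = 2)
  res <- mccv_run(tab, small_mccv(N = 10))
  mt <- marker_table(res, min_rank_freq = 0.5)
  expect_true(all(mt$rank_freq >= 0.5))
  expect_true(all(diff(mt$rank_freq) <= 0))
  expect_true(all(mt$control_level %in% c("Low", "High")))
  # positive planted effects: control Low, case High, matching the
  # univariate direction call on the full normalized table
  pl <- attr(tab, "planted")$marker
  got <- mt[mt$marker %in% pl, ]
  if (nrow(got)) expect_true(all(got$case_level == "High"))
  all_sel <- marker_table(res, 0)
  expect_setequal(all_sel$marker,
                  names(which(rank_frequency(res) > 0)))
})

test_that("degenerate aggregation: N = 1 equals the single iteration", {
  tab <- small_cohort()
  res <- mccv_run(tab, small_mccv(N = 1))
  expect_equal(res$mean_auc, res$iterations[[1]]$auc)
  expect_true(all(rank_frequency(res) %in% c(0, 1)))
})
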