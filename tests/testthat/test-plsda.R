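test_that("single predictor equal to the centered response is fit exactly", {
  y01 <- c(1, 1, 0, 0, 1, 0)
  x <- matrix(y01 - mean(y01), 6, 1)
  tab <- structure(list(intensities = x,
                        group = factor(ifelse(y01 == 1, "case", "control"),
                                       levels = c("control", "case")),
                        batch = factor(rep("B1", 6)),
                        sample_id = paste0("S", 1:6), markers = "M1"),
                   class = "feature_table")
  m <- fit_plsda(tab, n_components = 1)
  expect_equal(abs(m$weights[1, 1]), 1)
  expect_equal(m$ss_y[1], sum((y01 - mean(y01))^2))  # total response SS
})

test_that("weights and explained SS agree with an independent NIPALS oracle", {
  set.seed(99)
  for (rep in 1:5) {
    n <- 6 + rep; p <- 3 + rep
    x <- matrix(rnorm(n * p), n, p)
    g <- rep_len(c("case", "control"), n)
    tab <- feature_table(abs(x) + 1, group = g, batch = rep("B1", n))
    tab$intensities <- x  # arbitrary-sign data, bypassing raw validation
    m <- fit_plsda(tab, n_components = 2)
    orc <- nipals_oracle(x, as.numeric(g == "case"), 2)
    # sign indeterminacy: compare columns up to sign
    for (k in 1:2) {
      s <- sign(sum(m$weights[, k] * orc$W[, k]))
      expect_equal(m$weights[, k], s * orc$W[, k], tolerance = 1e-8)
    }
    expect_equal(m$ss_y, orc$ssy, tolerance = 1e-8)
  }
})

test_that("duplicating every sample leaves weights and VIPs unchanged", {
  tab <- tiny_table(n_case = 5, n_control = 6, p = 8, seed = 6)
  proc <- pareto_scale(log_transform(tab))
  dup <- subset_samples(proc, rep(seq_len(11), 2))
  dup$sample_id <- paste0("S", 1:22)
  m1 <- fit_plsda(proc, 2); m2 <- fit_plsda(dup, 2)
  expect_equal(abs(m1$weights), abs(m2$weights), tolerance = 1e-8)
  expect_equal(global_vip(m1), global_vip(m2), tolerance = 1e-8)
})

test_that("VIP matches the direct formula and mean-square-1 normalization", {
  tab <- tiny_table(n_case = 4, n_control = 4, p = 4, seed = 7)
  m <- fit_plsda(pareto_scale(log_transform(tab)), n_components = 2)
  for (a in 1:2) {
    v <- vip_scores(m, a)
    expect_equal(unname(v), vip_oracle(m$weights, m$ss_y, a),
                 tolerance = 1e-12)
    expect_lt(abs(mean(v^2) - 1), 1e-10)
  }
  expect_error(vip_scores(m, 3), "must be in")
  # single-component closed form: W[,1] = (1,0,0) -> VIP = (sqrt(3),0,0)
  fake <- structure(list(weights = matrix(c(1, 0, 0), 3, 1), ss_y = 2,
                         n_components = 1L, marker_names = c("a", "b", "c")),
                    class = "pls_model")
  expect_equal(unname(vip_scores(fake, 1)), c(sqrt(3), 0, 0))
})

test_that("global VIP is the max over depths; sign flips and permutations", {
  tab <- tiny_table(n_case = 6, n_control = 6, p = 10, seed = 8)
  proc <- pareto_scale(log_transform(tab))
  m <- fit_plsda(proc, 3)
  g <- global_vip(m)
  for (a in 1:3) expect_true(all(g >= vip_scores(m, a) - 1e-12))
  flipped <- m
  flipped$weights[, 2] <- -flipped$weights[, 2]
  expect_equal(global_vip(flipped), g)
  # permuting marker columns permutes VIPs identically
  perm <- sample(10)
  ptab <- proc
  ptab$intensities <- proc$intensities[, perm]
  ptab$markers <- proc$markers[perm]
  gp <- global_vip(fit_plsda(ptab, 3))
  expect_equal(gp[proc$markers], g, tolerance = 1e-10)
})

test_that("select_by_vip filters/sorts and errors surface on degenerate input", {
  rep_df <- data.frame(
    marker = sprintf("m%02d", 1:12),
    global = c(2.9, 2.8, 2.7, 2.1, 2.1, 2.1, 2.1, 2.1, 2.1, 2.0, 1.9, 1.5))
  sel <- select_by_vip(rep_df, 2.0)
  expect_identical(length(sel), 10L)
  expect_false("m11" %in% sel)
  expect_identical(sel[1:3], c("m01", "m02", "m03"))
  expect_identical(select_by_vip(rep_df, 0), rep_df$marker)
  expect_identical(select_by_vip(rep_df, 99), character(0))

  one_class <- tiny_table(n_case = 4, n_control = 4, p = 3)
  one_class$group <- factor(rep("case", 8), levels = c("control", "case"))
  expect_error(fit_plsda(one_class), "both classes")
})

test_that("planted markers get higher mean global VIP than null markers", {
  gaps <- vapply(1:20, function(s) {
    cfg <- synthetic_config(n_case = 10, n_control = 10, n_markers = 40,
                            n_informative = 5, seed = s)
    tab <- generate_cohort(cfg)
    g <- global_vip(fit_plsda(preprocess(tab), 3))
    pl <- planted_markers(cfg)$marker
    mean(g[pl]) - mean(g[setdiff(names(g), pl)])
  }, numeric(1))
  expect_gt(mean(gaps), 0)
})
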