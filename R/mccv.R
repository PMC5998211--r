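#' Configuration for Monte Carlo cross-validation
#'
#' @param n_iterations number of random train/test splits N (default 50).
#' @param train_fraction fraction of each class (when stratified) assigned to
#'   training (default 0.7).
#' @param stratified split within each class (default `TRUE`); every split
#'   must leave at least 2 samples per class on each side.
#' @param seed base seed; iteration seeds are derived by fixed offsets so
#'   results are reproducible and early iterations do not change when
#'   `n_iterations` grows.
#' @param sbs an [sbs_config()] driving per-split marker selection.
#' @param preprocess a [preprocess_config()]; batch normalization and the log
#'   transform are applied to the full table before splitting (batch structure
#'   is a property of acquisition, not of the classifier), while pareto
#'   centering/scaling constants are fitted on training data only.
#' @param select when `TRUE` (default) sequential backward selection is re-run
#'   inside every split; when `FALSE` a fixed panel (`markers`) is only
#'   validated.
#' @param markers optional fixed panel for `select = FALSE` (default: all).
#' @return an `mccv_config` object.
#' @export
mccv_config <- function(n_iterations = 50L, train_fraction = 0.7,
                        stratified = TRUE, seed = 1L,
                        sbs = sbs_config(), preprocess = preprocess_config(),
                        select = TRUE, markers = NULL) {
  if (n_iterations < 1L) stop("`n_iterations` must be >= 1")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("`train_fraction` must be in (0, 1)")
  structure(list(n_iterations = as.integer(n_iterations),
                 train_fraction = train_fraction,
                 stratified = isTRUE(stratified),
                 seed = as.integer(seed),
                 sbs = sbs, preprocess = preprocess,
                 select = isTRUE(select), markers = markers),
            class = "mccv_config")
}

# Row subset of a feature table, keeping labels aligned. Built without the
# raw-data validation: transformed intensities may legitimately be negative.
subset_samples <- function(table, rows) {
  structure(
    list(intensities = table$intensities[rows, , drop = FALSE],
         group = table$group[rows],
         batch = table$batch[rows],
         sample_id = table$sample_id[rows],
         markers = table$markers),
    class = "feature_table", steps = attr(table, "steps"))
}

# Stratified (or plain) train indices for one iteration, drawn under `seed`.
mccv_split <- function(group, train_fraction, stratified, seed) {
  n <- length(group)
  train <- local_seed(seed, {
    if (stratified) {
      unlist(lapply(c("control", "case"), function(cl) {
        rows <- which(group == cl)
        sample(rows, round(train_fraction * length(rows)))
      }), use.names = FALSE)
    } else {
      sample.int(n, round(train_fraction * n))
    }
  })
  train <- sort(train)
  test <- setdiff(seq_len(n), train)
  for (side in list(train, test))
    for (cl in c("control", "case"))
      if (sum(group[side] == cl) < 2L)
        stop("infeasible split: fewer than 2 ", cl,
             " samples on one side; adjust train_fraction or cohort size")
  list(train = train, test = test)
}

#' Monte Carlo cross-validation around backward selection
#'
#' Repeats N times: stratified random split; pareto centering/scaling fitted
#' on the training rows only and applied to the test rows; sequential backward
#' selection (random-forest OOB criterion) on the training data; a final
#' forest on the selected subset scoring the test rows (case-class vote
#' fraction); test ROC and AUC. Aggregates per-marker rank frequencies
#' (fraction of iterations selected), mean rescaled importances, direction
#' calls on batch-normalized data, the test-AUC distribution and a composite
#' ROC curve. Fully deterministic given `config$seed`.
#'
#' @param table a raw [feature_table()]; batch normalization / log transform
#'   are applied internally per `config$preprocess`. (If the table's step
#'   record shows a step already applied, it is not applied again.)
#' @param config an [mccv_config()].
#' @return an `mccv_result`: list with `iterations` (per-iteration list of
#'   `train`, `test`, `selected`, `oob_error`, `test_scores`, `roc`, `auc`),
#'   `test_auc` (length-N vector), `rank_frequency` (named, all markers),
#'   `importance` (named mean rescaled importance; `NA` if never selected),
#'   `directions` (data.frame of Low/High calls), `composite` (a composite
#'   ROC curve), `mean_auc`, `config`, `markers`.
#' @export
mccv_run <- function(table, config = mccv_config()) {
  stopifnot(inherits(table, "feature_table"))
  assert_two_classes(table$group)

  done <- attr(table, "steps")
  pp <- config$preprocess
  if (pp$apply_batch_norm && !"batch_norm" %in% done)
    table <- batch_normalize(table)
  norm_x <- if (!is.null(attr(table, "normalized_intensities")))
    attr(table, "normalized_intensities") else table$intensities
  if (pp$apply_log && !"log" %in% attr(table, "steps"))
    table <- log_transform(table, pp)

  markers <- table$markers
  panel <- if (is.null(config$markers)) markers else config$markers
  N <- config$n_iterations
  iters <- vector("list", N)
  sel_count <- stats::setNames(numeric(length(markers)), markers)
  imp_sum <- stats::setNames(numeric(length(markers)), markers)
  test_auc <- numeric(N)

  for (i in seq_len(N)) {
    iter_seed <- (config$seed + 7919L * i) %% 2147483647L
    sp <- mccv_split(table$group, config$train_fraction, config$stratified,
                     seed = iter_seed)
    train <- subset_samples(table, sp$train)
    test <- subset_samples(table, sp$test)
    if (pp$apply_pareto) {
      train <- pareto_scale(train)
      test <- apply_pareto(test, attr(train, "centers"),
                           attr(train, "scales"))
    }
    sbs_cfg <- config$sbs
    sbs_cfg$seed <- iter_seed
    if (config$select) {
      trace <- sbs(train, sbs_cfg, markers = panel)
      selected <- trace$selected_markers
      oob_err <- trace$rounds$oob_error[trace$best_round]
    } else {
      selected <- panel
      oob_err <- NA_real_
    }
    # final forest on the selected subset scores the held-out samples
    y <- as.integer(train$group == "case")
    Xtr <- train$intensities[, selected, drop = FALSE]
    Xte <- test$intensities[, selected, drop = FALSE]
    mtry <- if (is.null(sbs_cfg$mtry)) max(1L, floor(sqrt(ncol(Xtr))))
            else min(sbs_cfg$mtry, ncol(Xtr))
    fit <- cpp_random_forest(Xtr, y, ntree = sbs_cfg$n_trees, mtry = mtry,
                             seed = as.double(iter_seed) + 0.5, Xtest = Xte,
                             importance = TRUE)
    scores <- fit$test_prob
    rc <- roc_curve(scores, test$group)
    test_auc[i] <- rc$auc

    imp <- stats::setNames(fit$importance, selected)
    msq <- mean(imp^2)
    if (msq > 0) imp <- imp / sqrt(msq)  # VIP-like: panel mean square = 1
    sel_count[selected] <- sel_count[selected] + 1
    imp_sum[selected] <- imp_sum[selected] + imp

    iters[[i]] <- list(train = sp$train, test = sp$test, selected = selected,
                       oob_error = oob_err, test_scores = scores,
                       roc = rc, auc = rc$auc)
  }

  rank_freq <- sel_count / N
  importance <- ifelse(sel_count > 0, imp_sum / sel_count, NA_real_)
  dirs <- do.call(rbind, lapply(seq_along(markers), function(j) {
    dc <- direction_call(norm_x[, j], table$group)
    data.frame(marker = markers[j], control_level = dc$control_level,
               case_level = dc$case_level, stringsAsFactors = FALSE)
  }))
  res <- structure(list(iterations = iters, test_auc = test_auc,
                        rank_frequency = rank_freq, importance = importance,
                        directions = dirs, mean_auc = mean(test_auc),
                        config = config, markers = markers),
                   class = "mccv_result")
  res$composite <- composite_roc(res)
  res
}

#' @export
print.mccv_result <- function(x, ...) {
  cat("<mccv_result> ", length(x$iterations), " iterations, mean test AUC ",
      format(x$mean_auc, digits = 3), "\n", sep = "")
  top <- sort(x$rank_frequency, decreasing = TRUE)
  top <- top[top > 0]
  cat("  markers with rank frequency > 0: ", length(top), "\n", sep = "")
  invisible(x)
}

#' Per-marker rank frequency
#'
#' Fraction of MCCV iterations in which each marker was in the selected
#' subset; markers never selected have 0.
#'
#' @param result an `mccv_result`.
#' @return named numeric vector in `[0, 1]`, one entry per marker.
#' @export
rank_frequency <- function(result) {
  stopifnot(inherits(result, "mccv_result"))
  result$rank_frequency
}

#' Composite (vertically averaged) ROC curve
#'
#' Averages the per-iteration test ROC curves on a fixed false-positive-rate
#' grid (101 points from 0 to 1): each curve is linearly interpolated after
#' collapsing vertical segments to their upper TPR, TPRs are averaged per grid
#' point, and the first grid point is pinned to (0, 0) so the composite runs
#' monotonically from (0,0) to (1,1).
#'
#' @param result an `mccv_result` (or a plain list of `roc_curve` objects).
#' @param grid_size number of FPR grid points (default 101).
#' @return a `roc_curve` whose `points` also carry `sd_tpr`, the per-grid-point
#'   standard deviation across iterations.
#' @export
composite_roc <- function(result, grid_size = 101L) {
  curves <- if (inherits(result, "mccv_result"))
    lapply(result$iterations, `[[`, "roc") else result
  curves <- Filter(function(cv) inherits(cv, "roc_curve"), curves)
  if (!length(curves)) stop("no valid ROC curves to average")
  grid <- seq(0, 1, length.out = grid_size)
  tprs <- vapply(curves, function(cv) {
    pts <- cv$points
    # collapse duplicated FPRs (vertical segments) to their max TPR
    up <- tapply(pts$tpr, pts$fpr, max)
    fx <- as.numeric(names(up))
    stats::approx(fx, as.numeric(up), xout = grid, rule = 2)$y
  }, numeric(grid_size))
  tprs <- matrix(tprs, nrow = grid_size)
  mean_tpr <- rowMeans(tprs)
  sd_tpr <- apply(tprs, 1, stats::sd)
  mean_tpr[1] <- 0
  pts <- data.frame(fpr = grid, tpr = mean_tpr, sd_tpr = sd_tpr)
  structure(list(points = pts, auc = trapezoid_area(grid, mean_tpr),
                 positive_class = "case"),
            class = "roc_curve")
}

#' Marker summary table from an MCCV run
#'
#' Markers with rank frequency at or above a threshold, each with its mean
#' rescaled importance score and Low/High direction call, sorted by rank
#' frequency then importance descending.
#'
#' @param result an `mccv_result`.
#' @param min_rank_freq retention threshold (default 0.5).
#' @return data.frame `marker, rank_freq, importance, control_level,
#'   case_level`.
#' @export
marker_table <- function(result, min_rank_freq = 0.5) {
  stopifnot(inherits(result, "mccv_result"))
  rf <- result$rank_frequency
  keep <- names(rf)[rf >= min_rank_freq & rf > 0]
  df <- data.frame(marker = keep,
                   rank_freq = unname(rf[keep]),
                   importance = unname(result$importance[keep]),
                   stringsAsFactors = FALSE)
  df <- merge(df, result$directions, by = "marker", sort = FALSE)
  df <- df[order(-df$rank_freq, -df$importance, df$marker), , drop = FALSE]
  rownames(df) <- NULL
  df
}
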