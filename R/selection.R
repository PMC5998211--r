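#' Configuration for random-forest sequential backward selection
#'
#' Only the criterion (out-of-bag error) and the direction (backward) are
#' fixed; elimination schedule, floor, tree count and tie rule are tunable.
#'
#' @param n_trees trees per forest (default 500).
#' @param elimination_fraction fraction of surviving markers dropped per round
#'   (default 0.2; at least one marker is always dropped).
#' @param min_subset smallest subset size considered (default 2).
#' @param one_se_rule when `TRUE` (default) the selected round is the smallest
#'   subset whose OOB error is within one binomial standard error of the
#'   minimum; when `FALSE`, the smallest subset attaining the minimum.
#' @param mtry features tried per split; default `floor(sqrt(p))` per round.
#' @param seed integer seed for the forests (per-round seeds derived by fixed
#'   offset).
#' @return an `sbs_config` object.
#' @export
sbs_config <- function(n_trees = 500L, elimination_fraction = 0.2,
                       min_subset = 2L, one_se_rule = TRUE, mtry = NULL,
                       seed = 1L) {
  if (elimination_fraction <= 0 || elimination_fraction >= 1)
    stop("`elimination_fraction` must be in (0, 1)")
  if (min_subset < 1L) stop("`min_subset` must be >= 1")
  if (n_trees < 1L) stop("`n_trees` must be >= 1")
  structure(list(n_trees = as.integer(n_trees),
                 elimination_fraction = elimination_fraction,
                 min_subset = as.integer(min_subset),
                 one_se_rule = isTRUE(one_se_rule),
                 mtry = if (is.null(mtry)) NULL else as.integer(mtry),
                 seed = as.integer(seed)),
            class = "sbs_config")
}

#' Random-forest OOB error and permutation importance on a marker subset
#'
#' Grows a two-class forest (bootstrap CART, Gini splits) on the restricted
#' marker set and returns the out-of-bag misclassification rate, its binomial
#' standard error, and per-marker permutation importance (mean decrease in
#' OOB accuracy). Deterministic given the seed.
#'
#' @param table a `processed_table`/`feature_table` with both classes.
#' @param markers character vector of marker names to use (default: all).
#' @param config an [sbs_config()].
#' @param seed overrides `config$seed` when given.
#' @param importance compute permutation importance (default `TRUE`).
#' @return list with `oob_error`, `oob_se`, `n_oob`, `importance` (named),
#'   `oob_prob` (per-sample case-class OOB vote fraction).
#' @export
rf_oob <- function(table, markers = table$markers, config = sbs_config(),
                   seed = config$seed, importance = TRUE) {
  stopifnot(inherits(table, "feature_table"))
  assert_two_classes(table$group)
  miss <- setdiff(markers, table$markers)
  if (length(miss))
    stop("unknown marker(s): ", paste(miss, collapse = ", "))
  if (length(markers) < 1L) stop("at least one marker required")
  X <- table$intensities[, markers, drop = FALSE]
  y <- as.integer(table$group == "case")
  mtry <- if (is.null(config$mtry)) max(1L, floor(sqrt(ncol(X))))
          else min(config$mtry, ncol(X))
  res <- cpp_random_forest(X, y, ntree = config$n_trees, mtry = mtry,
                           seed = as.double(seed), Xtest = NULL,
                           importance = importance)
  imp <- res$importance
  names(imp) <- markers
  e <- res$oob_error
  se <- if (res$n_oob > 0) sqrt(e * (1 - e) / res$n_oob) else NA_real_
  list(oob_error = e, oob_se = se, n_oob = res$n_oob,
       importance = imp, oob_prob = res$oob_prob)
}

# Round sizes: ceil-based shrink, always dropping at least one marker,
# clamped at min_subset. E.g. 100 with fraction 0.2 -> 100, 80, 64, 52, ...
sbs_schedule <- function(p, fraction, min_subset) {
  sizes <- p
  while (p > min_subset) {
    p <- max(min_subset, min(p - 1L, as.integer(ceiling(p * (1 - fraction)))))
    sizes <- c(sizes, p)
  }
  sizes
}

#' Sequential backward selection by random-forest OOB error
#'
#' Starts from the full marker panel and repeatedly drops the least important
#' surviving markers (importance recomputed each round on the surviving set),
#' recording the OOB error of every round; the selected subset is the round
#' minimizing OOB error, optionally under a one-standard-error rule favoring
#' smaller subsets.
#'
#' @param table a `processed_table`/`feature_table` with both classes.
#' @param config an [sbs_config()].
#' @param markers starting panel (default all markers in the table).
#' @return an `sbs_trace`: list with `rounds` (data.frame `round, n_markers,
#'   oob_error, oob_se, dropped_markers`), `surviving` (list of per-round
#'   marker sets), `importance` (list of per-round named importances),
#'   `best_round`, `selected_markers`.
#' @export
sbs <- function(table, config = sbs_config(), markers = table$markers) {
  stopifnot(inherits(table, "feature_table"))
  if (length(markers) < config$min_subset)
    stop("need at least `min_subset` (", config$min_subset, ") markers")
  sizes <- sbs_schedule(length(markers), config$elimination_fraction,
                        config$min_subset)
  n_rounds <- length(sizes)
  surv <- vector("list", n_rounds)
  imps <- vector("list", n_rounds)
  oob <- se <- numeric(n_rounds)
  dropped <- character(n_rounds)
  current <- markers
  for (r in seq_len(n_rounds)) {
    fit <- rf_oob(table, current, config, seed = config$seed + r - 1L)
    surv[[r]] <- current
    imps[[r]] <- fit$importance
    oob[r] <- fit$oob_error
    se[r] <- fit$oob_se
    if (r < n_rounds) {
      n_drop <- length(current) - sizes[r + 1L]
      # least important first; ties broken by marker name for determinism
      ord <- order(fit$importance, names(fit$importance))
      drop_set <- names(fit$importance)[ord[seq_len(n_drop)]]
      dropped[r] <- paste(drop_set, collapse = ";")
      current <- setdiff(current, drop_set)
    }
  }
  best <- pick_best_round(oob, se, sizes, config$one_se_rule)
  structure(list(
    rounds = data.frame(round = seq_len(n_rounds), n_markers = sizes,
                        oob_error = oob, oob_se = se,
                        dropped_markers = dropped,
                        stringsAsFactors = FALSE),
    surviving = surv, importance = imps,
    best_round = best, selected_markers = surv[[best]]),
    class = "sbs_trace")
}

# Minimum-OOB round; with the one-SE rule, the smallest subset whose error is
# within one SE of the minimum. Ties always resolve to fewer markers.
pick_best_round <- function(oob, se, sizes, one_se_rule) {
  i_min <- which(oob == min(oob))
  i_min <- i_min[which.min(sizes[i_min])]
  if (!one_se_rule) return(i_min)
  cutoff <- oob[i_min] + ifelse(is.na(se[i_min]), 0, se[i_min])
  ok <- which(oob <= cutoff)
  ok[which.min(sizes[ok])]
}

#' @export
print.sbs_trace <- function(x, ...) {
  cat("<sbs_trace> ", nrow(x$rounds), " rounds, best round ", x$best_round,
      " (", length(x$selected_markers), " markers, OOB error ",
      format(x$rounds$oob_error[x$best_round], digits = 3), ")\n", sep = "")
  invisible(x)
}
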