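#' Area under the ROC curve (Mann-Whitney identity)
#'
#' Probability that a uniformly chosen case value exceeds a uniformly chosen
#' control value, ties counting one half (midrank convention). The case group
#' is the positive class and the AUC is reported unflipped, so markers
#' decreased in cases give AUC < 0.5; direction is carried separately by
#' [direction_call()].
#'
#' @param values per-sample numeric scores.
#' @param groups per-sample class labels (case/control, aliases accepted).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(values, groups) {
  groups <- normalize_group_labels(groups)
  assert_two_classes(groups)
  if (length(values) != length(groups))
    stop("`values` and `groups` must have equal length")
  r <- rank(values, ties.method = "average")
  n1 <- sum(groups == "case"); n0 <- sum(groups == "control")
  (sum(r[groups == "case"]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve by threshold sweep
#'
#' One point per distinct threshold (predict case when `value >= threshold`),
#' plus the (0,0) endpoint. The trapezoidal area under the returned points
#' equals [auc()] exactly (to floating tolerance), including under ties.
#'
#' @inheritParams auc
#' @return a `roc_curve`: list with `points` (data.frame `fpr`, `tpr`,
#'   nondecreasing, from (0,0) to (1,1)), `auc`, `positive_class = "case"`.
#' @export
roc_curve <- function(values, groups) {
  groups <- normalize_group_labels(groups)
  assert_two_classes(groups)
  thr <- sort(unique(values), decreasing = TRUE)
  case <- values[groups == "case"]; ctrl <- values[groups == "control"]
  tpr <- vapply(thr, function(t) mean(case >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(ctrl >= t), numeric(1))
  pts <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  structure(list(points = pts,
                 auc = trapezoid_area(pts$fpr, pts$tpr),
                 positive_class = "case"),
            class = "roc_curve")
}

trapezoid_area <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("<roc_curve> ", nrow(x$points), " points, AUC = ",
      format(x$auc, digits = 4), " (positive class: ", x$positive_class,
      ")\n", sep = "")
  invisible(x)
}

#' Group direction call for a marker
#'
#' Labels each class Low or High by comparing group means. Meant to be run on
#' batch-normalized (pre-pareto) intensities, where means are interpretable;
#' centering/scaling would destroy the comparison.
#'
#' @inheritParams auc
#' @return list with `control_level` and `case_level` (each `"Low"`/`"High"`,
#'   always opposite) and `tie` (logical; when `TRUE` the call is withheld and
#'   both levels are `NA`).
#' @export
direction_call <- function(values, groups) {
  groups <- normalize_group_labels(groups)
  assert_two_classes(groups)
  m_case <- mean(values[groups == "case"])
  m_ctrl <- mean(values[groups == "control"])
  if (m_case == m_ctrl)
    return(list(control_level = NA_character_, case_level = NA_character_,
                tie = TRUE))
  if (m_case > m_ctrl)
    list(control_level = "Low", case_level = "High", tie = FALSE)
  else
    list(control_level = "High", case_level = "Low", tie = FALSE)
}

#' Per-marker univariate report
#'
#' For every marker: AUC and ROC curve on the processed values, a Low/High
#' direction call on the batch-normalized values (taken from the processed
#' table's `normalized_intensities` attribute when present, since AUC is
#' invariant to the monotone log/pareto steps but means are not), and
#' five-number box-plot summaries per class.
#'
#' @param table a `processed_table` (or `feature_table`).
#' @return list with `table`: data.frame `marker, auc, control_level,
#'   case_level, ctrl_q1..q5, case_q1..q5` sorted by AUC descending, and
#'   `curves`: named list of `roc_curve` objects.
#' @export
univariate_report <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  assert_two_classes(table$group)
  x <- table$intensities
  norm <- attr(table, "normalized_intensities")
  if (is.null(norm)) norm <- x
  g <- table$group
  five <- function(v) stats::quantile(v, c(0, .25, .5, .75, 1), names = FALSE)
  rows <- lapply(seq_along(table$markers), function(j) {
    dc <- direction_call(norm[, j], g)
    c(list(marker = table$markers[j],
           auc = auc(x[, j], g),
           control_level = dc$control_level,
           case_level = dc$case_level),
      stats::setNames(as.list(five(norm[g == "control", j])),
                      paste0("ctrl_q", 1:5)),
      stats::setNames(as.list(five(norm[g == "case", j])),
                      paste0("case_q", 1:5)))
  })
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  curves <- lapply(seq_along(table$markers),
                   function(j) roc_curve(x[, j], g))
  names(curves) <- table$markers
  ord <- order(-df$auc, df$marker)
  list(table = df[ord, , drop = FALSE], curves = curves[ord])
}
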