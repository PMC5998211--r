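#' Fit a two-class PLS-DA model by NIPALS
#'
#' Partial least squares discriminant analysis against a centered 0/1 class
#' response, extracted component by component with X-deflation (NIPALS).
#' The class response is `control = 0`, `case = 1`, mean-centered; X columns
#' are mean-centered internally (pareto-scaled input is already centered, in
#' which case this is a no-op). Weight columns have unit Euclidean norm;
#' scores are projections of the deflated X. Deterministic: the score
#' iteration is initialized from the response vector, no randomness.
#'
#' @param table a `processed_table` (or any `feature_table`) with both classes
#'   present.
#' @param n_components number of components A (default 3); must not exceed
#'   `min(samples - 1, markers)`. If X runs out of rank earlier, fewer
#'   components are returned with a warning.
#' @param tol NIPALS convergence tolerance on the score vector (default 1e-10).
#' @param max_iter maximum NIPALS iterations per component (default 500).
#' @return a `pls_model`: list with `weights` (p x A, unit-norm columns),
#'   `scores` (n x A), `x_loadings` (p x A), `y_loadings` (length A),
#'   `ss_y` (per-component explained sum of squares of the response,
#'   nonnegative), `n_components`, `marker_names`.
#' @export
fit_plsda <- function(table, n_components = 3L, tol = 1e-10, max_iter = 500L) {
  stopifnot(inherits(table, "feature_table"))
  assert_two_classes(table$group)
  X <- table$intensities
  n <- nrow(X); p <- ncol(X)
  A <- as.integer(n_components)
  if (A < 1L || A > min(n - 1L, p))
    stop("`n_components` must be in [1, min(samples-1, markers)]")
  y <- as.numeric(table$group == "case")
  y <- y - mean(y)
  X <- sweep(X, 2, colMeans(X), "-")

  W <- matrix(0, p, A); Tm <- matrix(0, n, A); P <- matrix(0, p, A)
  q <- numeric(A); ssy <- numeric(A)
  ydef <- y
  a <- 0L
  for (k in seq_len(A)) {
    u <- ydef
    t_old <- rep(Inf, n)
    w <- NULL; tt <- NULL
    for (it in seq_len(max_iter)) {
      w <- drop(crossprod(X, u))
      nw <- sqrt(sum(w^2))
      if (nw < 1e-12) break
      w <- w / nw
      tt <- drop(X %*% w)
      if (sqrt(sum((tt - t_old)^2)) < tol * sqrt(sum(tt^2))) break
      t_old <- tt
      # single-column response: u stays the deflated response, so the
      # iteration converges on the second pass
      u <- ydef
    }
    if (is.null(tt) || sum(tt^2) < 1e-12 * n) {
      warning("rank deficient: returning ", a, " of ", A,
              " requested components")
      break
    }
    tsq <- sum(tt^2)
    pk <- drop(crossprod(X, tt)) / tsq
    cq <- sum(ydef * tt) / tsq
    W[, k] <- w; Tm[, k] <- tt; P[, k] <- pk; q[k] <- cq
    ssy[k] <- cq^2 * tsq
    X <- X - tcrossprod(tt, pk)
    ydef <- ydef - tt * cq
    a <- k
  }
  if (a == 0L) stop("no PLS component could be extracted (X has no variance)")
  keep <- seq_len(a)
  structure(list(weights = W[, keep, drop = FALSE],
                 scores = Tm[, keep, drop = FALSE],
                 x_loadings = P[, keep, drop = FALSE],
                 y_loadings = q[keep],
                 ss_y = ssy[keep],
                 n_components = a,
                 marker_names = table$markers),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat("<pls_model> ", length(x$marker_names), " markers, ",
      x$n_components, " components\n", sep = "")
  cat("  explained response SS per component:",
      signif(x$ss_y, 4), "\n")
  invisible(x)
}

#' Cumulative VIP scores through a component depth
#'
#' The standard variable-importance-in-projection quantity:
#' `VIP_j = sqrt(p * sum_{k<=a} ssy_k * W[j,k]^2 / sum_{k<=a} ssy_k)`.
#' Because weight columns are unit-norm, the mean of squared VIPs over markers
#' is exactly 1 at every depth.
#'
#' @param model a fitted [fit_plsda()] model.
#' @param a component depth, `1 <= a <= n_components`.
#' @return named nonnegative numeric vector, one VIP per marker.
#' @export
vip_scores <- function(model, a = model$n_components) {
  stopifnot(inherits(model, "pls_model"))
  if (length(a) != 1L || a < 1L || a > model$n_components)
    stop("`a` must be in [1, ", model$n_components, "]")
  k <- seq_len(a)
  p <- nrow(model$weights)
  num <- drop(model$weights[, k, drop = FALSE]^2 %*% model$ss_y[k])
  vip <- sqrt(p * num / sum(model$ss_y[k]))
  names(vip) <- model$marker_names
  vip
}

#' Global VIP per marker
#'
#' The maximum of the cumulative VIPs over depths `1..A`. With a dominant
#' first component, cumulative VIPs typically decrease with depth and the
#' global value equals the component-1 value.
#'
#' @param model a fitted [fit_plsda()] model.
#' @return named nonnegative numeric vector.
#' @export
global_vip <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  vips <- vapply(seq_len(model$n_components),
                 function(a) vip_scores(model, a),
                 numeric(nrow(model$weights)))
  out <- apply(matrix(vips, nrow = nrow(model$weights)), 1, max)
  names(out) <- model$marker_names
  out
}

#' Per-marker VIP report
#'
#' One row per marker: cumulative VIP through each component depth plus the
#' global VIP, sorted by global VIP descending (ties broken by marker name).
#'
#' @param model a fitted [fit_plsda()] model.
#' @return data.frame `marker, comp1, ..., compA, global`.
#' @export
vip_report <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  A <- model$n_components
  cols <- lapply(seq_len(A), function(a) unname(vip_scores(model, a)))
  names(cols) <- paste0("comp", seq_len(A))
  df <- data.frame(marker = model$marker_names, cols,
                   global = unname(global_vip(model)),
                   stringsAsFactors = FALSE)
  df[order(-df$global, df$marker), , drop = FALSE]
}

#' Shortlist markers by global VIP
#'
#' @param report a [vip_report()] data.frame (or anything with `marker` and
#'   `global` columns).
#' @param threshold retain markers with `global >= threshold` (default 2, the
#'   conventional "VIP >= 2" shortlist).
#' @return character vector of marker names, sorted by global VIP descending,
#'   ties broken lexicographically. May be empty.
#' @export
select_by_vip <- function(report, threshold = 2) {
  if (threshold < 0) stop("`threshold` must be >= 0")
  keep <- report[report$global >= threshold, , drop = FALSE]
  keep <- keep[order(-keep$global, keep$marker), , drop = FALSE]
  keep$marker
}
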