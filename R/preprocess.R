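#' Preprocessing configuration
#'
#' The pipeline applies, in fixed order: per-batch RMS normalization, log
#' transform, pareto scaling. Each step can be toggled; the order cannot.
#'
#' @param log_base one of 10, `exp(1)`, 2 (default 10). The base only rescales
#'   downstream scores uniformly.
#' @param log_offset nonnegative value added before the log (default 0, with a
#'   strict positivity check on the data).
#' @param apply_batch_norm,apply_log,apply_pareto step toggles (all default
#'   `TRUE`).
#' @return a `preprocess_config` object.
#' @export
preprocess_config <- function(log_base = 10, log_offset = 0,
                              apply_batch_norm = TRUE, apply_log = TRUE,
                              apply_pareto = TRUE) {
  if (!log_base %in% c(10, exp(1), 2))
    stop("`log_base` must be one of 10, e, 2")
  if (length(log_offset) != 1L || !is.finite(log_offset) || log_offset < 0)
    stop("`log_offset` must be a single nonnegative number")
  structure(list(log_base = log_base, log_offset = log_offset,
                 apply_batch_norm = isTRUE(apply_batch_norm),
                 apply_log = isTRUE(apply_log),
                 apply_pareto = isTRUE(apply_pareto)),
            class = "preprocess_config")
}

# Append a step name to a table's applied-step record (append-only).
record_step <- function(table, step) {
  attr(table, "steps") <- c(attr(table, "steps"), step)
  table
}

#' Per-batch RMS normalization
#'
#' Divides each marker within each batch by the root mean square of that
#' marker's values in that batch: `x[i,j] / sqrt(mean(x[b,j]^2))` for sample
#' `i` in batch `b`. Afterwards every marker has RMS exactly 1 within every
#' batch, so purely multiplicative per-batch scale effects cancel.
#'
#' @param table a [feature_table()].
#' @return the normalized table, with step record `"batch_norm"` appended.
#' @export
batch_normalize <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  x <- table$intensities
  for (b in levels(table$batch)) {
    rows <- table$batch == b
    rms <- sqrt(colMeans(x[rows, , drop = FALSE]^2))
    zero <- rms == 0
    if (any(zero))
      stop("degenerate scale: marker(s) entirely zero within batch ", b, ": ",
           paste(table$markers[zero], collapse = ", "))
    x[rows, ] <- sweep(x[rows, , drop = FALSE], 2, rms, "/")
  }
  table$intensities <- x
  record_step(table, "batch_norm")
}

#' Elementwise log transform
#'
#' @param table a [feature_table()].
#' @param config a [preprocess_config()] (supplies base and offset).
#' @return the transformed table, step record `"log"` appended.
#' @export
log_transform <- function(table, config = preprocess_config()) {
  stopifnot(inherits(table, "feature_table"))
  x <- table$intensities + config$log_offset
  if (any(x <= 0)) {
    bad <- which(x <= 0, arr.ind = TRUE)[1, ]
    stop("log of nonpositive value at sample ", table$sample_id[bad[1]],
         ", marker ", table$markers[bad[2]],
         " (value + offset = ", x[bad[1], bad[2]], ")")
  }
  table$intensities <- log(x, base = config$log_base)
  record_step(table, "log")
}

#' Pareto scaling
#'
#' Mean-centers each marker column, then divides by the square root of its
#' sample standard deviation (n-1 denominator) — a compromise between no
#' scaling and unit-variance scaling that tempers dominance of high-variance
#' markers while partially preserving data structure. Zero-variance columns
#' become all-zero and are flagged rather than dropped, so marker indices stay
#' stable.
#'
#' @param table a [feature_table()] with at least 2 samples.
#' @return a `processed_table` (still a `feature_table`) with attributes
#'   `centers`, `scales` (the sqrt-sd divisors), `zero_variance` (logical per
#'   marker), and step record `"pareto"` appended.
#' @export
pareto_scale <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (nrow(table$intensities) < 2L)
    stop("insufficient data: pareto scaling needs >= 2 samples")
  x <- table$intensities
  centers <- colMeans(x)
  sds <- apply(x, 2, stats::sd)
  zero <- sds == 0
  scales <- sqrt(sds)
  scales[zero] <- 1  # centered constant column is already all-zero
  x <- sweep(sweep(x, 2, centers, "-"), 2, scales, "/")
  table$intensities <- x
  attr(table, "centers") <- centers
  attr(table, "scales") <- scales
  attr(table, "zero_variance") <- zero
  table <- record_step(table, "pareto")
  class(table) <- unique(c("processed_table", class(table)))
  table
}

# Apply previously fitted pareto constants to new data (MCCV test folds).
apply_pareto <- function(table, centers, scales) {
  x <- sweep(sweep(table$intensities, 2, centers, "-"), 2, scales, "/")
  table$intensities <- x
  table <- record_step(table, "pareto")
  class(table) <- unique(c("processed_table", class(table)))
  table
}

#' Full preprocessing pipeline
#'
#' Applies the enabled steps in fixed order: batch normalization, log
#' transform, pareto scaling. The intensity matrix as it stood after batch
#' normalization (before the log) is kept as attribute
#' `normalized_intensities` so that direction calls can be made on a scale
#' where group means are interpretable.
#'
#' @param table a [feature_table()].
#' @param config a [preprocess_config()].
#' @return a `processed_table`; `attr(, "steps")` records the applied order.
#' @export
preprocess <- function(table, config = preprocess_config()) {
  stopifnot(inherits(table, "feature_table"))
  if (config$apply_batch_norm) {
    if (nlevels(table$batch) < 1L || anyNA(table$batch))
      stop("batch labels required for batch normalization")
    table <- batch_normalize(table)
  }
  attr(table, "normalized_intensities") <- table$intensities
  if (config$apply_log) table <- log_transform(table, config)
  if (config$apply_pareto) table <- pareto_scale(table)
  if (!inherits(table, "processed_table"))
    class(table) <- unique(c("processed_table", class(table)))
  table
}
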