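#' Configuration for the synthetic serum-metabolomics cohort generator
#'
#' Describes a two-class targeted-metabolomics cohort with a small set of
#' planted discriminative markers, multiplicative per-batch scale effects and
#' log-normal measurement noise. Defaults emulate a case-control serum study:
#' 15 cases, 21 controls, 232 targeted metabolites, ~10 informative markers of
#' which a majority are elevated in cases and a minority decreased.
#'
#' @param n_case number of case samples (default 15).
#' @param n_control number of control samples (default 21).
#' @param n_markers number of markers / metabolites (default 232).
#' @param n_informative number of planted discriminative markers (default 10).
#' @param n_batches number of analytical batches (default 2). Samples are
#'   assigned round-robin, so batch is not confounded with class.
#' @param effect_log2fc signed per-informative-marker log2 fold change
#'   (case vs control). Either a vector of length `n_informative` or `NULL`,
#'   in which case magnitudes are drawn uniformly from `effect_range` at
#'   generation time, with `n_up` of them positive and the rest negative.
#' @param effect_range interval for drawn effect magnitudes, in log2 units
#'   (default `c(1.5, 2.5)`).
#' @param n_up number of planted markers elevated in cases when effects are
#'   drawn (default `ceiling(0.7 * n_informative)`, i.e. 7 of 10).
#' @param baseline_log_mean per-marker mean of natural-log intensity; a single
#'   value, a vector of length `n_markers`, or `NULL` to draw uniformly from
#'   `baseline_range`.
#' @param baseline_range interval for drawn baseline log-means
#'   (default `log(c(1e4, 1e6))`, typical integrated peak areas).
#' @param noise_sd standard deviation of natural-log intensity noise
#'   (default 0.5).
#' @param batch_scale_range interval of multiplicative per-batch per-marker
#'   scale factors (default `c(0.5, 2)`); must be strictly positive.
#' @param seed integer seed; the generator is fully deterministic given the
#'   config.
#' @return a `synthetic_config` object (validated list).
#' @export
synthetic_config <- function(n_case = 15L, n_control = 21L, n_markers = 232L,
                             n_informative = 10L, n_batches = 2L,
                             effect_log2fc = NULL,
                             effect_range = c(1.5, 2.5),
                             n_up = NULL,
                             baseline_log_mean = NULL,
                             baseline_range = log(c(1e4, 1e6)),
                             noise_sd = 0.5,
                             batch_scale_range = c(0.5, 2),
                             seed = 1L) {
  chk_count <- function(x, name, min = 1L) {
    if (length(x) != 1L || is.na(x) || x < min || x != round(x))
      stop("invalid `", name, "`: must be a single integer >= ", min)
    as.integer(x)
  }
  n_case <- chk_count(n_case, "n_case")
  n_control <- chk_count(n_control, "n_control")
  n_markers <- chk_count(n_markers, "n_markers")
  n_informative <- chk_count(n_informative, "n_informative", min = 0L)
  n_batches <- chk_count(n_batches, "n_batches")
  if (n_informative > n_markers)
    stop("invalid `n_informative`: must be <= n_markers")
  if (length(noise_sd) != 1L || !is.finite(noise_sd) || noise_sd <= 0)
    stop("invalid `noise_sd`: must be a single positive number")
  if (length(batch_scale_range) != 2L || any(batch_scale_range <= 0) ||
      diff(batch_scale_range) < 0)
    stop("invalid `batch_scale_range`: must be a positive increasing interval")
  if (!is.null(effect_log2fc)) {
    if (length(effect_log2fc) != n_informative)
      stop("invalid `effect_log2fc`: length must equal n_informative")
    if (anyNA(effect_log2fc))
      stop("invalid `effect_log2fc`: contains NA")
  } else {
    if (length(effect_range) != 2L || diff(effect_range) < 0)
      stop("invalid `effect_range`: must be an increasing interval")
  }
  if (is.null(n_up)) n_up <- as.integer(ceiling(0.7 * n_informative))
  if (n_up > n_informative || n_up < 0)
    stop("invalid `n_up`: must be between 0 and n_informative")
  if (!is.null(baseline_log_mean) &&
      !(length(baseline_log_mean) %in% c(1L, n_markers)))
    stop("invalid `baseline_log_mean`: length must be 1 or n_markers")
  seed <- chk_count(seed, "seed", min = 0L)
  structure(
    list(n_case = n_case, n_control = n_control, n_markers = n_markers,
         n_informative = n_informative, n_batches = n_batches,
         effect_log2fc = effect_log2fc, effect_range = effect_range,
         n_up = as.integer(n_up),
         baseline_log_mean = baseline_log_mean,
         baseline_range = baseline_range,
         noise_sd = noise_sd, batch_scale_range = batch_scale_range,
         seed = seed),
    class = "synthetic_config")
}

# Deterministic draw of planted marker identities and signed effects.
# Shared by generate_cohort() and planted_markers() so both agree.
planted_spec <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  p <- config$n_markers; k <- config$n_informative
  marker_names <- paste0("M", formatC(seq_len(p), width = nchar(p), flag = "0"))
  out <- local_seed(config$seed, {
    idx <- sort(sample.int(p, k))
    if (!is.null(config$effect_log2fc)) {
      eff <- as.numeric(config$effect_log2fc)
    } else if (k > 0) {
      mag <- stats::runif(k, config$effect_range[1], config$effect_range[2])
      sgn <- rep(c(1, -1), c(config$n_up, k - config$n_up))
      eff <- mag * sgn
    } else {
      eff <- numeric(0)
    }
    list(idx = idx, effect = eff)
  })
  list(markers = marker_names[out$idx], index = out$idx,
       effect_log2fc = out$effect, all_markers = marker_names)
}

#' Generate a synthetic two-class cohort
#'
#' Intensities follow a log-normal model on the natural-log scale:
#' `log x = baseline + log(2) * effect_log2fc * [case & informative]
#'          + log(batch factor) + N(0, noise_sd)`.
#' Batch effects are purely multiplicative (per batch per marker), so
#' dividing each batch-marker block by its applied factor recovers the
#' batch-free table exactly; the factors are attached as attribute
#' `batch_factors` for that check. Deterministic given `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return a [feature_table()] with `n_case + n_control` rows and
#'   `n_markers` columns; attributes `planted` (data.frame of planted marker
#'   names and signed log2 effects) and `batch_factors`
#'   (n_batches x n_markers matrix).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_case + config$n_control
  p <- config$n_markers
  spec <- planted_spec(config)
  group <- rep(c("case", "control"), c(config$n_case, config$n_control))
  batch <- rep_len(paste0("B", seq_len(config$n_batches)), n)

  logx <- local_seed(config$seed + 1L, {
    baseline <- config$baseline_log_mean
    if (is.null(baseline))
      baseline <- stats::runif(p, config$baseline_range[1],
                               config$baseline_range[2])
    baseline <- rep_len(baseline, p)
    # scale raw uniforms by hand: runif(n, a, a) would skip the RNG stream,
    # breaking the exact batched / batch-free correspondence
    u <- stats::runif(config$n_batches * p)
    bf <- matrix(config$batch_scale_range[1] +
                   diff(config$batch_scale_range) * u,
                 nrow = config$n_batches, ncol = p,
                 dimnames = list(paste0("B", seq_len(config$n_batches)),
                                 spec$all_markers))
    noise <- matrix(stats::rnorm(n * p, sd = config$noise_sd), n, p)
    m <- matrix(baseline, n, p, byrow = TRUE) + noise
    if (length(spec$index))
      m[group == "case", spec$index] <-
        m[group == "case", spec$index] +
        matrix(log(2) * spec$effect_log2fc, sum(group == "case"),
               length(spec$index), byrow = TRUE)
    m <- m + log(bf)[batch, , drop = FALSE]
    list(m = m, bf = bf)
  })

  tab <- feature_table(exp(logx$m), group = group, batch = batch,
                       sample_id = paste0("S", formatC(seq_len(n),
                                                       width = nchar(n),
                                                       flag = "0")),
                       markers = spec$all_markers)
  attr(tab, "planted") <- data.frame(marker = spec$markers,
                                     effect_log2fc = spec$effect_log2fc,
                                     stringsAsFactors = FALSE)
  attr(tab, "batch_factors") <- logx$bf
  tab
}

#' Planted (informative) markers of a synthetic config
#'
#' @param config a [synthetic_config()].
#' @return data.frame with columns `marker` and `effect_log2fc` (signed),
#'   exactly `n_informative` rows, a subset of the generated table's markers.
#' @export
planted_markers <- function(config) {
  spec <- planted_spec(config)
  data.frame(marker = spec$markers, effect_log2fc = spec$effect_log2fc,
             stringsAsFactors = FALSE)
}

# Run code under a temporary RNG state so callers' streams are untouched.
local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}
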