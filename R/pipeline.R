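#' Assemble a full-run configuration
#'
#' Exactly one of `input` (path to a feature-table CSV) or `synthetic = TRUE`
#' must be active. A JSON config file can override any default; command-line
#' style overrides win over the file.
#'
#' @param input path to a feature-table CSV, or `NULL`.
#' @param synthetic generate a synthetic cohort instead of reading a file.
#' @param synthetic_cfg a [synthetic_config()] (used when `synthetic`).
#' @param preprocess_cfg a [preprocess_config()].
#' @param n_components PLS-DA components (default 3).
#' @param vip_threshold global-VIP shortlist threshold (default 2).
#' @param sbs_cfg an [sbs_config()].
#' @param mccv_cfg an [mccv_config()].
#' @param rank_freq_threshold marker-table threshold (default 0.5).
#' @param out output directory (created if absent).
#' @param seed global seed; fans out to the synthetic generator, SBS and MCCV
#'   by fixed offsets so adding a stage never perturbs another stage.
#' @param verbosity one of `"debug"`, `"info"`, `"warn"` (default `"info"`).
#' @return a `run_config` object.
#' @export
run_config <- function(input = NULL, synthetic = is.null(input),
                       synthetic_cfg = NULL, preprocess_cfg = NULL,
                       n_components = 3L, vip_threshold = 2,
                       sbs_cfg = NULL, mccv_cfg = NULL,
                       rank_freq_threshold = 0.5,
                       out = "metaboselect_out", seed = 1L,
                       verbosity = "info") {
  if (is.null(input) == !isTRUE(synthetic))
    stop("exactly one of `input` and `synthetic` must be active")
  seed <- as.integer(seed)
  if (is.null(synthetic_cfg)) synthetic_cfg <- synthetic_config(seed = seed)
  else synthetic_cfg$seed <- seed
  if (is.null(preprocess_cfg)) preprocess_cfg <- preprocess_config()
  if (is.null(sbs_cfg)) sbs_cfg <- sbs_config(seed = seed + 1000L)
  if (is.null(mccv_cfg))
    mccv_cfg <- mccv_config(seed = seed + 2000L, sbs = sbs_cfg,
                            preprocess = preprocess_cfg)
  structure(list(input = input, synthetic = isTRUE(synthetic),
                 synthetic_cfg = synthetic_cfg,
                 preprocess_cfg = preprocess_cfg,
                 n_components = as.integer(n_components),
                 vip_threshold = vip_threshold,
                 sbs_cfg = sbs_cfg, mccv_cfg = mccv_cfg,
                 rank_freq_threshold = rank_freq_threshold,
                 out = out, seed = seed, verbosity = verbosity),
            class = "run_config")
}

#' Read a run configuration from a JSON file
#'
#' Flat key-value JSON; recognized keys mirror the arguments of
#' [run_config()], with nested objects `synthetic`, `sbs`, `mccv` passing
#' fields to [synthetic_config()], [sbs_config()], [mccv_config()].
#'
#' @param path JSON file path.
#' @param ... overrides applied after the file (e.g. `seed`, `out`).
#' @return a `run_config`.
#' @export
read_run_config <- function(path, ...) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  over <- list(...)
  args <- list()
  for (k in c("input", "synthetic", "n_components", "vip_threshold",
              "rank_freq_threshold", "out", "seed", "verbosity"))
    if (!is.null(raw[[k]])) args[[k]] <- raw[[k]]
  if (!is.null(raw$synthetic_config))
    args$synthetic_cfg <- do.call(synthetic_config, as.list(raw$synthetic_config))
  if (!is.null(raw$preprocess))
    args$preprocess_cfg <- do.call(preprocess_config, as.list(raw$preprocess))
  if (!is.null(raw$sbs))
    args$sbs_cfg <- do.call(sbs_config, as.list(raw$sbs))
  if (!is.null(raw$mccv)) {
    m <- as.list(raw$mccv)
    if (!is.null(args$sbs_cfg)) m$sbs <- args$sbs_cfg
    if (!is.null(args$preprocess_cfg)) m$preprocess <- args$preprocess_cfg
    args$mccv_cfg <- do.call(mccv_config, m)
  }
  args[names(over)] <- over
  do.call(run_config, args)
}

msg <- function(config, level, ...) {
  levels <- c(debug = 1, info = 2, warn = 3)
  if (levels[[level]] >= levels[[config$verbosity]])
    message("[", level, "] ", ...)
}

write_num_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) df[[j]] <- sprintf("%.17g", df[[j]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full biomarker-discovery pipeline
#'
#' Simulation (or CSV input) -> preprocessing -> PLS-DA/VIP -> univariate ROC
#' -> sequential backward selection -> Monte Carlo cross-validation, writing
#' all stage reports into the output directory:
#' `processed_table.csv`, `vip_report.csv`, `univariate_report.csv`,
#' `sbs_trace.csv`, `mccv_marker_table.csv`, `composite_roc.csv`,
#' `auc_distribution.csv`, `manifest.txt` (plus `selected_markers.txt`).
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the in-memory results of every stage
#'   (`table`, `processed`, `pls`, `vip`, `univariate`, `sbs`, `mccv`,
#'   `marker_table`, `files`).
#' @export
run_full_analysis <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)

  tab <- if (config$synthetic) {
    msg(config, "info", "generating synthetic cohort (seed ",
        config$synthetic_cfg$seed, ")")
    generate_cohort(config$synthetic_cfg)
  } else {
    msg(config, "info", "reading feature table from ", config$input)
    read_feature_table(config$input)
  }

  processed <- preprocess(tab, config$preprocess_cfg)
  f_processed <- file.path(config$out, "processed_table.csv")
  write_feature_table(processed, f_processed)

  msg(config, "info", "fitting PLS-DA (", config$n_components, " components)")
  pls <- fit_plsda(processed, n_components = config$n_components)
  vips <- vip_report(pls)
  f_vip <- file.path(config$out, "vip_report.csv")
  write_num_csv(vips, f_vip)

  uni <- univariate_report(processed)
  f_uni <- file.path(config$out, "univariate_report.csv")
  write_num_csv(uni$table, f_uni)

  msg(config, "info", "sequential backward selection on the full table")
  trace <- sbs(processed, config$sbs_cfg)
  f_sbs <- file.path(config$out, "sbs_trace.csv")
  write_num_csv(trace$rounds, f_sbs)
  writeLines(trace$selected_markers,
             file.path(config$out, "selected_markers.txt"))

  msg(config, "info", "Monte Carlo cross-validation (",
      config$mccv_cfg$n_iterations, " iterations)")
  mres <- mccv_run(tab, config$mccv_cfg)
  mtab <- marker_table(mres, config$rank_freq_threshold)
  f_mccv <- file.path(config$out, "mccv_marker_table.csv")
  write_num_csv(mtab, f_mccv)
  f_roc <- file.path(config$out, "composite_roc.csv")
  write_num_csv(stats::setNames(mres$composite$points,
                                c("fpr", "mean_tpr", "sd_tpr")), f_roc)
  f_auc <- file.path(config$out, "auc_distribution.csv")
  write_num_csv(data.frame(test_auc = mres$test_auc), f_auc)

  f_manifest <- file.path(config$out, "manifest.txt")
  writeLines(c(
    paste0("package: metaboselect ",
           as.character(utils::packageVersion("metaboselect"))),
    paste0("r_version: ", R.version.string),
    paste0("seed: ", config$seed),
    paste0("input: ", if (config$synthetic) "synthetic" else config$input),
    paste0("n_samples: ", nrow(tab$intensities)),
    paste0("n_markers: ", ncol(tab$intensities)),
    paste0("n_components: ", config$n_components),
    paste0("vip_threshold: ", config$vip_threshold),
    paste0("rank_freq_threshold: ", config$rank_freq_threshold),
    paste0("mccv_iterations: ", config$mccv_cfg$n_iterations),
    paste0("mccv_train_fraction: ", config$mccv_cfg$train_fraction),
    paste0("sbs_n_trees: ", config$sbs_cfg$n_trees),
    paste0("sbs_elimination_fraction: ",
           config$sbs_cfg$elimination_fraction),
    paste0("mean_test_auc: ", sprintf("%.17g", mres$mean_auc))
  ), f_manifest)

  msg(config, "info", "done; outputs in ", config$out)
  invisible(list(table = tab, processed = processed, pls = pls, vip = vips,
                 univariate = uni, sbs = trace, mccv = mres,
                 marker_table = mtab,
                 files = c(processed = f_processed, vip = f_vip, uni = f_uni,
                           sbs = f_sbs, mccv = f_mccv, roc = f_roc,
                           auc = f_auc, manifest = f_manifest)))
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `preprocess`, `plsda`, `univariate`, `select`,
#' `mccv`, `all`. Each reads the previous stage's CSV (or generates data for
#' `simulate`) and writes its own outputs, so chaining the subcommands equals
#' `all`. Flags: `--config PATH`, `--seed INT`, `--out DIR`, `--input PATH`,
#' `--synthetic`, `--n-iterations INT`, `--vip-threshold X`,
#' `--rank-freq-threshold X`, `--log-level {debug,info,warn}`.
#'
#' @param args character vector of command-line arguments (default: the
#'   process's trailing arguments).
#' @return exit status, 0 on success (invisibly). The installed script
#'   `system.file("cli", "metaboselect.R", package = "metaboselect")` wraps
#'   this for `Rscript`.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (!length(args))
      stop("usage: metaboselect.R <simulate|preprocess|plsda|univariate|",
           "select|mccv|all> [--flags]")
    cmd <- args[1]
    flags <- parse_cli_flags(args[-1])
    cfg_args <- list()
    if (!is.null(flags$config)) {
      cfg <- read_run_config(flags$config)
    } else {
      cfg <- NULL
    }
    over <- list()
    if (!is.null(flags$seed)) over$seed <- as.integer(flags$seed)
    if (!is.null(flags$out)) over$out <- flags$out
    if (!is.null(flags$input)) over$input <- flags$input
    if (isTRUE(flags$synthetic)) over$synthetic <- TRUE
    if (!is.null(flags$`vip-threshold`))
      over$vip_threshold <- as.numeric(flags$`vip-threshold`)
    if (!is.null(flags$`rank-freq-threshold`))
      over$rank_freq_threshold <- as.numeric(flags$`rank-freq-threshold`)
    if (!is.null(flags$`log-level`)) over$verbosity <- flags$`log-level`
    cfg <- if (is.null(cfg)) do.call(run_config, over) else {
      cfg[names(over)] <- over
      # reassemble to revalidate and refan the seed
      do.call(run_config, cfg[setdiff(names(cfg), "synthetic")])
    }
    if (!is.null(flags$`n-iterations`))
      cfg$mccv_cfg$n_iterations <- as.integer(flags$`n-iterations`)

    dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
    intermediate <- file.path(cfg$out, "feature_table.csv")
    load_stage_table <- function() {
      path <- if (!is.null(cfg$input)) cfg$input else intermediate
      if (!file.exists(path))
        stop("no input table at ", path, "; run `simulate` first or pass --input")
      read_feature_table(path)
    }
    switch(cmd,
      simulate = {
        tab <- generate_cohort(cfg$synthetic_cfg)
        write_feature_table(tab, intermediate)
        message("wrote ", intermediate)
      },
      preprocess = {
        proc <- preprocess(load_stage_table(), cfg$preprocess_cfg)
        write_feature_table(proc, file.path(cfg$out, "processed_table.csv"))
        message("wrote ", file.path(cfg$out, "processed_table.csv"))
      },
      plsda = {
        proc <- preprocess(load_stage_table(), cfg$preprocess_cfg)
        write_num_csv(vip_report(fit_plsda(proc, cfg$n_components)),
                      file.path(cfg$out, "vip_report.csv"))
        message("wrote ", file.path(cfg$out, "vip_report.csv"))
      },
      univariate = {
        proc <- preprocess(load_stage_table(), cfg$preprocess_cfg)
        write_num_csv(univariate_report(proc)$table,
                      file.path(cfg$out, "univariate_report.csv"))
        message("wrote ", file.path(cfg$out, "univariate_report.csv"))
      },
      select = {
        proc <- preprocess(load_stage_table(), cfg$preprocess_cfg)
        trace <- sbs(proc, cfg$sbs_cfg)
        write_num_csv(trace$rounds, file.path(cfg$out, "sbs_trace.csv"))
        writeLines(trace$selected_markers,
                   file.path(cfg$out, "selected_markers.txt"))
        message("wrote ", file.path(cfg$out, "sbs_trace.csv"))
      },
      mccv = {
        tab <- load_stage_table()
        mres <- mccv_run(tab, cfg$mccv_cfg)
        write_num_csv(marker_table(mres, cfg$rank_freq_threshold),
                      file.path(cfg$out, "mccv_marker_table.csv"))
        write_num_csv(stats::setNames(mres$composite$points,
                                      c("fpr", "mean_tpr", "sd_tpr")),
                      file.path(cfg$out, "composite_roc.csv"))
        write_num_csv(data.frame(test_auc = mres$test_auc),
                      file.path(cfg$out, "auc_distribution.csv"))
        message("wrote ", file.path(cfg$out, "mccv_marker_table.csv"))
      },
      all = {
        if (cfg$synthetic) {
          tab <- generate_cohort(cfg$synthetic_cfg)
          write_feature_table(tab, intermediate)
        }
        run_full_analysis(cfg)
      },
      stop("unknown subcommand: ", cmd)
    )
    0L
  }, error = function(e) {
    message("[error] ", conditionMessage(e))
    1L
  })
  invisible(status)
}

# --flag value / --flag (bare flags become TRUE)
parse_cli_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- substring(a, 3)
    if (i < length(args) && !startsWith(args[i + 1L], "--")) {
      flags[[key]] <- args[i + 1L]
      i <- i + 2L
    } else {
      flags[[key]] <- TRUE
      i <- i + 1L
    }
  }
  flags
}
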