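#' Construct a two-class metabolomics feature table
#'
#' A `feature_table` is the package's central container: a samples x markers
#' matrix of nonnegative intensities (integrated peak areas, arbitrary units)
#' together with a per-sample group label (`case`/`control`), a per-sample
#' analytical batch label, and unique marker names.
#'
#' @param intensities numeric matrix, samples in rows, markers in columns.
#'   Must be nonnegative and free of missing values.
#' @param group character or factor of length `nrow(intensities)` with values
#'   `"case"`/`"control"` (aliases `"OC"` -> case, `"CNTRL"` -> control are
#'   accepted).
#' @param batch vector of batch identifiers, length `nrow(intensities)`.
#' @param sample_id optional sample identifiers; defaults to rownames or
#'   `S1..Sn`. Must be unique.
#' @param markers optional marker names; defaults to colnames or `M1..Mp`.
#'   Must be unique.
#' @return An object of class `feature_table`: a list with elements
#'   `intensities`, `group` (factor with levels control, case), `batch`
#'   (factor), `sample_id`, `markers`.
#' @export
feature_table <- function(intensities, group, batch,
                          sample_id = NULL, markers = NULL) {
  if (!is.matrix(intensities) || !is.numeric(intensities))
    stop("`intensities` must be a numeric matrix")
  n <- nrow(intensities); p <- ncol(intensities)
  if (anyNA(intensities))
    stop("`intensities` contains missing values")
  if (any(intensities < 0))
    stop("`intensities` must be nonnegative (peak areas)")
  group <- normalize_group_labels(group)
  if (length(group) != n)
    stop("`group` length (", length(group), ") != number of samples (", n, ")")
  if (length(batch) != n)
    stop("`batch` length (", length(batch), ") != number of samples (", n, ")")
  if (is.null(sample_id)) sample_id <- rownames(intensities)
  if (is.null(sample_id)) sample_id <- paste0("S", seq_len(n))
  if (anyDuplicated(sample_id))
    stop("duplicate sample ids: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  if (is.null(markers)) markers <- colnames(intensities)
  if (is.null(markers)) markers <- paste0("M", seq_len(p))
  if (anyDuplicated(markers))
    stop("duplicate marker names: ",
         paste(unique(markers[duplicated(markers)]), collapse = ", "))
  dimnames(intensities) <- list(sample_id, markers)
  structure(
    list(intensities = intensities,
         group = group,
         batch = factor(batch),
         sample_id = as.character(sample_id),
         markers = as.character(markers)),
    class = "feature_table")
}

# Map group aliases (OC -> case, CNTRL -> control) and validate the label set.
normalize_group_labels <- function(group) {
  g <- as.character(group)
  g[g %in% c("OC", "oc", "Case", "CASE")] <- "case"
  g[g %in% c("CNTRL", "cntrl", "Control", "CONTROL")] <- "control"
  bad <- setdiff(unique(g), c("case", "control"))
  if (length(bad))
    stop("invalid group labels (expected case/control, aliases OC/CNTRL): ",
         paste(bad, collapse = ", "))
  factor(g, levels = c("control", "case"))
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", nrow(x$intensities), " samples x ",
      ncol(x$intensities), " markers\n", sep = "")
  cat("  groups: ", sum(x$group == "case"), " case / ",
      sum(x$group == "control"), " control; batches: ",
      nlevels(x$batch), "\n", sep = "")
  steps <- attr(x, "steps")
  if (length(steps)) cat("  applied steps:", paste(steps, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensities)

# Both classes must be present for any between-group analysis.
assert_two_classes <- function(group) {
  if (nlevels(droplevels(factor(group))) < 2L ||
      !all(c("case", "control") %in% as.character(group)))
    stop("both classes (case and control) must be present")
  invisible(TRUE)
}

#' Read a feature table from CSV
#'
#' Expects the mandatory header `sample_id, group, batch, <marker_1>, ...`.
#' Group labels are validated against case/control with Table-style aliases
#' `OC` and `CNTRL` accepted. Values round-trip at full double precision when
#' written by [write_feature_table()].
#'
#' @param path path to a CSV file.
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "batch")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing mandatory column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  marker_cols <- setdiff(names(df), need)
  if (!length(marker_cols))
    stop("no marker columns found in ", path)
  mat <- as.matrix(df[, marker_cols, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- marker_cols[!vapply(df[marker_cols], is.numeric, logical(1))]
    stop("non-numeric intensity column(s) in ", path, ": ",
         paste(bad, collapse = ", "))
  }
  feature_table(mat, group = df$group, batch = df$batch,
                sample_id = df$sample_id, markers = marker_cols)
}

#' Write a feature table to CSV
#'
#' Columns `sample_id, group, batch` followed by one column per marker, full
#' decimal precision (lossless round trip with [read_feature_table()]).
#'
#' @param table a [feature_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- data.frame(sample_id = table$sample_id,
                   group = as.character(table$group),
                   batch = as.character(table$batch),
                   check.names = FALSE, stringsAsFactors = FALSE)
  mat <- table$intensities
  # %.17g is lossless for doubles and deterministic across runs
  for (j in seq_len(ncol(mat)))
    df[[table$markers[j]]] <- sprintf("%.17g", mat[, j])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
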