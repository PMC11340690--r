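# Genus aggregation, low-abundance filtering and total-sum scaling -- the
# standard preprocessing applied to each cohort independently before fitting.

#' Aggregate feature counts to the genus level
#'
#' Sums counts of all features (e.g. ASVs) that share a genus label; per-sample
#' totals are conserved exactly.
#'
#' @param table Samples x features count matrix.
#' @param taxa Lineage data.frame (see [read_taxa_table()]) with a `Genus`
#'   column; every feature of `table` must be present.
#' @param rank Lineage column to aggregate on (default `"Genus"`).
#' @return Samples x genera count matrix (genus labels as colnames).
#' @export
aggregate_to_genus <- function(table, taxa, rank = "Genus") {
  validate_count_table(table)
  missing <- setdiff(colnames(table), rownames(taxa))
  if (length(missing)) {
    stop("features absent from taxa table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!rank %in% colnames(taxa)) {
    stop("taxa table has no '", rank, "' column", call. = FALSE)
  }
  genus <- taxa[colnames(table), rank]
  if (any(is.na(genus) | genus == "")) {
    stop("features with empty ", rank, " label: ",
         paste(colnames(table)[is.na(genus) | genus == ""], collapse = ", "),
         call. = FALSE)
  }
  out <- t(rowsum(t(table), group = genus))
  validate_count_table(out)
  out
}

#' Remove features with pooled relative abundance below a threshold
#'
#' A feature is removed when its total reads across all samples, divided by
#' the grand total, fall strictly below `threshold` (the conventional 1e-5
#' low-abundance filter). Filtering is applied per dataset; cohorts are never
#' pooled.
#'
#' @param table Samples x features count matrix.
#' @param threshold Pooled relative-abundance cutoff (strict `<`);
#'   default `1e-5`.
#' @return `list(table = filtered matrix, report = filter_report)`; the
#'   report records counts before/after, the removed identifiers and the
#'   threshold.
#' @export
filter_low_abundance <- function(table, threshold = 1e-5) {
  validate_count_table(table)
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold >= 0)
  rel <- colSums(table) / sum(table)
  keep <- rel >= threshold
  if (!any(keep)) {
    stop("all ", ncol(table), " features fall below threshold ", threshold,
         call. = FALSE)
  }
  report <- structure(
    list(n_features_before = ncol(table),
         n_features_after = sum(keep),
         removed_ids = colnames(table)[!keep],
         threshold = threshold,
         rule = "pooled relative abundance < threshold (strict)"),
    class = "filter_report")
  list(table = table[, keep, drop = FALSE], report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Low-abundance filter (pooled relative abundance <", x$threshold, ")\n")
  cat("  features:", x$n_features_before, "->", x$n_features_after,
      sprintf("(%d removed)\n", length(x$removed_ids)))
  invisible(x)
}

# Serialize a filter report next to its table (one key-value row per field).
write_filter_report <- function(report, path) {
  df <- data.frame(
    key = c("n_features_before", "n_features_after", "n_removed",
            "threshold", "rule", "removed_ids"),
    value = c(report$n_features_before, report$n_features_after,
              length(report$removed_ids), format(report$threshold),
              report$rule, paste(report$removed_ids, collapse = ",")),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Total-sum scaling
#'
#' Rescales every sample (row) to a fixed total, 1e6 by default, so features
#' become comparable across uneven sequencing depths. Idempotent at a fixed
#' scale.
#'
#' @param table Samples x features matrix with positive row sums.
#' @param scale Target row total (default `1e6`; use 1 for relative
#'   abundances).
#' @return Matrix of the same shape; rows sum to `scale`.
#' @export
tss_normalize <- function(table, scale = 1e6) {
  validate_count_table(table, require_positive_rows = FALSE)
  stopifnot(is.numeric(scale), length(scale) == 1L, scale > 0)
  rs <- rowSums(table)
  if (any(rs <= 0)) {
    stop("zero-sum sample(s): ", paste(rownames(table)[rs <= 0], collapse = ", "),
         call. = FALSE)
  }
  table * (scale / rs)
}
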