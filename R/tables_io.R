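# File ingest/export: the pipeline's only contact with delimited files.
# Canonical in-memory form is a numeric matrix, samples in rows and features
# (genera, or topics downstream) in columns, with unique identifiers as
# dimnames -- the documents x terms orientation of topic modeling.

.infer_sep <- function(path, sep) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

# Read a delimited table into a character matrix, tolerating the flat BIOM
# TSV dialect ("# Constructed from biom file" banner, "#OTU ID" header).
.read_delim_raw <- function(path, sep) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) && grepl("^# ", lines[1L]) && length(lines) > 1L &&
      grepl("^#", lines[2L])) {
    lines <- lines[-1L]
  }
  if (length(lines)) lines[1L] <- sub("^#", "", lines[1L])
  utils::read.table(text = lines, header = TRUE, sep = sep, quote = "\"",
                    comment.char = "", check.names = FALSE,
                    stringsAsFactors = FALSE, colClasses = "character")
}

#' Read a count table from a delimited file
#'
#' Parses a TSV/CSV abundance table (one header row, one identifier column;
#' the flat BIOM TSV export dialect is also accepted) into the canonical
#' samples x features numeric matrix. The file may be laid out either way;
#' the orientation is always declared explicitly and never guessed.
#'
#' @param path Path to a delimited text file.
#' @param orientation `"samples-in-rows"` if file rows are samples,
#'   `"features-in-rows"` if file rows are features (genera). No default
#'   auto-detection is attempted.
#' @param sep Field delimiter; `NULL` (default) picks `","` for `.csv`,
#'   tab otherwise.
#' @return Numeric matrix, samples in rows, features in columns, with unique
#'   identifiers as dimnames. Negative, non-numeric or duplicate entries are
#'   rejected with the offending coordinates.
#' @seealso [write_count_table()], [read_metadata()], [align_tables()]
#' @export
read_count_table <- function(path,
                             orientation = c("samples-in-rows",
                                             "features-in-rows"),
                             sep = NULL) {
  orientation <- match.arg(orientation)
  sep <- .infer_sep(path, sep)
  raw <- .read_delim_raw(path, sep)
  if (ncol(raw) < 2L) stop("no data columns found in ", path, call. = FALSE)
  ids <- trimws(raw[[1L]])
  col_ids <- trimws(colnames(raw)[-1L])
  vals <- matrix(NA_real_, nrow(raw), ncol(raw) - 1L,
                 dimnames = list(ids, col_ids))
  for (j in seq_len(ncol(raw) - 1L)) {
    v <- suppressWarnings(as.numeric(raw[[j + 1L]]))
    bad <- which(is.na(v) & !is.na(raw[[j + 1L]]))
    if (length(bad)) {
      stop("non-numeric value '", raw[[j + 1L]][bad[1L]], "' at row '",
           ids[bad[1L]], "', column '", col_ids[j], "'", call. = FALSE)
    }
    vals[, j] <- v
  }
  if (orientation == "features-in-rows") vals <- t(vals)
  validate_count_table(vals)
  vals
}

#' Write a count table as TSV
#'
#' Inverse of [read_count_table()]: writes the canonical samples x features
#' matrix with an identifier column, so that read-after-write reproduces
#' integer tables bit-exactly.
#'
#' @param x Samples x features numeric matrix.
#' @param path Output path.
#' @param sep Field delimiter (tab by default).
#' @param id_column Name of the identifier column in the header.
#' @export
write_count_table <- function(x, path, sep = "\t", id_column = "sample_id") {
  validate_count_table(x, require_positive_rows = FALSE)
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample metadata
#'
#' @param path Delimited text file with one row per sample.
#' @param group_column Name of the column holding the binary group label
#'   (e.g. patient vs control).
#' @param sample_column Name or index of the sample-identifier column
#'   (default: first column).
#' @param sep Delimiter (see [read_count_table()]).
#' @return A data.frame with sample identifiers as rownames and a `group`
#'   factor whose levels keep their order of first appearance; all other
#'   columns are carried along as optional covariates. Samples absent from a
#'   count table are retained here; reconciliation happens in
#'   [align_tables()].
#' @export
read_metadata <- function(path, group_column, sample_column = 1L, sep = NULL) {
  sep <- .infer_sep(path, sep)
  raw <- .read_delim_raw(path, sep)
  if (is.numeric(sample_column)) sample_column <- colnames(raw)[sample_column]
  if (!group_column %in% colnames(raw)) {
    stop("group column '", group_column, "' not found; available columns: ",
         paste(colnames(raw), collapse = ", "), call. = FALSE)
  }
  ids <- trimws(raw[[sample_column]])
  if (anyDuplicated(ids)) {
    stop("duplicate sample identifiers in metadata: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  grp <- trimws(raw[[group_column]])
  if (any(is.na(grp) | grp == "")) {
    stop("samples with empty group label: ",
         paste(ids[is.na(grp) | grp == ""], collapse = ", "), call. = FALSE)
  }
  meta <- raw[, setdiff(colnames(raw), sample_column), drop = FALSE]
  meta$group <- factor(grp, levels = unique(grp))
  if (group_column != "group") meta[[group_column]] <- NULL
  rownames(meta) <- ids
  meta
}

#' Read a taxon lineage table
#'
#' @param path Delimited text with a feature-identifier column and lineage
#'   columns (`Kingdom` .. `Genus`).
#' @param feature_column Name or index of the feature-identifier column.
#' @param sep Delimiter.
#' @return data.frame with feature identifiers as rownames; lineage strings
#'   are whitespace-trimmed but otherwise opaque.
#' @export
read_taxa_table <- function(path, feature_column = 1L, sep = NULL) {
  sep <- .infer_sep(path, sep)
  raw <- .read_delim_raw(path, sep)
  if (is.numeric(feature_column)) feature_column <- colnames(raw)[feature_column]
  ids <- trimws(raw[[feature_column]])
  if (anyDuplicated(ids)) {
    stop("duplicate feature identifiers in taxa table", call. = FALSE)
  }
  taxa <- raw[, setdiff(colnames(raw), feature_column), drop = FALSE]
  taxa[] <- lapply(taxa, trimws)
  rownames(taxa) <- ids
  taxa
}

#' Restrict a count table and metadata to their shared samples
#'
#' Both inputs are subset to the intersection of sample identifiers, in the
#' count table's order; the number of dropped samples is reported via
#' `message()`.
#'
#' @param table Samples x features count matrix.
#' @param meta Metadata data.frame with sample rownames (see
#'   [read_metadata()]).
#' @return `list(table = , meta = )` with identical sample ordering.
#' @export
align_tables <- function(table, meta) {
  validate_count_table(table)
  shared <- intersect(rownames(table), rownames(meta))
  if (length(shared) == 0L) {
    stop("count table and metadata share no sample identifiers", call. = FALSE)
  }
  dropped <- (nrow(table) - length(shared)) + (nrow(meta) - length(shared))
  if (dropped > 0L) {
    message("align_tables: dropped ", nrow(table) - length(shared),
            " table sample(s) and ", nrow(meta) - length(shared),
            " metadata sample(s) outside the intersection")
  }
  list(table = table[shared, , drop = FALSE],
       meta = meta[shared, , drop = FALSE])
}
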