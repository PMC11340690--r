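# Conversion of fitted per-sample topic probabilities into a samples x topics
# abundance table: each sample's reads are apportioned to topics in proportion
# to its gamma row, so the topic table can re-enter the count-table code paths
# (differential abundance in particular).

# Round x to integers summing exactly to `total` (largest-remainder
# apportionment; ties broken by position).
largest_remainder_round <- function(x, total) {
  f <- floor(x)
  r <- as.integer(round(total) - sum(f))
  if (r > 0L) {
    idx <- order(-(x - f), seq_along(x))[seq_len(r)]
    f[idx] <- f[idx] + 1
  }
  f
}

#' Assign sample reads to topics
#'
#' Multiplies each sample's per-topic probabilities by its read depth, giving
#' a samples x topics abundance table whose rows sum to the sample depths
#' (exactly under `rounding = "nearest"`, to numerical precision otherwise).
#'
#' @param model Fitted [fit_lda()] model.
#' @param table The count table the depths come from; must contain every
#'   model sample (extra samples are ignored).
#' @param rounding `"none"` (default; fractional topic counts) or
#'   `"nearest"` (largest-remainder rounding so each row still sums to the
#'   integer depth).
#' @param prefix Optional dataset label prepended to topic identifiers
#'   (e.g. `"chen"` gives `"chen:Topic 1"`) so cross-dataset reports stay
#'   unambiguous.
#' @return Samples x topics numeric matrix with attributes `depths` and
#'   `rounding`.
#' @export
assign_reads_to_topics <- function(model, table,
                                   rounding = c("none", "nearest"),
                                   prefix = NULL) {
  stopifnot(inherits(model, "lda_vem"))
  rounding <- match.arg(rounding)
  validate_count_table(table)
  missing <- setdiff(model$doc_ids, rownames(table))
  if (length(missing)) {
    stop("model samples absent from table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  depths <- rowSums(table)[model$doc_ids]
  vals <- model$gamma * depths
  if (rounding == "nearest") {
    vals <- t(vapply(seq_along(depths), function(d) {
      largest_remainder_round(vals[d, ], depths[d])
    }, numeric(model$k)))
  }
  topic_ids <- rownames(model$beta)
  if (!is.null(prefix)) topic_ids <- paste0(prefix, ":", topic_ids)
  dimnames(vals) <- list(model$doc_ids, topic_ids)
  attr(vals, "depths") <- depths
  attr(vals, "rounding") <- rounding
  vals
}
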