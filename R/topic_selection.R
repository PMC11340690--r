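# Topic-number selection by grid search over K, scoring each fitted model
# with two criteria that are minimized at well-separated, well-supported
# topic sets: the mean pairwise cosine among topic-term rows (topic density)
# and the symmetric KL divergence between the normalized singular-value
# spectrum of beta and the document-length-weighted topic mass.

.as_beta <- function(model) {
  if (inherits(model, "lda_vem")) model$beta
  else if (is.matrix(model)) model
  else stop("expected an lda_vem model or a topics x terms matrix",
            call. = FALSE)
}

#' Topic-density selection criterion (mean pairwise topic cosine)
#'
#' Mean cosine similarity over all `K(K-1)/2` unordered pairs of topic-term
#' rows. Redundant topics drive the value toward 1; distinct topics toward 0.
#' Lower is better when scanning candidate topic numbers.
#'
#' @param model Fitted [fit_lda()] model, or a topics x terms probability
#'   matrix with at least 2 rows.
#' @return A number in `[0, 1]` for nonnegative rows.
#' @export
cao_juan_metric <- function(model) {
  beta <- .as_beta(model)
  k <- nrow(beta)
  if (k < 2L) stop("at least 2 topics required", call. = FALSE)
  rn <- beta / sqrt(rowSums(beta^2))
  C <- tcrossprod(rn)
  mean(C[upper.tri(C)])
}

# Symmetric KL with entries floored at 1e-12 inside the logs only.
.sym_kl <- function(p, q) {
  lp <- log(pmax(p, 1e-12)); lq <- log(pmax(q, 1e-12))
  sum(p * (lp - lq)) + sum(q * (lq - lp))
}

#' Spectral-divergence selection criterion
#'
#' Compares two length-`K` distributions: the singular values of the
#' topic-term matrix and the document-length-weighted column sums of the
#' document-topic matrix, each sorted descending and normalized to sum 1.
#' Returns their symmetric KL divergence; lower is better.
#'
#' @param model Fitted [fit_lda()] model.
#' @param doc_lengths Per-document total read counts (positive, length D);
#'   defaults to `NULL`, which requires an explicit vector.
#' @return Nonnegative number; 0 iff the two normalized spectra coincide.
#' @export
arun_metric <- function(model, doc_lengths) {
  stopifnot(inherits(model, "lda_vem") || is.list(model))
  beta <- model$beta; gamma <- model$gamma
  if (nrow(beta) < 2L) stop("at least 2 topics required", call. = FALSE)
  stopifnot(length(doc_lengths) == nrow(gamma), all(doc_lengths > 0))
  c1 <- sort(svd(beta, nu = 0L, nv = 0L)$d, decreasing = TRUE)
  c2 <- sort(as.numeric(crossprod(gamma, doc_lengths)), decreasing = TRUE)
  c1 <- c1 / sum(c1)
  c2 <- c2 / sum(c2)
  .sym_kl(c1, c2)
}

#' Grid search over the number of topics
#'
#' Fits one model per candidate `k` (one seeded fit, no restarts, mirroring
#' tuning-time practice) and evaluates both selection criteria; failures for
#' individual `k` are recorded and excluded from the argmin.
#'
#' @param table Samples x features count matrix.
#' @param grid Integer vector of candidate topic numbers.
#' @param settings [vem_settings()] used for every fit (restarts forced to 1).
#' @return Object of class `lda_tuning`: data.frame `metrics` with columns
#'   `k`, `cao_juan`, `arun`, list `best_k` (per-metric argmin), `settings`.
#' @export
tune_topic_number <- function(table, grid, settings = vem_settings()) {
  validate_count_table(table)
  grid <- sort(unique(as.integer(grid)))
  stopifnot(length(grid) >= 1L)
  settings$n_restarts <- 1L
  depths <- rowSums(table)
  cao <- arun <- rep(NA_real_, length(grid))
  errors <- character(length(grid))
  for (i in seq_along(grid)) {
    res <- tryCatch({
      fit <- fit_lda(table, grid[i], settings = settings)
      c(cao_juan_metric(fit), arun_metric(fit, depths))
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) errors[i] <- res else {
      cao[i] <- res[1L]; arun[i] <- res[2L]
    }
  }
  if (all(is.na(cao))) stop("every tuning fit failed", call. = FALSE)
  best <- list(cao_juan = grid[which.min(cao)], arun = grid[which.min(arun)])
  structure(list(metrics = data.frame(k = grid, cao_juan = cao, arun = arun),
                 best_k = best, errors = errors, settings = settings),
            class = "lda_tuning")
}

#' @export
print.lda_tuning <- function(x, ...) {
  cat("Topic-number grid search over k =",
      paste(range(x$metrics$k), collapse = ".."), "\n")
  print(x$metrics, row.names = FALSE)
  cat("argmin: topic-density", x$best_k$cao_juan,
      " spectral-divergence", x$best_k$arun, "\n")
  invisible(x)
}

#' @export
plot.lda_tuning <- function(x, ...) {
  m <- x$metrics
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(m$k, m$cao_juan, type = "b", xlab = "topics",
                 ylab = "mean pairwise topic cosine", main = "Topic density")
  graphics::plot(m$k, m$arun, type = "b", xlab = "topics",
                 ylab = "symmetric KL", main = "Spectral divergence")
  invisible(x)
}

#' Combine per-dataset topic-number optima
#'
#' Averages all per-metric best `k` values across datasets and rounds half
#' up; the result becomes the pipeline's common topic number.
#'
#' @param results A single `lda_tuning`, a list of them, or a numeric vector
#'   of best-`k` values.
#' @return Integer topic number.
#' @export
combine_dataset_optima <- function(results) {
  if (inherits(results, "lda_tuning")) results <- list(results)
  if (is.numeric(results)) ks <- results
  else {
    stopifnot(length(results) >= 1L)
    ks <- unlist(lapply(results, function(r) {
      stopifnot(inherits(r, "lda_tuning"))
      unlist(r$best_k)
    }))
  }
  if (length(ks) == 0L) stop("no tuning optima supplied", call. = FALSE)
  as.integer(floor(mean(ks) + 0.5))
}
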