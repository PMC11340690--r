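# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# n draws from Dirichlet(alpha); rows on the simplex.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = alpha, rate = 1), nrow = n,
              ncol = k, byrow = TRUE)
  # guard against all-zero rows when alpha is very small
  zero <- rowSums(x) == 0
  if (any(zero)) x[zero, sample.int(k, sum(zero), replace = TRUE)] <- 1
  x / rowSums(x)
}

# Validate a samples x features count matrix (the canonical orientation used
# throughout the package). Fractional values are allowed when `integer = FALSE`
# so topic-abundance tables can re-enter the same code paths.
validate_count_table <- function(x, require_positive_rows = TRUE,
                                 what = "count table") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(what, " must be a numeric matrix (samples in rows, features in columns)",
         call. = FALSE)
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop(what, " must carry sample rownames and feature colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) {
    stop("duplicate sample identifiers: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(x))) {
    stop("duplicate feature identifiers: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(x)) stop(what, " contains missing values", call. = FALSE)
  if (any(x < 0)) {
    bad <- which(x < 0, arr.ind = TRUE)[1L, ]
    stop("negative value at sample '", rownames(x)[bad[1L]], "', feature '",
         colnames(x)[bad[2L]], "'", call. = FALSE)
  }
  if (require_positive_rows && any(rowSums(x) <= 0)) {
    empty <- rownames(x)[rowSums(x) <= 0]
    stop("samples with zero total counts: ", paste(empty, collapse = ", "),
         call. = FALSE)
  }
  invisible(x)
}

# Exhaustive best-permutation topic matching for small K (used by recovery
# diagnostics); greedy fallback for larger K.
match_topic_rows <- function(sim) {
  k <- nrow(sim)
  stopifnot(ncol(sim) == k)
  if (k <= 7L) {
    perms <- permutations_of(k)
    scores <- vapply(perms, function(p) sum(sim[cbind(seq_len(k), p)]), 0)
    best <- perms[[which.max(scores)]]
  } else {
    best <- integer(k)
    taken <- logical(k)
    ord <- order(apply(sim, 1L, max), decreasing = TRUE)
    for (i in ord) {
      j <- order(sim[i, ], decreasing = TRUE)
      j <- j[!taken[j]][1L]
      best[i] <- j
      taken[j] <- TRUE
    }
  }
  best
}

permutations_of <- function(k) {
  if (k == 1L) return(list(1L))
  sub <- permutations_of(k - 1L)
  out <- vector("list", k * length(sub))
  idx <- 1L
  for (p in sub) {
    for (pos in seq_len(k)) {
      out[[idx]] <- append(p, k, after = pos - 1L)
      idx <- idx + 1L
    }
  }
  out
}
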