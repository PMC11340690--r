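# Shared fixtures and independent oracles, all built in code.

# Random integer count table (overdispersed multinomial rows).
rand_count_table <- function(n_samples, n_features, depth = 1000, seed = 1) {
  mbtopics:::with_seed(seed, {
    base <- as.numeric(mbtopics:::rdirichlet(1, rep(0.5, n_features)))
    P <- mbtopics:::rdirichlet(n_samples, 50 * base)
    counts <- t(vapply(seq_len(n_samples), function(i) {
      as.numeric(stats::rmultinom(1, depth, P[i, ]))
    }, numeric(n_features)))
    dimnames(counts) <- list(sprintf("s%03d", seq_len(n_samples)),
                             sprintf("f%03d", seq_len(n_features)))
    counts
  })
}

# Build an lda_vem object directly from beta/gamma (for testing downstream
# operations independently of the fitting path).
make_lda_model <- function(beta, gamma, alpha = 1, eta = 0.1) {
  k <- nrow(beta)
  stopifnot(ncol(gamma) == k)
  if (is.null(colnames(beta))) colnames(beta) <- sprintf("f%03d", seq_len(ncol(beta)))
  if (is.null(rownames(gamma))) rownames(gamma) <- sprintf("s%03d", seq_len(nrow(gamma)))
  rownames(beta) <- colnames(gamma) <- paste("Topic", seq_len(k))
  structure(list(k = k, beta = beta, gamma = gamma, alpha = alpha, eta = eta,
                 elbo_trace = 0, vocab = colnames(beta),
                 doc_ids = rownames(gamma), settings = vem_settings(),
                 seed = 1L, n_iter = 1L),
            class = "lda_vem")
}

# Exhaustive-enumeration oracle for the two-sided Wilcoxon rank-sum test
# (distinct values, no ties): enumerates every assignment of the pooled
# values to group A and computes the exact two-sided p the way the exact
# test defines it (doubled one-sided tail, capped at 1).
wilcoxon_enum_oracle <- function(x, y) {
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combs <- utils::combn(m + n, m)
  ws <- apply(combs, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  p_le <- mean(ws <= w_obs)
  p_ge <- mean(ws >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Brute-force step-up BH from the definition: q_(i) = min_{j>=i} p_(j)*m/j.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Mean cosine between Hungarian/permutation-matched rows of two topic-term
# matrices (recovery diagnostic used by several tests).
matched_mean_cosine <- function(beta_hat, beta_true) {
  S <- tcrossprod(beta_hat / sqrt(rowSums(beta_hat^2)),
                  beta_true / sqrt(rowSums(beta_true^2)))
  perm <- mbtopics:::match_topic_rows(S)
  mean(S[cbind(seq_len(nrow(S)), perm)])
}
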