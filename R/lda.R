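# Latent Dirichlet allocation fitted by variational expectation-maximization
# on the count-collapsed likelihood (documents = samples, terms = genera).
#
# E-step, per document d with counts n_dv:
#   phi_dvk  propto  beta_kv * exp(digamma(gamma_dk) - digamma(sum_k gamma_dk))
#   gamma_dk = alpha_k + sum_v n_dv phi_dvk
# iterated to convergence; fully vectorized over documents by noting that with
# E_dk = exp(E[log theta_dk]) and S = E %*% beta,
#   gamma_new = alpha + E * ((N / S) %*% t(beta)).
# M-step: beta_kv propto eta + sum_d n_dv phi_dvk = eta + beta_kv * (t(E) %*% (N/S))_kv,
# rows renormalized; optionally a symmetric alpha is re-estimated by Newton's
# method on the Dirichlet part of the bound.
#
# The reported ELBO is the variational objective including the topic-term
# smoothing term eta * sum(log beta), whose exact maximizer is the M-step
# update above; each EM iteration is therefore guaranteed non-decreasing.

#' Variational EM settings for [fit_lda()]
#'
#' @param max_em_iters Maximum EM iterations (default 100).
#' @param em_tol Relative ELBO change declaring EM convergence (default 1e-4).
#' @param max_estep_iters Cap on inner E-step iterations per EM step
#'   (default 50).
#' @param estep_tol Mean absolute per-document change in the variational
#'   Dirichlet parameters declaring E-step convergence (default 1e-6).
#' @param estimate_alpha Re-estimate the symmetric document-topic prior during
#'   fitting (default TRUE).
#' @param n_restarts Number of random restarts; the fit with the best final
#'   ELBO is kept (default 1, matching a single seeded fit per dataset).
#' @param seed Integer seed; restart r uses `seed + r - 1`.
#' @return Object of class `vem_settings`.
#' @export
vem_settings <- function(max_em_iters = 100L, em_tol = 1e-4,
                         max_estep_iters = 50L, estep_tol = 1e-6,
                         estimate_alpha = TRUE, n_restarts = 1L, seed = 1L) {
  stopifnot(max_em_iters >= 1L, max_estep_iters >= 1L,
            em_tol > 0, estep_tol > 0, n_restarts >= 1L)
  structure(list(max_em_iters = as.integer(max_em_iters), em_tol = em_tol,
                 max_estep_iters = as.integer(max_estep_iters),
                 estep_tol = estep_tol,
                 estimate_alpha = isTRUE(estimate_alpha),
                 n_restarts = as.integer(n_restarts),
                 seed = as.integer(seed)),
            class = "vem_settings")
}

# One block of fixed-point E-step iterations for all documents at once.
# Returns converged Gamma plus the E and S matrices evaluated at it.
.lda_estep <- function(N, beta, alpha_vec, Gamma, max_iters, tol) {
  A <- matrix(alpha_vec, nrow(N), length(alpha_vec), byrow = TRUE)
  for (i in seq_len(max_iters)) {
    E <- exp(digamma(Gamma) - digamma(rowSums(Gamma)))
    S <- E %*% beta
    S[S < 1e-300] <- 1e-300
    Gamma_new <- A + E * ((N / S) %*% t(beta))
    delta <- max(rowMeans(abs(Gamma_new - Gamma)))
    Gamma <- Gamma_new
    if (delta < tol) break
  }
  E <- exp(digamma(Gamma) - digamma(rowSums(Gamma)))
  S <- E %*% beta
  S[S < 1e-300] <- 1e-300
  list(Gamma = Gamma, E = E, S = S)
}

# Variational objective; `nz` indexes the nonzero counts of N (precomputed).
.lda_elbo <- function(N, nz, Gamma, beta, alpha_vec, eta, E, S) {
  D <- nrow(N)
  dg <- digamma(Gamma) - digamma(rowSums(Gamma))
  A <- matrix(alpha_vec, D, length(alpha_vec), byrow = TRUE)
  words <- sum(N[nz] * log(S[nz]))
  theta <- D * (lgamma(sum(alpha_vec)) - sum(lgamma(alpha_vec))) +
    sum((A - Gamma) * dg) + sum(lgamma(Gamma)) - sum(lgamma(rowSums(Gamma)))
  words + theta + eta * sum(log(beta))
}

# Newton update (in log space, with backtracking) of the symmetric
# document-topic prior, maximizing
#   f(a) = D * (lgamma(K a) - K lgamma(a)) + (a - 1) * T,
# where T = sum of E[log theta]. Returns the old value unless f improves.
.update_alpha <- function(alpha, Gamma, max_iters = 20L, tol = 1e-6) {
  D <- nrow(Gamma); K <- ncol(Gamma)
  T_ <- sum(digamma(Gamma) - digamma(rowSums(Gamma)))
  f <- function(a) D * (lgamma(K * a) - K * lgamma(a)) + (a - 1) * T_
  a <- alpha
  for (i in seq_len(max_iters)) {
    g <- D * K * (digamma(K * a) - digamma(a)) + T_
    h <- D * K * (K * trigamma(K * a) - trigamma(a))
    step <- (g * a) / (h * a * a + g * a)
    if (!is.finite(step)) break
    la_new <- log(a) - step
    a_new <- exp(la_new)
    halvings <- 0L
    while ((!is.finite(a_new) || a_new < 1e-4 || a_new > 1e4 ||
            f(a_new) < f(a)) && halvings < 12L) {
      step <- step / 2
      a_new <- exp(log(a) - step)
      halvings <- halvings + 1L
    }
    if (!is.finite(a_new) || f(a_new) < f(a)) break
    converged <- abs(log(a_new) - log(a)) < tol
    a <- a_new
    if (converged) break
  }
  a
}

.fit_lda_once <- function(N, k, alpha, eta, settings, seed) {
  D <- nrow(N); V <- ncol(N)
  depths <- rowSums(N)
  nz <- N > 0
  # init: corpus term frequencies, multiplicatively perturbed per topic
  beta <- with_seed(seed, {
    tf <- colSums(N) / sum(N) + 1e-8
    b <- matrix(tf, k, V, byrow = TRUE) *
      matrix(stats::rgamma(k * V, shape = 1, rate = 1), k, V)
    b / rowSums(b)
  })
  alpha_scalar <- length(alpha) == 1L
  alpha_vec <- rep(alpha, length.out = k)
  Gamma <- matrix(alpha_vec, D, k, byrow = TRUE) + depths / k
  elbo_trace <- numeric(0)
  prev <- -Inf
  for (iter in seq_len(settings$max_em_iters)) {
    es <- .lda_estep(N, beta, alpha_vec, Gamma, settings$max_estep_iters,
                     settings$estep_tol)
    Gamma <- es$Gamma
    # M-step: expected topic-term counts, Dirichlet-smoothed
    C <- beta * crossprod(es$E, N / es$S)
    beta <- C + eta
    beta <- beta / rowSums(beta)
    if (settings$estimate_alpha && alpha_scalar) {
      alpha_vec <- rep(.update_alpha(alpha_vec[1L], Gamma), k)
    }
    S_new <- es$E %*% beta
    S_new[S_new < 1e-300] <- 1e-300
    elbo <- .lda_elbo(N, nz, Gamma, beta, alpha_vec, eta, es$E, S_new)
    if (!is.finite(elbo)) {
      stop("non-finite ELBO at EM iteration ", iter, call. = FALSE)
    }
    elbo_trace <- c(elbo_trace, elbo)
    if (iter > 1L && abs(elbo - prev) < settings$em_tol * abs(prev)) break
    prev <- elbo
  }
  # re-run the E-step once so the reported gamma is the fixed point of the
  # final beta (rather than of the previous iteration's)
  Gamma <- .lda_estep(N, beta, alpha_vec, Gamma, settings$max_estep_iters,
                      settings$estep_tol)$Gamma
  gamma <- Gamma / rowSums(Gamma)
  list(beta = beta, gamma = gamma, alpha = if (alpha_scalar) alpha_vec[1L]
       else alpha_vec, elbo_trace = elbo_trace, seed = seed,
       n_iter = length(elbo_trace))
}

#' Fit latent Dirichlet allocation by variational EM
#'
#' Infers `k` latent topics (microbial community types) from a samples x
#' features count table. Samples play the role of documents and features
#' (genera) the role of terms; each topic is a probability distribution over
#' genera (`beta`, rows on the simplex) and each sample a probability
#' distribution over topics (`gamma`).
#'
#' @param x Samples x features count matrix with positive row sums.
#'   Fractional counts are accepted; integer counts are the documented
#'   ingest path.
#' @param k Number of topics; must satisfy `2 <= k < min(nrow(x), ncol(x))`.
#' @param settings A [vem_settings()] object.
#' @param alpha Initial symmetric document-topic Dirichlet prior; default
#'   `50 / k`. A length-`k` vector may be supplied, in which case it is held
#'   fixed (re-estimation applies to the symmetric scalar prior only).
#' @param eta Symmetric topic-term smoothing prior (fixed; default 0.1).
#' @return Object of class `lda_vem` with components `beta` (`k` x V,
#'   probability scale), `gamma` (D x `k`, rows on the simplex), `alpha`,
#'   `eta`, `elbo_trace` (non-decreasing), `vocab`, `doc_ids`, `settings`,
#'   `seed` and `n_iter`. Supports `print`, `summary`, `coef`, `logLik`,
#'   `predict`, `plot` and `simulate`.
#' @examples
#' sim <- generate_dataset(synthetic_spec(n_samples = 30, n_features = 40,
#'                                        n_topics = 3, depth_mean = 2000,
#'                                        seed = 7))
#' fit <- fit_lda(sim$table, k = 3, settings = vem_settings(seed = 7))
#' fit
#' @export
fit_lda <- function(x, k, settings = vem_settings(), alpha = NULL, eta = 0.1) {
  validate_count_table(x)
  stopifnot(inherits(settings, "vem_settings"), is.numeric(eta), eta > 0)
  k <- as.integer(k)
  if (k < 2L || k >= min(nrow(x), ncol(x))) {
    stop("k must satisfy 2 <= k < min(n_samples, n_features) = ",
         min(nrow(x), ncol(x)), call. = FALSE)
  }
  if (is.null(alpha)) alpha <- 50 / k
  stopifnot(all(alpha > 0), length(alpha) %in% c(1L, k))
  best <- NULL
  for (r in seq_len(settings$n_restarts)) {
    fit <- .fit_lda_once(x, k, alpha, eta, settings,
                         seed = settings$seed + r - 1L)
    if (is.null(best) ||
        fit$elbo_trace[fit$n_iter] > best$elbo_trace[best$n_iter]) {
      best <- fit
    }
  }
  topic_ids <- paste("Topic", seq_len(k))
  dimnames(best$beta) <- list(topic_ids, colnames(x))
  dimnames(best$gamma) <- list(rownames(x), topic_ids)
  structure(list(k = k, beta = best$beta, gamma = best$gamma,
                 alpha = best$alpha, eta = eta,
                 elbo_trace = best$elbo_trace,
                 vocab = colnames(x), doc_ids = rownames(x),
                 settings = settings, seed = best$seed,
                 n_iter = best$n_iter),
            class = "lda_vem")
}

#' Per-document topic probabilities of a fitted model
#'
#' Accessor for the gamma matrix: each row is the fitted topic-membership
#' distribution of one sample (normalized variational Dirichlet parameters,
#' rows summing to 1).
#'
#' @param model A fitted [fit_lda()] model.
#' @return D x k probability matrix.
#' @export
per_document_topic_probabilities <- function(model) {
  stopifnot(inherits(model, "lda_vem"))
  model$gamma
}

#' @export
print.lda_vem <- function(x, ...) {
  cat("Latent Dirichlet allocation (variational EM)\n")
  cat(sprintf("  topics: %d   samples: %d   features: %d\n",
              x$k, length(x$doc_ids), length(x$vocab)))
  cat(sprintf("  alpha: %s   eta: %g   seed: %d\n",
              paste(signif(x$alpha, 4), collapse = " "), x$eta, x$seed))
  cat(sprintf("  ELBO: %.4f after %d EM iterations\n",
              x$elbo_trace[x$n_iter], x$n_iter))
  invisible(x)
}

#' @export
summary.lda_vem <- function(object, n_terms = 8L, ...) {
  top <- apply(object$beta, 1L, function(b) {
    o <- order(b, decreasing = TRUE)[seq_len(n_terms)]
    paste0(object$vocab[o], " (", signif(b[o], 2), ")", collapse = ", ")
  })
  structure(list(model = object, top_terms = top, n_terms = n_terms),
            class = "summary.lda_vem")
}

#' @export
print.summary.lda_vem <- function(x, ...) {
  print(x$model)
  cat("Top", x$n_terms, "terms per topic:\n")
  for (i in seq_along(x$top_terms)) {
    cat(" ", names(x$top_terms)[i], ": ", x$top_terms[i], "\n", sep = "")
  }
  invisible(x)
}

#' @export
coef.lda_vem <- function(object, ...) object$beta

#' @export
logLik.lda_vem <- function(object, ...) {
  structure(object$elbo_trace[object$n_iter],
            df = object$k * (length(object$vocab) - 1L), class = "logLik")
}

#' Infer topic proportions for new samples under a fitted model
#'
#' Runs the variational E-step with the fitted topic-term matrix held fixed.
#' Features absent from the model vocabulary are dropped (their reads cannot
#' be attributed to any topic); model terms absent from `newdata` contribute
#' zero counts.
#'
#' @param object Fitted [fit_lda()] model.
#' @param newdata Samples x features count matrix.
#' @param ... Unused.
#' @return Matrix of topic proportions, one row per new sample.
#' @export
predict.lda_vem <- function(object, newdata, ...) {
  validate_count_table(newdata)
  N <- matrix(0, nrow(newdata), length(object$vocab),
              dimnames = list(rownames(newdata), object$vocab))
  shared <- intersect(colnames(newdata), object$vocab)
  if (length(shared) == 0L) {
    stop("newdata shares no features with the model vocabulary", call. = FALSE)
  }
  N[, shared] <- newdata[, shared]
  if (any(rowSums(N) <= 0)) {
    stop("samples with no reads on the model vocabulary: ",
         paste(rownames(N)[rowSums(N) <= 0], collapse = ", "), call. = FALSE)
  }
  alpha_vec <- rep(object$alpha, length.out = object$k)
  Gamma <- matrix(alpha_vec, nrow(N), object$k, byrow = TRUE) +
    rowSums(N) / object$k
  # iterate the fixed-point map well past the default cap: prediction is cheap
  es <- .lda_estep(N, object$beta, alpha_vec, Gamma,
                   max_iters = 20L * object$settings$max_estep_iters,
                   tol = object$settings$estep_tol)
  g <- es$Gamma / rowSums(es$Gamma)
  dimnames(g) <- list(rownames(N), rownames(object$beta))
  g
}

#' @export
plot.lda_vem <- function(x, ...) {
  graphics::plot(seq_along(x$elbo_trace), x$elbo_trace, type = "b",
                 xlab = "EM iteration", ylab = "ELBO",
                 main = "Variational EM convergence", ...)
  invisible(x)
}

#' Simulate count tables from a fitted topic model
#'
#' Draws multinomial counts for each sample with probabilities
#' `gamma[d, ] %*% beta` at the original (or supplied) depths.
#'
#' @param object Fitted [fit_lda()] model.
#' @param nsim Number of simulated tables.
#' @param seed Integer seed (default 1).
#' @param depths Per-sample read depths; default 10000 reads per sample.
#' @param ... Unused.
#' @return List of `nsim` samples x features count matrices.
#' @export
simulate.lda_vem <- function(object, nsim = 1L, seed = 1L,
                             depths = NULL, ...) {
  D <- length(object$doc_ids)
  if (is.null(depths)) depths <- rep(10000L, D)
  stopifnot(length(depths) == D, all(depths >= 1))
  P <- object$gamma %*% object$beta
  with_seed(seed, {
    lapply(seq_len(nsim), function(s) {
      out <- t(vapply(seq_len(D), function(d) {
        as.numeric(stats::rmultinom(1L, round(depths[d]), P[d, ]))
      }, numeric(ncol(P))))
      dimnames(out) <- list(object$doc_ids, object$vocab)
      out
    })
  })
}
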