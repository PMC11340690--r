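# Generative simulator for two-cohort community-typing studies: corpora drawn
# from the LDA generative process with group-dependent topic prevalence
# (the case/control effect enters through the document-topic Dirichlet prior
# mass, i.e. a prevalence shift, not a change of topic content) and optional
# topics shared verbatim across cohorts.

#' Specification of a synthetic cohort
#'
#' Defaults mirror the scale of published two-cohort 16S genus tables:
#' roughly 60 samples, 170 genera, 8 latent community types and log-normally
#' distributed read depths around 2e4.
#'
#' @param n_samples Number of samples D.
#' @param n_features Number of genera V.
#' @param n_topics Number of latent topics K.
#' @param depth_mean Mean per-sample read depth (log-normal).
#' @param depth_sdlog Log-scale depth standard deviation (default 0.3).
#' @param alpha0 Base document-topic Dirichlet concentration per topic
#'   (default 0.5: samples dominated by a few communities).
#' @param eta0 Topic-term Dirichlet concentration per term (default 0.1:
#'   sparse, distinct topics).
#' @param case_fraction Fraction of samples labeled case (default 0.5).
#' @param effect_topics Integer topic indices whose prior mass is multiplied
#'   in cases (default none).
#' @param effect_size Multiplier on the prior mass of `effect_topics` in
#'   cases (default 1 = no group effect).
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 60L, n_features = 170L, n_topics = 8L,
                           depth_mean = 2e4, depth_sdlog = 0.3,
                           alpha0 = 0.5, eta0 = 0.1, case_fraction = 0.5,
                           effect_topics = integer(0), effect_size = 1,
                           seed = 1L) {
  stopifnot(n_samples >= 2L, n_features >= 2L, n_topics >= 1L,
            depth_mean >= 1, depth_sdlog >= 0, alpha0 > 0, eta0 > 0,
            case_fraction >= 0, case_fraction <= 1, effect_size > 0)
  effect_topics <- as.integer(effect_topics)
  if (length(effect_topics) &&
      (any(effect_topics < 1L) || any(effect_topics > n_topics))) {
    stop("effect_topics must index topics 1..", n_topics, call. = FALSE)
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_features = as.integer(n_features),
                 n_topics = as.integer(n_topics),
                 depth_mean = depth_mean, depth_sdlog = depth_sdlog,
                 alpha0 = alpha0, eta0 = eta0,
                 case_fraction = case_fraction,
                 effect_topics = effect_topics, effect_size = effect_size,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate one cohort from the LDA generative process
#'
#' Draws topic-term rows `beta_k ~ Dirichlet(eta0)` (unless supplied), per
#' sample a topic mixture `theta_d ~ Dirichlet(alpha_d)` where cases have the
#' prior mass of `effect_topics` multiplied by `effect_size`, a log-normal
#' read depth, and counts `~ Multinomial(depth, t(beta) %*% theta_d)`.
#' Deterministic given the spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @param fixed_topics Optional matrix of topic-term rows planted as the
#'   first topics (shared across cohorts); remaining topics are drawn fresh.
#' @param feature_ids,sample_prefix Identifier cosmetics.
#' @return Object of class `synthetic_dataset`: `table` (samples x genera
#'   counts), `meta` (data.frame with `group`; level order control, case),
#'   `true_beta` (K x V), `true_theta` (D x K), `depths`, `spec`.
#' @export
generate_dataset <- function(spec, fixed_topics = NULL, feature_ids = NULL,
                             sample_prefix = "S") {
  stopifnot(inherits(spec, "synthetic_spec"))
  D <- spec$n_samples; V <- spec$n_features; K <- spec$n_topics
  if (is.null(feature_ids)) {
    feature_ids <- sprintf("g%03d", seq_len(V))
  }
  stopifnot(length(feature_ids) == V)
  if (!is.null(fixed_topics)) {
    stopifnot(is.matrix(fixed_topics), ncol(fixed_topics) == V,
              nrow(fixed_topics) <= K)
  }
  with_seed(spec$seed, {
    n_fixed <- if (is.null(fixed_topics)) 0L else nrow(fixed_topics)
    beta <- rbind(fixed_topics,
                  if (K > n_fixed) rdirichlet(K - n_fixed, rep(spec$eta0, V)))
    n_case <- round(spec$case_fraction * D)
    group <- factor(rep(c("control", "case"), c(D - n_case, n_case)),
                    levels = c("control", "case"))
    alpha_base <- rep(spec$alpha0, K)
    alpha_case <- alpha_base
    alpha_case[spec$effect_topics] <-
      alpha_case[spec$effect_topics] * spec$effect_size
    theta <- matrix(0, D, K)
    for (d in seq_len(D)) {
      a <- if (group[d] == "case") alpha_case else alpha_base
      theta[d, ] <- rdirichlet(1L, a)
    }
    depths <- pmax(1, round(stats::rlnorm(
      D, meanlog = log(spec$depth_mean) - spec$depth_sdlog^2 / 2,
      sdlog = spec$depth_sdlog)))
    P <- theta %*% beta
    counts <- t(vapply(seq_len(D), function(d) {
      as.numeric(stats::rmultinom(1L, depths[d], P[d, ]))
    }, numeric(V)))
    sample_ids <- sprintf("%s%03d", sample_prefix, seq_len(D))
    dimnames(counts) <- list(sample_ids, feature_ids)
    dimnames(beta) <- list(paste("Topic", seq_len(K)), feature_ids)
    dimnames(theta) <- list(sample_ids, rownames(beta))
    meta <- data.frame(group = group, row.names = sample_ids)
    structure(list(table = counts, meta = meta, true_beta = beta,
                   true_theta = theta, depths = stats::setNames(depths, sample_ids),
                   spec = spec),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  s <- x$spec
  cat(sprintf("Synthetic cohort: %d samples x %d genera, %d topics, seed %d\n",
              s$n_samples, s$n_features, s$n_topics, s$seed))
  cat(sprintf("  cases: %d (effect x%g on topics %s)\n",
              sum(x$meta$group == "case"), s$effect_size,
              if (length(s$effect_topics)) paste(s$effect_topics, collapse = ",")
              else "none"))
  invisible(x)
}

#' Generate an exploratory/validation cohort pair with shared topics
#'
#' The first `n_shared` topic-term rows are drawn once and planted verbatim
#' in both cohorts (their cross-cohort cosine on the true matrices is exactly
#' 1); remaining topics are drawn independently. Optionally a random subset
#' of genera is dropped from cohort B's observed table to emulate cohorts
#' retaining different genus sets after independent filtering.
#'
#' @param spec_a,spec_b [synthetic_spec()]s with equal `n_features`.
#' @param n_shared Number of shared topics (`<= min(K_A, K_B)`).
#' @param seed Master seed for the shared topics; cohorts are generated under
#'   their own spec seeds.
#' @param drop_features_b Number of random genera removed from cohort B's
#'   observed table (ground-truth `true_beta` of B keeps the retained columns
#'   without renormalization).
#' @return `list(a = , b = )` of `synthetic_dataset`s.
#' @export
generate_paired_datasets <- function(spec_a, spec_b, n_shared, seed = 1L,
                                     drop_features_b = 0L) {
  stopifnot(inherits(spec_a, "synthetic_spec"),
            inherits(spec_b, "synthetic_spec"),
            spec_a$n_features == spec_b$n_features,
            n_shared >= 0L,
            n_shared <= min(spec_a$n_topics, spec_b$n_topics),
            drop_features_b >= 0L,
            drop_features_b < spec_b$n_features)
  V <- spec_a$n_features
  shared <- if (n_shared > 0L) {
    with_seed(seed, rdirichlet(n_shared, rep(spec_a$eta0, V)))
  }
  a <- generate_dataset(spec_a, fixed_topics = shared, sample_prefix = "A")
  b <- generate_dataset(spec_b, fixed_topics = shared, sample_prefix = "B")
  if (drop_features_b > 0L) {
    drop <- with_seed(seed + 1L,
                      sample(colnames(b$table), drop_features_b))
    keep <- setdiff(colnames(b$table), drop)
    b$table <- b$table[, keep, drop = FALSE]
    b$true_beta <- b$true_beta[, keep, drop = FALSE]
    b$dropped_features <- drop
  }
  list(a = a, b = b)
}
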