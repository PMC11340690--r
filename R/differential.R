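# Differential abundance: a bias-corrected compositional linear model for
# topics (per-feature least squares on log relative abundances, with the
# common compositional shift removed as the mode of the coefficient
# ensemble), and a Wilcoxon rank-sum screen on TSS-scaled genus tables.
# Both end in Benjamini-Hochberg adjustment and the conjunctive significance
# rule p <= 0.05 AND q <= 0.25.

#' Settings for the differential-abundance procedures
#'
#' @param pseudocount Added to every count before the log-ratio transform
#'   (default 0.5, the conventional count-mode half-count).
#' @param p_threshold Raw p-value threshold (default 0.05).
#' @param q_threshold BH-adjusted threshold (default 0.25).
#' @param winsorize Must be `FALSE`; outlier winsorization is deliberately
#'   disabled and not implemented.
#' @return Object of class `diff_settings`.
#' @export
diff_settings <- function(pseudocount = 0.5, p_threshold = 0.05,
                          q_threshold = 0.25, winsorize = FALSE) {
  stopifnot(pseudocount > 0,
            p_threshold > 0, p_threshold < 1,
            q_threshold > 0, q_threshold < 1)
  if (isTRUE(winsorize)) {
    stop("winsorization is not supported (and is disabled by design)",
         call. = FALSE)
  }
  structure(list(pseudocount = pseudocount, p_threshold = p_threshold,
                 q_threshold = q_threshold, winsorize = FALSE),
            class = "diff_settings")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (`q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1,
#' mapped back to input order), computed via [stats::p.adjust()].
#'
#' @param p_values Vector of p-values in `[0, 1]`.
#' @return Vector of adjusted q-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Midranks for ties; exact null distribution when the combined sample size
#' is at most 12 and no ties are present, otherwise the normal approximation
#' with continuity and tie corrections.
#'
#' @param x,y Values of the two groups (both nonempty).
#' @return `list(stat = rank-sum W statistic, p = two-sided p-value,
#'   exact = logical)`. All values identical across both groups gives p = 1.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  if (length(unique(c(x, y))) == 1L) {
    return(list(stat = length(x) * length(y) / 2, p = 1, exact = FALSE))
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y) <= 12L) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  p <- wt$p.value
  if (!is.finite(p)) p <- 1
  list(stat = unname(wt$statistic), p = min(p, 1), exact = exact)
}

.check_binary_group <- function(meta) {
  if (!"group" %in% colnames(meta)) {
    stop("metadata must contain a 'group' column", call. = FALSE)
  }
  g <- factor(meta$group)
  g <- droplevels(g)
  if (nlevels(g) != 2L) {
    stop("group must have exactly 2 observed levels, found ", nlevels(g),
         call. = FALSE)
  }
  if (any(table(g) < 2L)) {
    stop("each group level needs at least 2 samples", call. = FALSE)
  }
  g
}

#' Bias-corrected compositional linear model for differential abundance
#'
#' For feature j and sample i the model regresses
#' `y[i, j] = log2((count[i, j] + pseudocount) / depth[i])` on the group
#' indicator (plus optional covariates) by least squares. Because the
#' compositional constraint shifts every feature's log relative abundance by
#' the same unknown amount, the ensemble of fitted group coefficients is
#' centered by subtracting its mode, estimated by Gaussian kernel density
#' (Silverman bandwidth) maximized on a 512-point grid spanning the
#' coefficient range. Corrected coefficients are referred to a t distribution
#' with the regression's residual degrees of freedom, then BH-adjusted.
#'
#' @param table Samples x features matrix of (possibly fractional) counts;
#'   features may be topics. At least 2 features are required, since the
#'   bias correction needs a coefficient ensemble.
#' @param meta Metadata with a binary `group` column (first level is the
#'   reference; effects are second level vs first). Rows must match the
#'   table's samples.
#' @param settings [diff_settings()].
#' @param covariates Optional character vector of additional metadata columns
#'   to adjust for.
#' @return data.frame of class `linda_da` with one row per feature:
#'   `feature`, `effect` (bias-corrected log2 fold change), `se`, `stat`,
#'   `p`, `q`, `significant`. Attributes: `bias` (the subtracted mode),
#'   `df`, `settings`. Features with zero residual variance get `p = 1` and
#'   are flagged in the `degenerate` column.
#' @export
linda_test <- function(table, meta, settings = diff_settings(),
                       covariates = NULL) {
  validate_count_table(table, require_positive_rows = TRUE)
  stopifnot(inherits(settings, "diff_settings"))
  if (ncol(table) < 2L) {
    stop("bias correction needs at least 2 features", call. = FALSE)
  }
  meta <- meta[rownames(table), , drop = FALSE]
  g <- .check_binary_group(meta)
  depth <- rowSums(table)
  Y <- log2((table + settings$pseudocount) / depth)
  dat <- data.frame(group = g)
  form <- ~ group
  if (!is.null(covariates)) {
    missing <- setdiff(covariates, colnames(meta))
    if (length(missing)) {
      stop("covariates absent from metadata: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    dat <- cbind(dat, meta[, covariates, drop = FALSE])
    form <- stats::reformulate(c("group", covariates))
  }
  X <- stats::model.matrix(form, dat)
  if (qr(X)$rank < ncol(X)) {
    stop("design matrix is rank-deficient (constant group or collinear covariates)",
         call. = FALSE)
  }
  XtX_inv <- solve(crossprod(X))
  B <- XtX_inv %*% crossprod(X, Y)            # coefficients, q x p
  R <- Y - X %*% B
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(R^2) / df
  ci <- XtX_inv[2L, 2L]                        # group coefficient variance factor
  b <- B[2L, ]
  se <- sqrt(sigma2 * ci)
  bias <- .coef_mode(b)
  effect <- b - bias
  # a feature whose transformed values are identical in every sample has no
  # residual variance; tiny positive sigma2 from floating-point matrix
  # arithmetic must not masquerade as evidence
  constant <- apply(Y, 2L, function(col) diff(range(col)) == 0)
  degenerate <- constant | se <= 0 | !is.finite(se)
  stat <- ifelse(degenerate, NA_real_, effect / se)
  p <- ifelse(degenerate, 1, 2 * stats::pt(-abs(stat), df))
  q <- bh_adjust(p)
  out <- data.frame(feature = colnames(table), effect = effect, se = se,
                    stat = stat, p = p, q = q,
                    significant = p <= settings$p_threshold &
                                  q <= settings$q_threshold,
                    degenerate = degenerate,
                    row.names = NULL, stringsAsFactors = FALSE)
  out$se[degenerate] <- NA_real_
  attr(out, "bias") <- bias
  attr(out, "df") <- df
  attr(out, "settings") <- settings
  attr(out, "contrast") <- paste(levels(g)[2L], "vs", levels(g)[1L])
  class(out) <- c("linda_da", "data.frame")
  out
}

# Mode of the coefficient ensemble: Gaussian KDE, Silverman bandwidth,
# argmax over a 512-point grid spanning the coefficient range.
.coef_mode <- function(b) {
  if (length(unique(b)) == 1L || stats::sd(b) == 0) return(b[1L])
  d <- stats::density(b, bw = "nrd0", kernel = "gaussian", n = 512L,
                      from = min(b), to = max(b))
  d$x[which.max(d$y)]
}

#' @export
print.linda_da <- function(x, ...) {
  s <- attr(x, "settings")
  if (!is.null(s)) {   # subsetting drops attributes; print what survives
    cat("Bias-corrected compositional differential abundance (",
        attr(x, "contrast"), ")\n", sep = "")
    cat(sprintf("  %d features, residual df = %d, compositional bias = %.4f\n",
                nrow(x), attr(x, "df"), attr(x, "bias")))
    cat("  significant (p <=", s$p_threshold, "& q <=", s$q_threshold, "):",
        sum(x$significant), "\n")
  }
  NextMethod()
}

#' Genus-level Wilcoxon screen on TSS-scaled abundances
#'
#' Applies total-sum scaling to `scale` reads per sample, tests every genus
#' between the two groups with [wilcoxon_rank_sum()], adjusts with
#' [bh_adjust()], and applies the conjunctive significance rule. The effect
#' column is `log2((mean case + 1) / (mean control + 1))` on the TSS scale
#' and indicates direction only.
#'
#' @param table Samples x genera count matrix (already filtered).
#' @param meta Metadata with a binary `group` column; second level is the
#'   case group.
#' @param settings [diff_settings()].
#' @param scale TSS target (default 1e6).
#' @return data.frame with the same columns as [linda_test()] (`se` is `NA`;
#'   `stat` is the rank-sum statistic).
#' @export
genus_level_screen <- function(table, meta, settings = diff_settings(),
                               scale = 1e6) {
  validate_count_table(table)
  meta <- meta[rownames(table), , drop = FALSE]
  g <- .check_binary_group(meta)
  tss <- tss_normalize(table, scale = scale)
  case <- g == levels(g)[2L]
  res <- lapply(seq_len(ncol(tss)), function(j) {
    wilcoxon_rank_sum(tss[case, j], tss[!case, j])
  })
  p <- vapply(res, `[[`, 0, "p")
  q <- bh_adjust(p)
  effect <- log2((colMeans(tss[case, , drop = FALSE]) + 1) /
                 (colMeans(tss[!case, , drop = FALSE]) + 1))
  data.frame(feature = colnames(tss), effect = unname(effect), se = NA_real_,
             stat = vapply(res, `[[`, 0, "stat"), p = p, q = q,
             significant = p <= settings$p_threshold &
                           q <= settings$q_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}
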