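# Cross-cohort validation of community types: topic-term distributions from
# two independently fitted models are expressed over a common vocabulary,
# compared by cosine similarity, thresholded into a many-to-many match set,
# and grouped into community types as connected components of the bipartite
# match graph.

#' Express two topic-term matrices over their union vocabulary
#'
#' Both matrices are re-expressed over the sorted union of their term sets;
#' terms absent from one matrix get probability 0 there. Rows are *not*
#' renormalized: renormalizing would inflate similarity between topics
#' concentrated on shared taxa.
#'
#' @param beta_a,beta_b Topics x terms matrices with term colnames (or
#'   fitted [fit_lda()] models).
#' @return `list(beta_a = , beta_b = , vocab = )` over the union vocabulary.
#' @export
harmonize_vocabularies <- function(beta_a, beta_b) {
  beta_a <- .as_beta(beta_a); beta_b <- .as_beta(beta_b)
  va <- colnames(beta_a); vb <- colnames(beta_b)
  if (is.null(va) || is.null(vb)) {
    stop("topic-term matrices must carry term colnames", call. = FALSE)
  }
  if (length(intersect(va, vb)) == 0L) {
    stop("vocabularies are disjoint; nothing to compare", call. = FALSE)
  }
  vocab <- sort(union(va, vb))
  expand <- function(m) {
    out <- matrix(0, nrow(m), length(vocab),
                  dimnames = list(rownames(m), vocab))
    out[, colnames(m)] <- m
    out
  }
  list(beta_a = expand(beta_a), beta_b = expand(beta_b), vocab = vocab)
}

#' Cosine similarity of two nonnegative vectors
#'
#' @param u,v Nonnegative numeric vectors of equal length with positive norm.
#' @return `dot(u, v) / (|u| |v|)`, in `[0, 1]` for nonnegative inputs.
#' @export
cosine_similarity <- function(u, v) {
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("zero vector has no direction", call. = FALSE)
  sum(u * v) / (nu * nv)
}

# All-pairs cosine between rows of A and rows of B (same column space).
.cosine_matrix <- function(A, B) {
  na <- sqrt(rowSums(A^2)); nb <- sqrt(rowSums(B^2))
  if (any(na == 0) || any(nb == 0)) {
    stop("zero topic row encountered", call. = FALSE)
  }
  tcrossprod(A, B) / outer(na, nb)
}

# Connected components via union-find on character node ids.
.components <- function(nodes, edges_from, edges_to) {
  parent <- stats::setNames(seq_along(nodes), nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (e in seq_along(edges_from)) {
    ra <- find(which(nodes == edges_from[e]))
    rb <- find(which(nodes == edges_to[e]))
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(seq_along(nodes), find, 0L)
  match(roots, unique(roots))
}

#' Match topics across two models by cosine similarity
#'
#' Computes the full `K_A x K_B` cosine-similarity matrix over the harmonized
#' (union, zero-filled) vocabulary, keeps every pair at or above the
#' threshold (matching is many-to-many; several topics of one model may match
#' a single topic of the other), and groups matched topics into community
#' types as connected components of the bipartite match graph.
#'
#' @param model_a,model_b Fitted [fit_lda()] models (or topics x terms
#'   probability matrices with term colnames).
#' @param threshold Inclusive cosine cutoff (default 0.80).
#' @param labels Length-2 character vector naming the two datasets in
#'   community reports (default `c("A", "B")`).
#' @return Object of class `topic_match`: `similarity` (K_A x K_B matrix),
#'   `matches` (data.frame `topic_a`, `topic_b`, `cosine`), `communities`
#'   (data.frame `community`, `dataset`, `topic`), `threshold`, `labels`.
#' @export
match_topics <- function(model_a, model_b, threshold = 0.80,
                         labels = c("A", "B")) {
  stopifnot(threshold >= 0, threshold <= 1, length(labels) == 2L)
  h <- harmonize_vocabularies(model_a, model_b)
  sim <- .cosine_matrix(h$beta_a, h$beta_b)
  hits <- which(sim >= threshold, arr.ind = TRUE)
  matches <- data.frame(
    topic_a = rownames(sim)[hits[, 1L]],
    topic_b = colnames(sim)[hits[, 2L]],
    cosine = sim[hits],
    stringsAsFactors = FALSE)
  matches <- matches[order(matches$topic_a, matches$topic_b), , drop = FALSE]
  rownames(matches) <- NULL
  if (nrow(matches)) {
    node_a <- paste0(labels[1L], ":", matches$topic_a)
    node_b <- paste0(labels[2L], ":", matches$topic_b)
    nodes <- unique(c(node_a, node_b))
    comp <- .components(nodes, node_a, node_b)
    communities <- data.frame(
      community = comp,
      dataset = sub(":.*$", "", nodes),
      topic = sub("^[^:]*:", "", nodes),
      stringsAsFactors = FALSE)
    communities <- communities[order(communities$community,
                                     communities$dataset,
                                     communities$topic), , drop = FALSE]
    rownames(communities) <- NULL
  } else {
    communities <- data.frame(community = integer(0), dataset = character(0),
                              topic = character(0), stringsAsFactors = FALSE)
  }
  structure(list(similarity = sim, matches = matches,
                 communities = communities, threshold = threshold,
                 labels = labels),
            class = "topic_match")
}

#' @export
print.topic_match <- function(x, ...) {
  cat(sprintf("Cross-dataset topic matching (%d x %d topics, cosine >= %.2f)\n",
              nrow(x$similarity), ncol(x$similarity), x$threshold))
  cat("  matched pairs:", nrow(x$matches),
      "  community types:", length(unique(x$communities$community)), "\n")
  if (nrow(x$matches)) print(x$matches, row.names = FALSE)
  invisible(x)
}

#' Annotate matched community types with differential-abundance evidence
#'
#' Labels every community type with the significance and enrichment direction
#' of its member topics in each dataset, and flags it as validated according
#' to the chosen rule: `"exploratory-significant"` (default; the community
#' contains a significant topic of the exploratory dataset A, matched across
#' cohorts by construction) or `"both-significant"` (some matched pair has a
#' significant topic on both sides), which is strictly more stringent.
#'
#' @param matches A [match_topics()] result.
#' @param diff_a,diff_b Differential-abundance results ([linda_test()]) for
#'   the two datasets' topic tables; `feature` entries must use the same
#'   topic identifiers as the models.
#' @param rule Validation rule (see above).
#' @return data.frame with one row per community type: `community`,
#'   `topics_a`, `topics_b` (comma-separated), `n_significant_a`,
#'   `n_significant_b`, `direction` (sign consensus of significant effects,
#'   `"case-enriched"`, `"control-enriched"` or `"mixed"`), `validated`.
#' @export
validated_communities <- function(matches, diff_a, diff_b,
                                  rule = c("exploratory-significant",
                                           "both-significant")) {
  stopifnot(inherits(matches, "topic_match"))
  rule <- match.arg(rule)
  comm <- matches$communities
  lookup <- function(diff, topics, col) {
    idx <- match(topics, diff$feature)
    if (anyNA(idx)) {
      stop("unknown topic identifier(s): ",
           paste(topics[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    diff[[col]][idx]
  }
  ids <- sort(unique(comm$community))
  rows <- lapply(ids, function(cid) {
    sub <- comm[comm$community == cid, , drop = FALSE]
    ta <- sub$topic[sub$dataset == matches$labels[1L]]
    tb <- sub$topic[sub$dataset == matches$labels[2L]]
    sig_a <- lookup(diff_a, ta, "significant")
    sig_b <- lookup(diff_b, tb, "significant")
    eff <- c(lookup(diff_a, ta, "effect")[sig_a],
             lookup(diff_b, tb, "effect")[sig_b])
    direction <- if (length(eff) == 0L) "none"
      else if (all(eff > 0)) "case-enriched"
      else if (all(eff < 0)) "control-enriched"
      else "mixed"
    validated <- if (rule == "exploratory-significant") any(sig_a) else {
      pair_ok <- FALSE
      m <- matches$matches
      for (r in seq_len(nrow(m))) {
        if (m$topic_a[r] %in% ta && m$topic_b[r] %in% tb &&
            lookup(diff_a, m$topic_a[r], "significant") &&
            lookup(diff_b, m$topic_b[r], "significant")) {
          pair_ok <- TRUE
          break
        }
      }
      pair_ok
    }
    data.frame(community = cid,
               topics_a = paste(ta, collapse = ","),
               topics_b = paste(tb, collapse = ","),
               n_significant_a = sum(sig_a),
               n_significant_b = sum(sig_b),
               direction = direction,
               validated = validated,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(community = integer(0), topics_a = character(0),
                      topics_b = character(0), n_significant_a = integer(0),
                      n_significant_b = integer(0), direction = character(0),
                      validated = logical(0), stringsAsFactors = FALSE)
  }
  attr(out, "rule") <- rule
  out
}
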