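test_that("cosine similarity matches closed forms", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0.0)
  expect_equal(cosine_similarity(c(1, 1, 0), c(1, 0, 0)), 1 / sqrt(2))
  expect_error(cosine_similarity(c(0, 0), c(1, 0)), "zero vector")
})

test_that("vocabulary harmonization zero-fills without renormalizing", {
  a <- matrix(c(0.6, 0.4), 1, dimnames = list("Topic 1", c("g1", "g2")))
  b <- matrix(c(0.7, 0.3), 1, dimnames = list("Topic 1", c("g2", "g3")))
  h <- harmonize_vocabularies(a, b)
  expect_identical(h$vocab, c("g1", "g2", "g3"))
  expect_equal(unname(h$beta_a[1, ]), c(0.6, 0.4, 0))
  expect_equal(unname(h$beta_b[1, ]), c(0, 0.7, 0.3))
  expect_equal(rowSums(h$beta_b), c("Topic 1" = 1))  # no renormalization

  # identical vocabularies: unchanged up to column order
  h2 <- harmonize_vocabularies(a, a)
  expect_equal(h2$beta_a[, colnames(a)], a[1, ])

  d <- matrix(1, 1, 1, dimnames = list("Topic 1", "zz"))
  expect_error(harmonize_vocabularies(a, d), "disjoint")
})

test_that("self-matching returns the diagonal for separated topics", {
  beta <- diag(4) * 0.9 + 0.025
  colnames(beta) <- paste0("g", 1:4)
  rownames(beta) <- paste("Topic", 1:4)
  mt <- match_topics(beta, beta, threshold = 0.80)
  expect_equal(unname(diag(mt$similarity)), rep(1, 4))
  expect_identical(mt$matches$topic_a, mt$matches$topic_b)
  expect_equal(nrow(mt$matches), 4)
  # at threshold 1 + jittered copy, generic fits give an empty match set
  mt2 <- match_topics(beta, beta + 1e-3, threshold = 1)
  expect_equal(nrow(mt2$matches), 0)
  expect_equal(nrow(mt2$communities), 0)
})

test_that("matching is symmetric under argument transposition", {
  set.seed(8)
  a <- mbtopics:::rdirichlet(4, rep(0.3, 25))
  b <- mbtopics:::rdirichlet(5, rep(0.3, 25))
  colnames(a) <- colnames(b) <- paste0("g", 1:25)
  rownames(a) <- paste("Topic", 1:4)
  rownames(b) <- paste("Topic", 1:5)
  m_ab <- match_topics(a, b, threshold = 0.2)
  m_ba <- match_topics(b, a, threshold = 0.2)
  expect_equal(m_ab$similarity, t(m_ba$similarity))
  expect_equal(nrow(m_ab$matches), nrow(m_ba$matches))
})

test_that("communities are connected components and partition matched topics", {
  # A1-B1, A2-B1 (many-to-one), A3-B2: two communities
  beta_b <- rbind(c(1, 0, 0, 0), c(0, 0, 1, 0))
  beta_a <- rbind(c(0.97, 0.03, 0, 0), c(0.9, 0.1, 0, 0), c(0, 0, 0.95, 0.05))
  colnames(beta_a) <- colnames(beta_b) <- paste0("g", 1:4)
  rownames(beta_a) <- paste("Topic", 1:3)
  rownames(beta_b) <- paste("Topic", 1:2)
  mt <- match_topics(beta_a, beta_b, threshold = 0.80)
  expect_equal(nrow(mt$matches), 3)
  expect_equal(length(unique(mt$communities$community)), 2)
  # each matched topic appears in exactly one community
  key <- paste(mt$communities$dataset, mt$communities$topic)
  expect_false(anyDuplicated(key) > 0)
})

test_that("validation rules annotate communities and nest correctly", {
  beta_b <- rbind(c(1, 0, 0, 0), c(0, 0, 1, 0))
  beta_a <- rbind(c(0.97, 0.03, 0, 0), c(0.9, 0.1, 0, 0), c(0, 0, 0.95, 0.05))
  colnames(beta_a) <- colnames(beta_b) <- paste0("g", 1:4)
  rownames(beta_a) <- paste("Topic", 1:3)
  rownames(beta_b) <- paste("Topic", 1:2)
  mt <- match_topics(beta_a, beta_b, threshold = 0.80)
  diff_a <- data.frame(feature = paste("Topic", 1:3),
                       effect = c(1.2, -0.5, 0.3),
                       significant = c(TRUE, FALSE, FALSE))
  diff_b <- data.frame(feature = paste("Topic", 1:2),
                       effect = c(0.8, 0.9),
                       significant = c(FALSE, TRUE))
  expl <- validated_communities(mt, diff_a, diff_b,
                                rule = "exploratory-significant")
  both <- validated_communities(mt, diff_a, diff_b, rule = "both-significant")
  # community with the significant A topic is validated under the lax rule
  expect_true(expl$validated[grepl("Topic 1", expl$topics_a)])
  expect_false(expl$validated[expl$topics_a == "Topic 3"])
  # stricter rule validates a subset
  expect_true(all(both$validated <= expl$validated))
  # A1 significant but its matched B1 is not: fails both-significant
  expect_false(both$validated[grepl("Topic 1", both$topics_a)])
  expect_error(validated_communities(mt, diff_a[-1, ], diff_b),
               "unknown topic")
})
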