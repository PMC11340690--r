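test_that("generation is deterministic and respects depths", {
  spec <- synthetic_spec(n_samples = 20, n_features = 30, n_topics = 4,
                         depth_mean = 2000, seed = 5)
  d1 <- generate_dataset(spec)
  d2 <- generate_dataset(spec)
  expect_identical(d1$table, d2$table)
  expect_identical(d1$true_beta, d2$true_beta)
  expect_identical(unname(rowSums(d1$table)), unname(d1$depths))
  expect_lt(max(abs(rowSums(d1$true_theta) - 1)), 1e-12)
})

test_that("a single-topic model degenerates to one multinomial", {
  d <- generate_dataset(synthetic_spec(n_samples = 10, n_features = 20,
                                       n_topics = 1, depth_mean = 1000,
                                       seed = 2))
  expect_true(all(d$true_theta == 1))
  expect_identical(dim(d$true_beta), c(1L, 20L))
})

test_that("invalid specs are rejected", {
  expect_error(synthetic_spec(effect_topics = 9, n_topics = 8), "1..8")
  expect_error(synthetic_spec(effect_size = 0))
  expect_error(synthetic_spec(alpha0 = -1))
})

test_that("case/control are exchangeable when the effect is absent", {
  # with effect_size = 1 the group label carries no information; the mean
  # topic mass difference between groups should be small noise
  diffs <- sapply(1:10, function(s) {
    d <- generate_dataset(synthetic_spec(n_samples = 80, n_features = 40,
                                         n_topics = 4, depth_mean = 1000,
                                         effect_topics = 1, effect_size = 1,
                                         seed = s))
    case <- d$meta$group == "case"
    mean(d$true_theta[case, 1]) - mean(d$true_theta[!case, 1])
  })
  expect_lt(abs(mean(diffs)), 0.03)
})

test_that("the group effect raises topic prevalence in cases", {
  d <- generate_dataset(synthetic_spec(n_samples = 300, n_features = 40,
                                       n_topics = 5, depth_mean = 1000,
                                       effect_topics = 1, effect_size = 4,
                                       seed = 3))
  case <- d$meta$group == "case"
  expect_gt(mean(d$true_theta[case, 1]), mean(d$true_theta[!case, 1]) + 0.05)
})

test_that("expected genus abundance follows mean(theta) x beta", {
  d <- generate_dataset(synthetic_spec(n_samples = 150, n_features = 30,
                                       n_topics = 3, depth_mean = 5e4,
                                       depth_sdlog = 0, seed = 9))
  expected <- colMeans(d$true_theta %*% d$true_beta)
  observed <- colSums(d$table) / sum(d$table)
  expect_lt(max(abs(observed - expected)), 0.01)
})

test_that("paired cohorts share exactly the planted topics", {
  sa <- synthetic_spec(n_samples = 10, n_features = 25, n_topics = 4, seed = 1)
  sb <- synthetic_spec(n_samples = 10, n_features = 25, n_topics = 4, seed = 2)
  pair <- generate_paired_datasets(sa, sb, n_shared = 2, seed = 3)
  expect_identical(pair$a$true_beta[1:2, ], pair$b$true_beta[1:2, ])
  expect_false(identical(pair$a$true_beta[3, ], pair$b$true_beta[3, ]))
  for (k in 1:2) {
    expect_equal(cosine_similarity(pair$a$true_beta[k, ],
                                   pair$b$true_beta[k, ]), 1.0)
  }
  # full sharing and no sharing
  pair2 <- generate_paired_datasets(sa, sb, n_shared = 4, seed = 3)
  expect_identical(pair2$a$true_beta, pair2$b$true_beta)
  pair0 <- generate_paired_datasets(sa, sb, n_shared = 0, seed = 3)
  expect_false(any(duplicated(rbind(pair0$a$true_beta, pair0$b$true_beta))))

  # vocabulary mismatch emulation drops columns from B only
  pair3 <- generate_paired_datasets(sa, sb, n_shared = 2, seed = 3,
                                    drop_features_b = 5)
  expect_equal(ncol(pair3$b$table), 20)
  expect_equal(ncol(pair3$a$table), 25)
  expect_identical(colnames(pair3$b$true_beta), colnames(pair3$b$table))
})
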