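test_that("wilcoxon exact path matches the enumeration oracle", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p, 0.1)
  # identical multisets with ties: stat at its null mean, p ~ 1
  r <- wilcoxon_rank_sum(c(1, 2), c(1, 2))
  expect_equal(r$stat, 2)
  expect_gt(r$p, 0.9)
  expect_equal(wilcoxon_rank_sum(rep(3, 4), rep(3, 5))$p, 1)

  set.seed(42)
  for (m in 2:5) {
    for (n in m:(10 - m)) {
      x <- sample(1000, m)
      y <- sample(2000:3000, n)
      got <- wilcoxon_rank_sum(x, y)
      expect_true(got$exact)
      expect_equal(got$p, wilcoxon_enum_oracle(x, y), tolerance = 1e-12,
                   info = sprintf("m=%d n=%d", m, n))
    }
  }
})

test_that("BH adjustment matches the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(7)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_lt(max(abs(bh_adjust(p) - bh_bruteforce(p))), 1e-12)
  }
})

test_that("identical features receive identical statistics", {
  tab <- rand_count_table(20, 5, depth = 2000, seed = 3)
  tab <- cbind(tab, dup1 = tab[, 2], dup2 = tab[, 2])
  meta <- data.frame(group = factor(rep(c("hc", "ms"), each = 10),
                                    levels = c("hc", "ms")),
                     row.names = rownames(tab))
  res <- linda_test(tab, meta)
  expect_equal(res$p[res$feature == "dup1"], res$p[res$feature == "dup2"])
  expect_equal(res$effect[res$feature == "dup1"],
               res$effect[res$feature == "dup2"])
})

test_that("degenerate features and invalid designs are handled", {
  # constant depth + constant count gives a feature whose transformed
  # values are identical in every sample (undefined standard error)
  set.seed(5)
  mid <- matrix(sample(50:200, 36, replace = TRUE), 12, 3)
  tab <- cbind(50, mid, 2000 - 50 - rowSums(mid))
  dimnames(tab) <- list(paste0("s", 1:12), paste0("f", 1:5))
  meta <- data.frame(group = factor(rep(c("a", "b"), each = 6)),
                     row.names = rownames(tab))
  res <- linda_test(tab, meta)
  expect_true(res$degenerate[1])
  expect_equal(res$p[1], 1)
  expect_true(is.na(res$se[1]))

  meta$group <- factor(rep("a", 12))
  expect_error(linda_test(tab, meta), "2 observed levels")
  tab[, 1] <- 51:62
  expect_error(linda_test(tab[, 1, drop = FALSE],
                          data.frame(group = factor(rep(c("a", "b"), 6)),
                                     row.names = rownames(tab))),
               "at least 2 features")
  expect_error(diff_settings(winsorize = TRUE), "not supported")
})

test_that("a pure compositional shift yields near-zero corrected effects", {
  set.seed(31)
  meds <- replicate(50, {
    V <- 100; n <- 100
    base <- as.numeric(mbtopics:::rdirichlet(1, rep(2, V)))
    counts <- t(vapply(seq_len(n), function(i) {
      as.numeric(stats::rmultinom(1, 1e4, base))
    }, numeric(V)))
    dimnames(counts) <- list(paste0("s", seq_len(n)), paste0("f", seq_len(V)))
    counts <- counts[, colSums(counts) > 0, drop = FALSE]
    meta <- data.frame(group = factor(rep(c("control", "case"), each = n / 2),
                                      levels = c("control", "case")),
                       row.names = rownames(counts))
    median(abs(linda_test(counts, meta)$effect))
  })
  expect_lt(median(meds), 0.05)
})

test_that("the genus screen applies TSS, ranks and the conjunctive rule", {
  # groups with identical sample compositions: nothing is significant
  half <- rand_count_table(20, 30, depth = 5000, seed = 17)
  tab0 <- rbind(half, half)
  rownames(tab0) <- paste0("s", 1:40)
  meta <- data.frame(group = factor(rep(c("hc", "ms"), each = 20),
                                    levels = c("hc", "ms")),
                     row.names = rownames(tab0))
  res0 <- genus_level_screen(tab0, meta)
  expect_false(any(res0$significant))

  # planted case enrichment (counts moved from the most abundant genus so
  # row sums, hence the TSS factor, stay untouched)
  tab <- tab0
  donor <- which.max(colSums(tab0))
  target <- order(colSums(tab0), decreasing = TRUE)[10]
  ms <- meta$group == "ms"
  shift <- floor(tab[ms, donor] / 2)
  tab[ms, target] <- tab[ms, target] + shift
  tab[ms, donor] <- tab[ms, donor] - shift
  res <- genus_level_screen(tab, meta)
  expect_true(res$significant[target])
  expect_gt(res$effect[target], 0)
  expect_identical(res$significant, res$p <= 0.05 & res$q <= 0.25)
})
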