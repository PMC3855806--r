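test_that("permutation p-values obey the add-one and degeneracy rules", {
  d <- planted_data(n = 100, m = 20, n_signal = 2, effect = 10, seed = 2)
  X <- d$X
  X[, 20] <- 5  # constant feature
  p <- permutation_pvalues(X, d$y, n_perm = 1000, seed = 3)
  expect_equal(unname(p[20]), 1)
  # a 10-sd separation cannot be reached by any permutation
  expect_equal(unname(p[1]), 1 / 1001)
  expect_true(all(p > 0 & p <= 1))
  expect_error(permutation_pvalues(X, rep(1, 100)), "two classes")
  # determinism
  p2 <- permutation_pvalues(X, d$y, n_perm = 1000, seed = 3)
  expect_identical(p, p2)
})

test_that("null permutation p-values are approximately uniform", {
  d <- planted_data(n = 40, m = 500, n_signal = 0, seed = 4)
  p <- permutation_pvalues(d$X, d$y, n_perm = 1000, seed = 5)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("q-values follow the Storey estimator and match the brute-force oracle", {
  expect_equal(as.numeric(qvalues(rep(1, 5))), rep(1, 5))
  # hand evaluation at lambda = 0.5: pi0 = 1, q = (0.04, 0.04, 0.9, 0.9)
  q <- qvalues(c(0.01, 0.02, 0.8, 0.9))
  expect_equal(as.numeric(q), c(0.04, 0.04, 0.9, 0.9))
  expect_equal(attr(q, "pi0"), 1)
  expect_error(qvalues(c(0.5, 0)), "\\(0, 1\\]")

  withr::with_seed(8, {
    for (rep in 1:50) {
      m <- sample(3:40, 1)
      p <- runif(m)^sample(1:3, 1)
      p[p == 0] <- 0.5
      q <- as.numeric(qvalues(p))
      expect_equal(q, oracle_qvalues(p), tolerance = 1e-12)
      expect_true(all(q <= 1))
      # q monotone in p
      expect_true(all(diff(q[order(p)]) >= -1e-15))
    }
  })
})

test_that("SVM-RFE ranks a separating feature last and groups duplicates", {
  d <- planted_data(n = 120, m = 21, n_signal = 1, effect = 6, seed = 6)
  hits <- 0
  for (s in 1:20) {
    dd <- planted_data(n = 120, m = 21, n_signal = 1, effect = 6, seed = s)
    r <- svm_rfe(dd$X, dd$y)
    if (r$elim_rank[1] == max(r$elim_rank)) hits <- hits + 1
  }
  expect_gte(hits, 19)

  r2 <- svm_rfe(d$X[, 1:2], d$y)
  expect_setequal(r2$elim_rank, 1:2)

  Xdup <- cbind(d$X[, 1:5], dup = d$X[, 1])
  r3 <- svm_rfe(Xdup, d$y)
  expect_equal(r3$elim_rank[6], r3$elim_rank[1])
  expect_equal(r3$group[6], r3$group[1])
})

test_that("two-stage selection recovers planted features compactly", {
  recovered <- integer(0)
  total <- integer(0)
  for (s in 1:3) {
    d <- planted_data(n = 200, m = 200, n_signal = 10, effect = 2, seed = s)
    sel <- select_features(d$X, d$y, q_cutoff = 0.005, n_perm = 5000,
                           cv_folds = 5, seed = s)
    tab <- sel$table
    # planted features must survive the q-value screen; the final subset may
    # legitimately be smaller because the planted effects are redundant
    recovered <- c(recovered, sum(tab$q_value[1:10] < 0.005))
    total <- c(total, sum(tab$selected))
    expect_true(all(tab$q_value[tab$selected] < 0.005))
  }
  expect_true(all(recovered >= 8))
  expect_true(all(total <= 20))
})

test_that("selection is deterministic and degrades to the RFE minimum subset", {
  d <- planted_data(n = 80, m = 12, n_signal = 2, effect = 3, seed = 10)
  s1 <- select_features(d$X, d$y, q_cutoff = 1.0000001, perf_tolerance = 1,
                        n_perm = 200, cv_folds = 4, seed = 1)
  # with unlimited tolerance the smallest nested subset (one group) wins
  expect_equal(s1$n_selected, 1L)
  s2 <- select_features(d$X, d$y, q_cutoff = 1.0000001, perf_tolerance = 1,
                        n_perm = 200, cv_folds = 4, seed = 1)
  expect_identical(tidy(s1), tidy(s2))

  dn <- planted_data(n = 60, m = 30, n_signal = 0, seed = 11)
  expect_error(select_features(dn$X, dn$y, q_cutoff = 1e-6, n_perm = 100),
               "q_cutoff")
})

test_that("few features are called under a global null", {
  frac <- vapply(1:5, function(s) {
    d <- planted_data(n = 60, m = 500, n_signal = 0, seed = 100 + s)
    p <- permutation_pvalues(d$X, d$y, n_perm = 500, seed = s)
    mean(qvalues(p) < 0.005)
  }, numeric(1))
  expect_lte(mean(frac), 0.02)
})
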