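test_that("affinity matrix follows the Gaussian kernel contract", {
  X <- rbind(a = c(0, 0), b = c(0, 0), c = c(3, 4))
  W <- build_affinity(X, ranking_config(sigma = 1))
  expect_equal(W["a", "b"], 1)
  expect_equal(max(abs(diag(W))), 0)
  expect_true(isSymmetric(W))
  # distance sigma*sqrt(2) -> weight exp(-1)
  X2 <- rbind(p = 0, q = sqrt(2))
  W2 <- build_affinity(X2, ranking_config(sigma = 1))
  expect_equal(W2["p", "q"], exp(-1), tolerance = 1e-12)

  Xsame <- rbind(u = c(1, 1), v = c(1, 1), w = c(1, 1))
  expect_error(build_affinity(Xsame), "sigma")
})

test_that("label propagation matches the direct solve and its limits", {
  # 3-node path P - B1 - B2 with unit weights
  W <- matrix(0, 3, 3, dimnames = list(c("P", "B1", "B2"), c("P", "B1", "B2")))
  W["P", "B1"] <- W["B1", "P"] <- 1
  W["B1", "B2"] <- W["B2", "B1"] <- 1
  cfg <- ranking_config(alpha = 0.5, tolerance = 1e-12)
  res <- manifold_rank(W, "P", cfg)
  direct <- manifold_rank_direct(W, "P", cfg)
  expect_equal(res$score[match(names(direct), res$id)], unname(direct),
               tolerance = 1e-8)

  # alpha -> 0: scores collapse to the prior labels
  cfg0 <- ranking_config(alpha = 1e-9)
  r0 <- manifold_rank(W, "P", cfg0)
  expect_equal(r0$score[r0$id == "P"], 1, tolerance = 1e-6)
  expect_equal(sum(r0$score[r0$id != "P"]), 0, tolerance = 1e-6)

  # isolated background node scores exactly 0
  W4 <- rbind(cbind(W, 0), 0)
  dimnames(W4) <- list(c("P", "B1", "B2", "ISO"), c("P", "B1", "B2", "ISO"))
  r4 <- manifold_rank(W4, "P", ranking_config(alpha = 0.5))
  expect_equal(r4$score[r4$id == "ISO"], 0)
  expect_equal(r4$rank[r4$id == "ISO"], max(r4$rank, na.rm = TRUE))

  expect_error(manifold_rank(matrix(c(0, 1, 2, 0), 2, 2), "1"), "symmetric")
  expect_error(manifold_rank(W, character(0)), "positive")
})

test_that("iterative and direct solutions agree on random graphs", {
  withr::with_seed(31, {
    for (rep in 1:5) {
      n <- sample(20:200, 1)
      X <- matrix(rnorm(n * 4), n, 4)
      rownames(X) <- sprintf("n%03d", seq_len(n))
      W <- build_affinity(X)
      pos <- rownames(X)[1:3]
      cfg <- ranking_config(alpha = 0.9, tolerance = 1e-12)
      res <- manifold_rank(W, pos, cfg)
      direct <- manifold_rank_direct(W, pos, cfg)
      expect_equal(res$score[match(names(direct), res$id)], unname(direct),
                   tolerance = 1e-8)
      expect_true(all(res$score >= 0 & res$score <= 1 + 1e-12))
      expect_setequal(res$rank[!res$positive], seq_len(n - 3))
    }
  })
})

test_that("background members of the positives' cluster rank first", {
  withr::with_seed(32, {
    A <- matrix(rnorm(30 * 3), 30, 3)
    B <- matrix(rnorm(30 * 3, mean = 8), 30, 3)
  })
  X <- rbind(A, B)
  rownames(X) <- c(sprintf("a%02d", 1:30), sprintf("b%02d", 1:30))
  # alpha below the default: at alpha near 1 the propagation approaches its
  # degree-driven stationary limit and the cluster contrast washes out on
  # small balanced graphs
  cfg <- ranking_config(alpha = 0.9)
  res <- manifold_rank(build_affinity(X, cfg), sprintf("a%02d", 1:5), cfg)
  bg <- res[!res$positive, ]
  a_ranks <- bg$rank[startsWith(bg$id, "a")]
  b_ranks <- bg$rank[startsWith(bg$id, "b")]
  expect_lt(max(a_ranks), min(b_ranks))
})

test_that("increasing connectivity to positives never lowers a score", {
  withr::with_seed(33, {
    X <- matrix(rnorm(40 * 3), 40, 3)
  })
  rownames(X) <- sprintf("n%02d", 1:40)
  W <- build_affinity(X)
  cfg <- ranking_config(alpha = 0.9)
  base <- manifold_rank(W, "n01", cfg)
  W2 <- W
  W2["n01", "n20"] <- W2["n20", "n01"] <- min(1, W["n01", "n20"] * 3 + 0.2)
  bumped <- manifold_rank(W2, "n01", cfg)
  expect_gte(bumped$score[bumped$id == "n20"],
             base$score[base$id == "n20"])
})

test_that("ranking evaluation counts overlaps and scores them", {
  withr::with_seed(34, X <- matrix(rnorm(30 * 2), 30, 2))
  rownames(X) <- sprintf("n%02d", 1:30)
  res <- manifold_rank(build_affinity(X), c("n01", "n02"))
  bg <- res[!res$positive, ]
  top5 <- bg$id[bg$rank <= 5]
  ev <- evaluate_ranking(res, known_ids = top5, top_n = 5, population_N = 100)
  expect_equal(ev$overlap, 5L)
  ev0 <- evaluate_ranking(res, known_ids = character(0), top_n = 5,
                          population_N = 100)
  expect_equal(ev0$overlap, 0L)
  expect_equal(ev0$p_value, 1)
})
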