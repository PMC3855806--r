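make_expr <- function(case, control, ids = NULL) {
  case <- as.matrix(case)
  control <- as.matrix(control)
  if (is.null(ids)) ids <- sprintf("g%02d", seq_len(nrow(case)))
  mat <- cbind(case, control)
  colnames(mat) <- c(paste0("case_", seq_len(ncol(case))),
                     paste0("control_", seq_len(ncol(control))))
  dplyr::bind_cols(tibble::tibble(gene_id = ids), tibble::as_tibble(mat))
}

test_that("fold change is the ratio of sums with the stated symmetries", {
  e <- make_expr(matrix(3, 2, 4), matrix(2, 2, 4))
  expect_equal(fold_change(e)$fold_change, c(1.5, 1.5))
  e2 <- make_expr(matrix(c(2, 4), 1, 2), matrix(c(1, 1), 1, 2))
  expect_equal(fold_change(e2)$fold_change, 3)
  expect_equal(fold_change(make_expr(matrix(5, 1, 3),
                                     matrix(5, 1, 3)))$fold_change, 1)

  # swapping case and control inverts the ratio-of-sums fold change
  withr::with_seed(41, {
    case <- matrix(rlnorm(30), 5, 6)
    control <- matrix(rlnorm(30), 5, 6)
  })
  fc_fwd <- fold_change(make_expr(case, control))$fold_change
  fc_rev <- fold_change(make_expr(control, case))$fold_change
  expect_equal(fc_fwd, 1 / fc_rev, tolerance = 1e-12)

  # mean-of-ratios alternative
  expect_equal(fold_change(e2, method = "mean_of_ratios")$fold_change, 3)
  expect_error(fold_change(make_expr(matrix(1, 1, 2), matrix(0, 1, 2))),
               "positive")
})

test_that("paired t-test matches stats::t.test and handles degeneracy", {
  withr::with_seed(42, {
    case <- matrix(rlnorm(200, 3), 20, 10)
    control <- matrix(rlnorm(200, 3), 20, 10)
  })
  e <- make_expr(case, control)
  got <- paired_ttest(e)
  for (i in c(1, 7, 20)) {
    ref <- stats::t.test(case[i, ], control[i, ], paired = TRUE)
    expect_equal(got$p_value[i], ref$p.value, tolerance = 1e-10)
    expect_equal(got$statistic[i], unname(ref$statistic), tolerance = 1e-10)
  }
  # all differences zero -> p = 1; constant nonzero shift -> smallest double
  e_deg <- make_expr(rbind(c(1, 2, 3), c(2, 3, 4)),
                     rbind(c(1, 2, 3), c(1, 2, 3)))
  pd <- paired_ttest(e_deg)
  expect_equal(pd$p_value[1], 1)
  expect_equal(pd$p_value[2], .Machine$double.xmin)
  expect_error(paired_ttest(make_expr(matrix(1, 2, 1), matrix(1, 2, 1))),
               "2 sample pairs")
})

test_that("null paired p-values are approximately uniform", {
  # normal paired differences: the t reference distribution is exact
  withr::with_seed(43, {
    control <- matrix(rlnorm(1000 * 8, 5), 1000, 8)
    case <- control + matrix(rnorm(1000 * 8), 1000, 8)
    case <- pmax(case, 1e-3)
  })
  p <- paired_ttest(make_expr(case, control))$p_value
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("DEG selection applies the inclusive fold-change rule", {
  fc <- tibble::tibble(gene_id = paste0("g", 1:5),
                       fold_change = c(2.0, 1.2, 0.5, 1.5, 0.7))
  pv <- tibble::tibble(gene_id = paste0("g", 1:5),
                       p_value = c(0.01, 0.01, 0.01, 0.2, 0.01))
  expect_equal(select_deg(fc, pv), c("g1", "g3"))
  # fc exactly 1.5 kept when p passes
  pv$p_value[4] <- 0.01
  expect_equal(select_deg(fc, pv), c("g1", "g3", "g4"))
  # 0.8 is inside (1/1.5, 1.5): dropped regardless of p
  fc$fold_change[2] <- 0.8
  expect_false("g2" %in% select_deg(fc, pv))
})

test_that("hypergeometric pmf and tail match stats and their invariants", {
  # closed cross-check against the reference distribution functions
  withr::with_seed(44, {
    for (rep in 1:50) {
      N <- sample(10:5000, 1)
      S <- sample(0:N, 1)
      n <- sample(0:N, 1)
      s <- sample(0:min(S, n), 1)
      expect_equal(hypergeom_pmf(N, S, n, s),
                   stats::dhyper(s, S, N - S, n), tolerance = 1e-12)
      expect_equal(hypergeom_tail(N, S, n, s),
                   stats::phyper(s - 1, S, N - S, n, lower.tail = FALSE),
                   tolerance = 1e-10)
      # role symmetry of S and n (1e-10: log-gamma cancellation at large N)
      expect_equal(hypergeom_pmf(N, S, n, s), hypergeom_pmf(N, n, S, s),
                   tolerance = 1e-10)
    }
  })
  # normalization over the support
  support <- max(0, 20 - 40):10
  expect_equal(sum(vapply(support, function(s) hypergeom_pmf(50, 10, 20, s),
                          numeric(1))), 1, tolerance = 1e-12)
  expect_equal(hypergeom_pmf(1, 1, 1, 1), 1)
  expect_equal(hypergeom_tail(100, 10, 10, 0), 1)
  expect_error(hypergeom_pmf(100, 10, 10, 11), "min")
  expect_error(hypergeom_pmf(100, 200, 10, 1), "exceed")
})

test_that("candidate intersection respects set logic and rank order", {
  expect_equal(nrow(intersect_candidates("a", "b", "c")), 0)
  expect_equal(intersect_candidates(c("a", "b", "c"), c("b", "c", "d"),
                                    "c")$id, "c")
  # nested sets give the innermost
  expect_setequal(intersect_candidates(c("a", "b", "c"), c("a", "b", "c"),
                                       c("b", "c"))$id, c("b", "c"))
  # ranked ordering
  rk <- tibble::tibble(id = c("a", "b", "c"), rank = c(3L, 1L, 2L),
                       positive = FALSE, score = c(0.1, 0.9, 0.5))
  out <- intersect_candidates(c("a", "b", "c"), c("a", "b", "c"),
                              c("a", "b", "c"), ranking = rk)
  expect_equal(out$id, c("b", "c", "a"))
})

test_that("synthetic DEG recovery at the cohort scale reaches F1 >= 0.9", {
  sp <- synth_spec(n_genes = 1000, m_pairs = 43, n_de = 100,
                   true_fc = 2, noise_sd = 0.3)
  ge <- generate_expression(sp, seed = 7)
  de <- differential_expression(ge$expression)
  tp <- sum(de$de & ge$truth$de)
  fp <- sum(de$de & !ge$truth$de)
  fn <- sum(!de$de & ge$truth$de)
  f1 <- 2 * tp / (2 * tp + fp + fn)
  expect_gte(f1, 0.9)
})
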