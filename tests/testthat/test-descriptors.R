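test_that("composition blocks match hand counts and sum to one", {
  expect_equal(unname(aa_composition("AAAA")["A"]), 1)
  expect_equal(unname(aa_composition("ACDEFGHIKLMNPQRSTVWY")),
               rep(0.05, 20))
  expect_equal(unname(aa_composition("AAC")[c("A", "C")]), c(2 / 3, 1 / 3))
  expect_error(aa_composition(""))

  expect_equal(unname(dipeptide_composition("AA")["AA"]), 1)
  v <- dipeptide_composition("ACA")
  expect_equal(unname(v[c("AC", "CA")]), c(0.5, 0.5))
  expect_error(dipeptide_composition("A"))

  withr::with_seed(3, {
    for (s in vapply(sample(10:300, 5), random_sequence, character(1))) {
      expect_equal(sum(aa_composition(s)), 1, tolerance = 1e-12)
      expect_equal(sum(dipeptide_composition(s)), 1, tolerance = 1e-12)
    }
  })
})

test_that("standardized scales have mean 0 and population sd 1", {
  for (s in default_scales()) {
    expect_equal(mean(s), 0, tolerance = 1e-12)
    expect_equal(sqrt(mean((s - mean(s))^2)), 1, tolerance = 1e-12)
  }
  for (g in default_groupings()) {
    expect_setequal(unlist(g), AA20)
    expect_equal(length(unlist(g)), 20)
  }
})

test_that("two-residue and degenerate autocorrelation identities hold", {
  sc <- default_scales()$hydrophobicity
  expect_equal(autocorrelation("AC", sc, "moran", 1), -1)
  expect_equal(autocorrelation("AC", sc, "geary", 1), 1)
  expect_equal(autocorrelation("AAAA", sc, "moran", 1), 0)
  expect_equal(autocorrelation("AAAA", sc, "geary", 1), 0)
  expect_error(autocorrelation("ACDE", sc, "moran", 4), "lag")
})

test_that("autocorrelation matches the direct-summation oracle", {
  scales <- default_scales()
  withr::with_seed(17, {
    for (rep in 1:20) {
      s <- random_sequence(50)
      sc <- scales[[sample(length(scales), 1)]]
      for (m in c("moreau_broto", "moran", "geary")) {
        for (d in 1:5) {
          expect_equal(autocorrelation(s, sc, m, d),
                       oracle_autocorr(s, sc, m, d), tolerance = 1e-12)
        }
      }
    }
  })
})

test_that("CTD follows the stated composition/transition/distribution rules", {
  g <- default_groupings()$charge  # classes: KR | neutral | DE
  v <- ctd("KKKK", g)
  expect_equal(unname(v[1:3]), c(1, 0, 0))
  expect_equal(unname(v[4:6]), c(0, 0, 0))
  expect_equal(unname(v[7:11]), c(0.25, 0.25, 0.5, 0.75, 1))
  expect_equal(unname(v[12:21]), rep(0, 10))

  # alternating class 1 / class 2: every adjacent pair is a 1-2 transition
  v2 <- ctd("KAKA", g)
  expect_equal(unname(v2["trans.g12"]), 1)

  v3 <- ctd("K", g)
  expect_equal(unname(v3[1:6]), c(1, 0, 0, 0, 0, 0))
})

test_that("physicochemical summaries follow their definitions", {
  expect_equal(unname(physico_summary("K")["net_charge"]), 1)
  expect_equal(unname(physico_summary("DE")["net_charge"]), -2)
  expect_equal(unname(physico_summary("KRHDE")["net_charge"]), 0.1)
  g10 <- strrep("G", 10)
  expect_equal(unname(physico_summary(g10)["mean_hydrophobicity"]), -0.4)
  expect_equal(unname(physico_summary(g10)["length"]), 10)
})

test_that("disorder profile separates hydrophobic from charged chains", {
  expect_equal(unname(disorder_profile(strrep("I", 60))["disordered_fraction"]), 0)
  expect_equal(unname(disorder_profile(strrep("E", 60))["disordered_fraction"]), 1)
  withr::with_seed(5, {
    for (s in vapply(rep(80, 5), random_sequence, character(1))) {
      f <- disorder_profile(s)["disordered_fraction"]
      expect_gte(f, 0)
      expect_lte(f, 1)
    }
  })
  expect_error(disorder_profile("ACDE", window = 10), "odd")
})

test_that("secondary-structure fractions are a valid composition", {
  expect_equal(unname(ss_composition(strrep("A", 8))["helix"]), 1)
  expect_equal(unname(ss_composition(strrep("V", 8))["sheet"]), 1)
  withr::with_seed(6, {
    for (s in vapply(rep(100, 5), random_sequence, character(1))) {
      expect_equal(sum(ss_composition(s)), 1, tolerance = 1e-12)
    }
  })
})

test_that("radius scaling and TAT motif behave as specified", {
  expect_equal(radius_estimate(1), 2.2)
  expect_equal(radius_estimate(100), 2.2 * 100^0.38)
  expect_true(all(diff(radius_estimate(1:500)) > 0))

  expect_true(tat_motif("MSRRGFLKAAA"))
  expect_false(tat_motif("MKVLLLAAAGG"))
  far <- paste0(strrep("A", 39), "SRRGFLK")
  expect_false(tat_motif(far))
})

test_that("featurize is deterministic, finite, and has the documented dimension", {
  expect_equal(descriptor_dim(), 1302L)
  withr::with_seed(9, {
    prot <- tibble::tibble(id = sprintf("X%02d", 1:6),
                           sequence = vapply(sample(40:120, 6),
                                             random_sequence, character(1)))
  })
  f1 <- featurize(prot)
  f2 <- featurize(prot)
  expect_identical(f1, f2)
  expect_equal(dim(f1), c(6L, 1303L))
  expect_true(all(is.finite(as.matrix(f1[, -1]))))
  expect_equal(f1$id, prot$id)

  one <- featurize(prot[3, ])
  expect_equal(nrow(one), 1L)
  expect_equal(as.matrix(one[, -1]), as.matrix(f1[3, -1]), ignore_attr = TRUE)

  # short sequence: infeasible lags zero-filled with a warning naming it
  short <- tibble::tibble(id = "S1", sequence = random_sequence(10))
  expect_warning(fs <- featurize(short), "S1")
  ac_cols <- grep("lag2[0-9]", names(fs))
  expect_true(all(as.matrix(fs[, ac_cols]) == 0))
})
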