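test_that("Weir-Cockerham theta is exact at fixation and undefined when monomorphic", {
  fixed <- weir_cockerham_fst(snp_counts(c(20, 0, 0), c(0, 0, 20)))
  expect_equal(fixed$theta, 1)
  expect_equal(fixed$a, 0.5)
  expect_equal(fixed$b, 0)
  expect_equal(fixed$c, 0)

  mono <- weir_cockerham_fst(snp_counts(c(15, 0, 0), c(25, 0, 0)))
  expect_false(mono$defined)
  expect_true(is.na(mono$theta))
})

test_that("theta matches an independent transcription of the component formulas", {
  set.seed(101)
  for (i in 1:200) {
    counts <- random_snp_counts()
    got <- weir_cockerham_fst(counts)
    want <- wc_fst_oracle(counts)
    if (!want$defined) {
      expect_false(got$defined)
    } else {
      expect_equal(got$theta, want$theta, tolerance = 1e-12)
      expect_equal(got$a, want$a, tolerance = 1e-12)
      expect_equal(got$b, want$b, tolerance = 1e-12)
      expect_equal(got$c, want$c, tolerance = 1e-12)
      expect_lte(got$theta, 1)
    }
  }
})

test_that("theta is invariant to population-label and allele-label swaps", {
  set.seed(102)
  for (i in 1:50) {
    counts <- random_snp_counts()
    base <- weir_cockerham_fst(counts)$theta
    expect_equal(weir_cockerham_fst(counts[2:1, ])$theta, base)
    expect_equal(weir_cockerham_fst(counts[, 3:1])$theta, base)
  }
})

test_that("Fisher allelic test matches enumeration and known closed forms", {
  # complete separation of 10 vs 10 alleles: p = 2 / choose(20, 10)
  p_sep <- fisher_allelic_test(snp_counts(c(5, 0, 0), c(0, 0, 5)))
  expect_equal(p_sep, 2 / choose(20, 10), tolerance = 1e-10)
  expect_equal(p_sep, 1.082e-5, tolerance = 1e-3)

  set.seed(103)
  for (i in 1:200) {
    counts <- random_snp_counts(max_n = 15)   # margins <= 30 alleles
    a <- 2 * counts[1, 1] + counts[1, 2]; b <- 2 * counts[1, 3] + counts[1, 2]
    c2 <- 2 * counts[2, 1] + counts[2, 2]; d <- 2 * counts[2, 3] + counts[2, 2]
    expect_equal(fisher_allelic_test(counts), fisher_enum_oracle(a, b, c2, d),
                 tolerance = 1e-10)
    # independent cross-check against the standard implementation
    expect_equal(fisher_allelic_test(counts),
                 stats::fisher.test(matrix(c(a, c2, b, d), 2))$p.value,
                 tolerance = 1e-7)
  }
})

test_that("Fisher allelic test returns 1 on exchangeable and zero-margin tables", {
  expect_equal(fisher_allelic_test(snp_counts(c(0, 5, 5), c(0, 5, 5))), 1)
  expect_equal(fisher_allelic_test(snp_counts(c(5, 0, 0), c(7, 0, 0))), 1)
})

test_that("HWE exact test matches enumeration for n <= 50", {
  expect_equal(hwe_exact_test(10, 0, 0), 1)
  expect_equal(hwe_exact_test(0, 10, 0), hwe_enum_oracle(0, 10, 0),
               tolerance = 1e-12)
  set.seed(104)
  for (i in 1:200) {
    n <- sample(1:50, 1)
    g <- tabulate(rbinom(n, 2, runif(1, 0.05, 0.95)) + 1, 3)
    expect_equal(hwe_exact_test(g[1], g[2], g[3]),
                 hwe_enum_oracle(g[1], g[2], g[3]), tolerance = 1e-10)
    # allele-label symmetry
    expect_equal(hwe_exact_test(g[1], g[2], g[3]),
                 hwe_exact_test(g[3], g[2], g[1]))
  }
})

test_that("Pearson chi-square matches the textbook formula and drops zero margins", {
  flat <- pearson_chi_square(matrix(c(10, 10, 10, 10), 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  diag40 <- pearson_chi_square(matrix(c(20, 0, 0, 20), 2))
  expect_equal(diag40$statistic, 40)
  expect_equal(diag40$df, 1)

  set.seed(105)
  for (i in 1:20) {
    tab <- matrix(rpois(6, 12) + 1, 3, 2)
    got <- pearson_chi_square(tab)
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$df, unname(ref$parameter))
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  }

  tab0 <- rbind(c(5, 3), c(0, 0), c(2, 8))
  expect_warning(res <- pearson_chi_square(tab0), "zero row")
  expect_equal(res$df, 1)
})

test_that("genomic inflation is 1 at the chi-square median and scale-equivariant", {
  expect_equal(genomic_inflation(chi2 = rep(0.4549364, 5)), 1,
               tolerance = 1e-6)
  set.seed(106)
  chi2 <- rchisq(1000, 3)
  expect_equal(genomic_inflation(chi2 = 2 * chi2),
               2 * genomic_inflation(chi2 = chi2))
  p <- runif(10000)
  expect_equal(genomic_inflation(p = p), 1, tolerance = 0.05)
  expect_error(genomic_inflation(chi2 = numeric(0)), "no finite")
})

test_that("Bonferroni threshold is alpha over the test count", {
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 2), 0.025)
  expect_equal(signif(bonferroni_threshold(0.05, 46563), 3), 1.07e-6)
})

test_that("tracks: fixed difference gives theta 1, X gets no Fst, Fisher covers X", {
  g <- cbind(c(rep(0L, 10), rep(2L, 10)),
             rep(c(0L, 1L, 2L, 1L), 5),
             rep(c(0L, 1L, 2L, 1L), 5))
  ds <- toy_dataset(g, rep(c("A", "B"), each = 10),
                    chrom = c("1", "1", "X"), pos = c(1000L, 2000L, 1000L))
  ft <- fst_track(ds)
  expect_equal(ft$value[1], 1)
  expect_true(is.na(ft$value[3]))
  fi <- fisher_track(ds)
  expect_true(all(is.finite(fi$value)))
  expect_lt(fi$value[1], 1e-8)
})

test_that("tracks agree with the per-marker scalar operations", {
  set.seed(107)
  sim <- simulate_dataset(sim_config(n_pop_a = 12, n_pop_b = 18, n_chrom = 2,
                                     markers_per_chrom = 60,
                                     f_background = 0.1,
                                     missing_rate = 0.05, seed = 107))
  ds <- sim$dataset
  ft <- fst_track(ds)
  fi <- fisher_track(ds)
  for (j in sample(ncol(ds$genotypes), 20)) {
    gA <- ds$genotypes[ds$samples$population == "A", j]
    gB <- ds$genotypes[ds$samples$population == "B", j]
    counts <- snp_counts(tabulate(gA[!is.na(gA)] + 1, 3),
                         tabulate(gB[!is.na(gB)] + 1, 3))
    want <- weir_cockerham_fst(counts)
    if (want$defined) expect_equal(ft$value[j], want$theta)
    expect_equal(fi$value[j], fisher_allelic_test(counts))
  }
})

test_that("mean theta is near zero on a panmictic split", {
  set.seed(108)
  sim <- simulate_dataset(sim_config(n_pop_a = 50, n_pop_b = 50, n_chrom = 2,
                                     markers_per_chrom = 1000,
                                     f_background = 0, missing_rate = 0,
                                     seed = 108))
  ft <- fst_track(sim$dataset)
  expect_lt(abs(mean(ft$value, na.rm = TRUE)), 0.01)
})
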