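test_that("degenerate and invalid inputs are handled", {
  mono <- cbind(rep(1L, 8), rep(1L, 8))
  p <- hwe_exact_test(mono, 99, seed = 1)
  expect_equal(as.numeric(p), 1)
  expect_true(attr(p, "degenerate"))
  allna <- cbind(c(NA, NA), c(NA, NA))
  expect_error(hwe_exact_test(allna, 99, seed = 1), "missing")
  expect_error(hwe_exact_test(cbind(1L, 2L), 99, seed = 1), "at least 2")
})

test_that("biallelic enumeration matches the brute-force re-pairing oracle", {
  set.seed(14)
  for (rep in 1:8) {
    n <- sample(4:10, 1)
    g <- draw_hwe_locus(n, c(0.5, 0.5), F = runif(1, 0, 0.6))
    if (length(unique(c(g))) < 2) next
    p_pkg <- hwe_exact_test(g, method = "enumeration")
    p_oracle <- enumerate_het_pvalue(c(g[, 1], g[, 2]), sum(g[, 1] != g[, 2]))
    expect_equal(as.numeric(p_pkg), p_oracle, tolerance = 1e-12)
  }
})

test_that("Monte-Carlo p-values estimate the enumerated target", {
  set.seed(15)
  g <- draw_hwe_locus(10, c(0.4, 0.6), F = 0.5)
  p_exact <- as.numeric(hwe_exact_test(g, method = "enumeration"))
  p_mc <- as.numeric(hwe_exact_test(g, n_permutations = 20000, seed = 99))
  expect_equal(p_mc, p_exact, tolerance = 4 * sqrt(p_exact * (1 - p_exact) / 20000) + 2e-4)
  # determinism in the seed
  expect_identical(hwe_exact_test(g, 999, seed = 7), hwe_exact_test(g, 999, seed = 7))
})

test_that("p-values are super-uniform under the null and relabel invariant", {
  set.seed(16)
  n_loci <- 400
  rej <- 0
  for (i in 1:n_loci) {
    g <- draw_hwe_locus(30, prop.table(rgamma(5, 1)))
    if (length(unique(c(g))) < 2) next
    if (as.numeric(hwe_exact_test(g, 499, seed = i)) <= 0.05) rej <- rej + 1
  }
  # the discrete one-sided test never over-rejects (binomial 3.5 sigma slack)
  expect_lt(rej / n_loci, 0.05 + 3.5 * sqrt(0.05 * 0.95 / n_loci))

  g <- draw_hwe_locus(20, c(0.3, 0.3, 0.4))
  relab <- matrix(c(3L, 1L, 2L)[g], ncol = 2)
  expect_equal(as.numeric(hwe_exact_test(g, 999, seed = 4)),
               as.numeric(hwe_exact_test(relab, 999, seed = 4)))
})

test_that("bonferroni implements the alpha/m threshold rule", {
  d <- bonferroni(c(0.001, 0.04), alpha = 0.05)
  expect_identical(as.logical(d), c(TRUE, FALSE))
  expect_equal(attr(d, "threshold"), 0.025)
  # m = 1 reduces to the uncorrected test
  expect_true(as.logical(bonferroni(0.04, 0.05, m = 1)))
  # p >= alpha is never rejected for any family size
  for (m in c(1, 2, 10)) expect_false(any(bonferroni(c(0.05, 0.2), 0.05, m = m)))
  expect_length(bonferroni(numeric(0)), 0)
})

test_that("linkage test flags a duplicated locus and respects independence", {
  set.seed(18)
  ga <- draw_hwe_locus(20, c(0.4, 0.3, 0.3))
  p_dup <- ld_test(ga, ga, n_permutations = 999, seed = 3)
  expect_lte(as.numeric(p_dup), 2 / 1000)

  # monomorphic locus is degenerate
  mono <- cbind(rep(1L, 20), rep(1L, 20))
  expect_true(attr(ld_test(ga, mono, 99, seed = 1), "degenerate"))

  # type-I behaviour on independent loci (wide bounds, small n of pairs)
  rej <- 0
  n_pairs <- 300
  for (i in 1:n_pairs) {
    a <- draw_hwe_locus(25, prop.table(rgamma(4, 1)))
    b <- draw_hwe_locus(25, prop.table(rgamma(4, 1)))
    p <- suppressWarnings(ld_test(a, b, 299, seed = i))
    if (!attr(p, "degenerate") && as.numeric(p) <= 0.05) rej <- rej + 1
  }
  expect_gt(rej / n_pairs, 0.01)
  expect_lt(rej / n_pairs, 0.09)
})

test_that("a planted heterozygote-deficit locus is dropped, clean loci kept", {
  set.seed(19)
  n_pop <- 13
  n_per <- 24
  L <- 14
  a1 <- a2 <- matrix(NA_integer_, n_pop * n_per, L)
  pops <- rep(sprintf("p%02d", 1:n_pop), each = n_per)
  for (pop in 1:n_pop) {
    rows <- which(pops == sprintf("p%02d", pop))
    for (l in 1:L) {
      # locus 14 has a strong deficit in 8 of 13 populations
      Fcoef <- if (l == 14L && pop <= 8) 0.85 else 0
      g <- draw_hwe_locus(n_per, prop.table(rgamma(4, 1) + 0.3), F = Fcoef)
      a1[rows, l] <- g[, 1]; a2[rows, l] <- g[, 2]
    }
  }
  gt <- genotype_table(a1, a2, sprintf("i%03d", seq_along(pops)), pops,
                       sprintf("loc%02d", 1:L))
  # Monte-Carlo resolution must sit below the Bonferroni threshold
  # (0.05 / 182 tests), so the default-scale 9999 permutations are needed
  rep <- qc_report(gt, n_permutations = 9999, seed = 55, ld = FALSE)
  fl <- flag_loci(rep, max_failing_populations = 5)
  expect_identical(fl$dropped, "loc14")
  expect_length(fl$retained, 13L)
  expect_false("loc14" %in% fl$retained)

  # all-clean report keeps everything
  rep2 <- rep
  rep2$reject[] <- FALSE
  fl2 <- flag_loci(rep2)
  expect_length(fl2$retained, 14L)
  expect_length(fl2$dropped, 0L)
})
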