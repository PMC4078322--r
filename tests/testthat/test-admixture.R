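test_that("K = 1 forces unit ancestry and rows always sum to one", {
  ds <- simulate_zone(zone_config(n_per_site = 4, seed = 2))
  f1 <- fit_admixture(ds$genotypes, admixture_config(K = 1, burn_in = 10,
                                                     n_iter = 50, seed = 1))
  expect_true(all(f1$Q == 1))
  f2 <- fit_admixture(ds$genotypes, admixture_config(K = 3, burn_in = 100,
                                                     n_iter = 400, seed = 1))
  expect_equal(unname(rowSums(f2$Q)), rep(1, nrow(f2$Q)), tolerance = 1e-9)
  expect_true(all(f2$Q >= 0 & f2$Q <= 1))
  expect_error(admixture_config(K = 0), "K")
})

test_that("fully private alleles separate the parental pools", {
  set.seed(4)
  pools <- jaycline:::parental_pools(13, 8, 1)
  ga <- draw_pool_genotypes(pools$coastal, 40)
  gb <- draw_pool_genotypes(pools$interior, 40)
  gt <- genotype_table(rbind(ga$a1, gb$a1), rbind(ga$a2, gb$a2),
                       sprintf("i%02d", 1:80),
                       rep(c("coastal", "interior"), each = 40),
                       sprintf("L%02d", 1:13))
  fit <- fit_admixture(gt, admixture_config(burn_in = 500, n_iter = 2000,
                                            seed = 11))
  # orient cluster 1 on the coastal pool
  q1 <- fit$Q[, 1]
  if (mean(q1[1:40]) < 0.5) q1 <- 1 - q1
  expect_true(all(q1[1:40] >= 0.95))
  expect_true(all(q1[41:80] <= 0.05))
})

test_that("constructed F1s sit near even ancestry", {
  set.seed(6)
  pools <- jaycline:::parental_pools(13, 8, 1)
  ga <- draw_pool_genotypes(pools$coastal, 30)
  gb <- draw_pool_genotypes(pools$interior, 30)
  # F1: one allele per locus from each pool
  f1_a <- draw_pool_genotypes(pools$coastal, 12)$a1
  f1_b <- draw_pool_genotypes(pools$interior, 12)$a1
  gt <- genotype_table(rbind(ga$a1, gb$a1, f1_a), rbind(ga$a2, gb$a2, f1_b),
                       sprintf("i%02d", 1:72),
                       c(rep("pA", 30), rep("pB", 30), rep("F1", 12)),
                       sprintf("L%02d", 1:13))
  fit <- fit_admixture(gt, admixture_config(burn_in = 500, n_iter = 3000,
                                            seed = 21))
  qf1 <- fit$Q[61:72, 1]
  expect_true(all(abs(qf1 - 0.5) <= 0.1))
})

test_that("missing calls are tolerated and do not break normalisation", {
  ds <- simulate_zone(zone_config(n_per_site = 6, seed = 13))
  gt <- ds$genotypes
  set.seed(1)
  drop <- sample(length(gt$a1), length(gt$a1) %/% 10)
  gt$a1[drop] <- NA
  gt$a2[drop] <- NA
  fit <- fit_admixture(gt, admixture_config(burn_in = 200, n_iter = 800,
                                            seed = 3))
  expect_equal(unname(rowSums(fit$Q)), rep(1, nrow(fit$Q)), tolerance = 1e-9)
})

test_that("label alignment undoes column permutations", {
  set.seed(8)
  q <- matrix(runif(40), ncol = 2)
  q <- q / rowSums(q)
  swapped <- q[, 2:1]
  out <- align_labels(list(q, swapped))
  expect_equal(out[[2]], q, ignore_attr = TRUE)
  # identical runs align to identity
  out3 <- align_labels(list(q, q, q))
  expect_equal(out3[[3]], q)
  # alignment can only reduce the disagreement at K = 2
  noisy <- pmin(pmax(1 - q + matrix(rnorm(40, 0, 0.02), ncol = 2), 0), 1)
  before <- sum(abs(noisy - q))
  after <- sum(abs(align_labels(list(q, noisy))[[2]] - q))
  expect_lte(after, before)
  expect_error(align_labels(list(q, matrix(1, 3, 2))), "share")
})

test_that("successive splitting recovers a planted hierarchical partition", {
  skip_if_not_installed("mclust")
  set.seed(9)
  # five pools with fully private allele blocks: 10 alleles, two per pool
  L <- 12
  freq <- lapply(1:5, function(g) {
    f <- matrix(0, L, 10)
    f[, (2 * g - 1):(2 * g)] <- 0.5
    f
  })
  n_per <- 14
  a1 <- do.call(rbind, lapply(freq, function(f) draw_pool_genotypes(f, n_per)$a1))
  a2 <- do.call(rbind, lapply(freq, function(f) draw_pool_genotypes(f, n_per)$a2))
  truth <- rep(1:5, each = n_per)
  gt <- genotype_table(a1, a2, sprintf("i%03d", seq_along(truth)),
                       sprintf("pop%d", truth), sprintf("L%02d", 1:L))
  tree <- successive_split(gt, admixture_config(burn_in = 300, n_iter = 1200,
                                                seed = 77))
  leaves <- split_leaves(tree)
  member <- integer(length(truth))
  for (i in seq_along(leaves))
    member[match(leaves[[i]], gt$individuals)] <- i
  expect_equal(length(leaves), 5L)
  expect_equal(mclust::adjustedRandIndex(member, truth), 1)
})

test_that("a homogeneous population is a leaf", {
  set.seed(10)
  f <- matrix(1 / 6, 10, 6)
  g <- draw_pool_genotypes(f, 40)
  gt <- genotype_table(g$a1, g$a2, sprintf("i%02d", 1:40), rep("one", 40),
                       sprintf("L%02d", 1:10))
  tree <- successive_split(gt, admixture_config(burn_in = 300, n_iter = 1200,
                                                seed = 5))
  expect_null(tree$children)
  # too-small nodes stop immediately
  tiny <- jaycline:::subset_individuals(gt, 1:3)
  leaf <- successive_split(tiny, admixture_config(seed = 1))
  expect_null(leaf$children)
  expect_null(leaf$q)
})

test_that("site-mean ancestry is the arithmetic mean with sample variance", {
  q <- matrix(c(0.2, 0.8, 0.8, 0.2), ncol = 2)
  out <- site_mean_q(q, c("s1", "s1"), focal_cluster = 1)
  expect_equal(out$mean_q, 0.5)
  expect_equal(out$var_q, 0.18)
  out2 <- site_mean_q(matrix(c(1, 1, 0, 0), ncol = 2), c("a", "a"))
  expect_equal(out2$mean_q, 1)
  expect_error(site_mean_q(q, "s1"), "cover")
})

test_that("posterior summaries are invariant to individual order", {
  set.seed(20)
  pools <- jaycline:::parental_pools(13, 8, 0.9)
  ga <- draw_pool_genotypes(pools$coastal, 25)
  gb <- draw_pool_genotypes(pools$interior, 25)
  gt <- genotype_table(rbind(ga$a1, gb$a1), rbind(ga$a2, gb$a2),
                       sprintf("i%02d", 1:50), rep(c("a", "b"), each = 25),
                       sprintf("L%02d", 1:13))
  perm <- sample(50)
  gt_p <- jaycline:::subset_individuals(gt, perm)
  cfg <- admixture_config(burn_in = 500, n_iter = 4000, seed = 31)
  f1 <- fit_admixture(gt, cfg)
  f2 <- fit_admixture(gt_p, cfg)
  q2 <- align_labels(list(f1$Q, f2$Q[match(gt$individuals, gt_p$individuals), ]))[[2]]
  # one shared random stream means draws differ, but the posterior means
  # must agree up to Monte-Carlo error
  expect_lt(max(abs(q2 - f1$Q)), 0.06)
})

test_that("identical parental pools are unresolvable (negative control)", {
  ds <- simulate_zone(zone_config(n_per_site = 10, divergence = 0, seed = 51))
  fit <- fit_admixture(ds$genotypes,
                       admixture_config(burn_in = 500, n_iter = 4000, seed = 52))
  # with nothing to separate, posterior-mean ancestry hugs symmetry
  expect_lt(mean(abs(fit$Q[, 1] - 0.5)), 0.15)
  expect_lt(abs(mean(fit$Q[, 1]) - 0.5), 0.1)
})
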