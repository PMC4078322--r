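test_that("AICc formula and guards", {
  expect_equal(aicc(-10, 2, 13), 25.2)
  expect_equal(aicc(-7, 0, 13), 14)
  expect_error(aicc(-10, 12, 13), "n_obs")
  # correction is positive and vanishes with n
  for (k in 1:4) {
    expect_gt(aicc(-10, k, 13), -2 * -10 + 2 * k - 1e-12)
    expect_equal(aicc(-10, k, 1e7), -2 * -10 + 2 * k, tolerance = 1e-4)
  }
})

test_that("fit recovers a simulated cline and matches the grid-search oracle", {
  ds <- mt_sites_from_zone(seed = 7)
  fit <- suppressWarnings(
    fit_mh(ds$sites, data_kind = "mt_frequency", seed = 7))
  ci_w <- ci_2ll(fit, "width")
  ci_c <- ci_2ll(fit, "center")
  expect_true(ci_w[1] <= 131 && 131 <= ci_w[2])
  expect_true(ci_c[1] <= 300 && 300 <= ci_c[2])
  oracle <- grid_ml_fast(ds$sites$distance, ds$sites$k_interior, ds$sites$n)
  expect_lt(abs(fit$max_ll - oracle), 0.5)
  # CI brackets the point estimate for every free parameter
  for (par in fit$free) {
    ci <- ci_2ll(fit, par)
    expect_true(ci[1] <= fit$point_estimate[par] &&
                  fit$point_estimate[par] <= ci[2])
  }
  expect_error(ci_2ll(fit, "delta_L"), "not in this model")
})

test_that("same seed reproduces the fit bit for bit; different seeds differ", {
  ds <- mt_sites_from_zone(seed = 3)
  a <- suppressWarnings(fit_mh(ds$sites, seed = 5, tuning_iters = 2000,
                               chain_iters = 6000, n_chains = 2))
  b <- suppressWarnings(fit_mh(ds$sites, seed = 5, tuning_iters = 2000,
                               chain_iters = 6000, n_chains = 2))
  d <- suppressWarnings(fit_mh(ds$sites, seed = 6, tuning_iters = 2000,
                               chain_iters = 6000, n_chains = 2))
  expect_identical(a$samples, b$samples)
  expect_identical(a$max_ll, b$max_ll)
  expect_false(identical(a$samples, d$samples))
})

test_that("a step transition puts the fitted center between the flanking sites", {
  sites <- tibble::tibble(distance = seq(0, 600, by = 50), n = 30L)
  sites$k_interior <- ifelse(sites$distance <= 250, 0L, 30L)
  fit <- suppressWarnings(fit_mh(sites, seed = 2, tuning_iters = 3000,
                                 chain_iters = 8000, n_chains = 2))
  est <- unname(fit$point_estimate["center"])
  expect_gt(est, 250)
  expect_lt(est, 300)
})

test_that("two-log-likelihood intervals match the Gaussian closed form", {
  # ll(theta) = -(theta - m)^2 / (2 s^2) has its 2-LL points at m +/- 2s
  m <- 10; s <- 1.5
  theta <- seq(m - 5 * s, m + 5 * s, length.out = 20001)
  fake <- structure(list(
    free = "theta", point_estimate = c(theta = m), max_ll = 0,
    ci_2ll = {
      ll <- -(theta - m)^2 / (2 * s^2)
      keep <- ll >= -2
      matrix(range(theta[keep]), 1, 2,
             dimnames = list("theta", c("low", "high")))
    }), class = "cline_fit")
  ci <- ci_2ll(fake, "theta")
  expect_equal(ci[1], m - 2 * s, tolerance = 1e-3)
  expect_equal(ci[2], m + 2 * s, tolerance = 1e-3)
})

test_that("the null model matches the closed-form binomial ML", {
  set.seed(8)
  sites <- tibble::tibble(distance = seq(0, 600, length.out = 13), n = 20L,
                          k_interior = rbinom(13, 20, 0.4))
  nl <- fit_null(sites)
  p_hat <- sum(sites$k_interior) / sum(sites$n)
  expect_equal(nl$p_hat, p_hat)
  expect_equal(nl$max_ll, sum(dbinom(sites$k_interior, sites$n, p_hat, log = TRUE)))
  expect_equal(nl$aicc, -2 * nl$max_ll + 2 + 4 / 11)
})

test_that("model selection prefers the null under no spatial signal", {
  set.seed(21)
  sites <- tibble::tibble(distance = seq(0, 600, length.out = 13), n = 20L,
                          k_interior = rbinom(13, 20, 0.5))
  ms <- model_select(sites, seed = 21, tuning_iters = 2000,
                     chain_iters = 6000, n_chains = 2)
  expect_equal(ms$table$model[1], "null")
  expect_equal(nrow(ms$table), 16L)
})

test_that("reciprocal CI comparison implements both directions", {
  mt <- cline_estimate(131, c(76, 270), "width")
  nuc <- cline_estimate(331, c(145, 678), "width")
  expect_true(compare_clines(mt, nuc)$significantly_different)
  # identical estimates are never significant
  expect_false(compare_clines(mt, mt)$significantly_different)
  # one-sided overlap is not significant under the reciprocal rule
  a <- cline_estimate(100, c(50, 150))
  b <- cline_estimate(200, c(90, 400))   # a inside b's CI, b outside a's
  expect_false(compare_clines(a, b)$significantly_different)
})

test_that("transect projection uses the haversine great circle", {
  sites <- tibble::tibble(site_id = c("a", "b", "c"),
                          latitude = c(40, 39, 39),
                          longitude = c(-120, -120, -120))
  pr <- project_transect(sites)
  expect_equal(pr$distance[1], 0)
  expect_equal(pr$distance[2], 111.19, tolerance = 1e-4)
  expect_equal(pr$distance[3], pr$distance[2])  # duplicated coordinate adds 0
  # reversing the anchor order mirrors the distances
  rev_pr <- project_transect(sites, anchor_order = c("c", "b", "a"))
  total <- max(pr$distance)
  expect_equal(rev_pr$distance, total - rev(pr$distance))
  expect_error(project_transect(tibble::tibble(site_id = "a", latitude = 1,
                                               longitude = 1)), "at least 2")
  bad <- sites; bad$latitude[1] <- 97
  expect_error(project_transect(bad), "coordinates")
})

test_that("split R-hat and ESS behave like their definitions", {
  set.seed(13)
  # iid chains: rhat ~ 1, ess ~ n
  chains <- lapply(1:3, function(i) matrix(rnorm(4000), ncol = 1))
  expect_lt(jaycline:::split_rhat(chains), 1.02)
  expect_gt(jaycline:::sum_ess(chains), 0.5 * 12000)
  # disjoint chains: rhat far above 1
  apart <- lapply(1:3, function(i) matrix(rnorm(4000, mean = i * 50), ncol = 1))
  expect_gt(jaycline:::split_rhat(apart), 2)
  # AR(1) with strong autocorrelation: ess well below n
  ar <- lapply(1:3, function(i)
    matrix(as.numeric(arima.sim(list(ar = 0.95), 4000)), ncol = 1))
  expect_lt(jaycline:::sum_ess(ar), 3000)
})
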