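test_that("sigmoid midpoint, half-width point and scaling limits are exact", {
  p <- cline_params(center = 300, width = 131)
  expect_equal(cline_eval(p, 300), 0.5)
  # at x = c + w/2 the exponent is exactly -2
  expect_equal(cline_eval(p, 365.5), stats::plogis(2), tolerance = 1e-12)
  sc <- cline_params(center = 300, width = 131, p_min = 0.1, p_max = 0.7,
                     scaling = "free")
  expect_equal(cline_eval(sc, -1e7), 0.1, tolerance = 1e-9)
  expect_equal(cline_eval(sc, 1e7), 0.7, tolerance = 1e-9)
})

test_that("invalid parameters are rejected", {
  expect_error(cline_params(center = 300, width = 0), "width")
  expect_error(cline_params(center = 300, width = -5), "width")
  expect_error(cline_params(300, 100, p_min = 0.8, p_max = 0.2), "p_min")
  expect_error(cline_params(300, 100, tau_l = 1.5), "tau_l")
})

test_that("tails join the sigmoid continuously, C1 exactly at tau = 1", {
  # slope matching: one-sided finite differences at the junction
  p <- cline_params(center = 300, width = 131, delta_l = 50, tau_l = 1,
                    delta_r = 50, tau_r = 1, tail = "both")
  h <- 1e-6
  x0 <- 300 - 50
  slope_out <- (cline_eval(p, x0) - cline_eval(p, x0 - h)) / h
  slope_in <- (cline_eval(p, x0 + h) - cline_eval(p, x0)) / h
  expect_equal(slope_out, slope_in, tolerance = 1e-6)
  x1 <- 300 + 50
  slope_in_r <- (cline_eval(p, x1) - cline_eval(p, x1 - h)) / h
  slope_out_r <- (cline_eval(p, x1 + h) - cline_eval(p, x1)) / h
  expect_equal(slope_in_r, slope_out_r, tolerance = 1e-6)

  # continuity at the junctions for random parameter draws
  set.seed(41)
  for (i in 1:25) {
    pp <- cline_params(center = runif(1, 100, 500), width = runif(1, 20, 400),
                       delta_l = runif(1, 0, 150), tau_l = runif(1),
                       delta_r = runif(1, 0, 150), tau_r = runif(1),
                       tail = sample(c("left", "right", "mirror", "both"), 1))
    for (x0 in c(pp$center - pp$delta_l, pp$center + pp$delta_r)) {
      lo <- cline_eval(pp, x0 - 1e-9)
      hi <- cline_eval(pp, x0 + 1e-9)
      expect_equal(lo, hi, tolerance = 1e-7)
    }
  }
})

test_that("the cline is nondecreasing in x for random valid parameters", {
  set.seed(99)
  for (i in 1:30) {
    pm <- sort(runif(2))
    pp <- cline_params(center = runif(1, 0, 600), width = runif(1, 5, 800),
                       delta_l = runif(1, 0, 300), tau_l = runif(1),
                       delta_r = runif(1, 0, 300), tau_r = runif(1),
                       p_min = pm[1], p_max = pm[2],
                       tail = sample(c("none", "left", "right", "mirror", "both"), 1),
                       scaling = "free")
    y <- cline_eval(pp, seq(-500, 1100, length.out = 800))
    expect_true(all(diff(y) >= -1e-12))
  }
})

test_that("mirror tails share delta and tau", {
  p <- cline_params(center = 0, width = 100, delta_l = 30, tau_l = 0.5,
                    tail = "mirror")
  expect_equal(p$delta_r, 30)
  expect_equal(p$tau_r, 0.5)
  expect_equal(cline_eval(p, -80), 1 - cline_eval(p, 80), tolerance = 1e-12)
})

test_that("compiled and R evaluations of the log-likelihood agree", {
  set.seed(7)
  sites <- tibble::tibble(distance = seq(0, 600, length.out = 13),
                          n = rep(20L, 13),
                          k_interior = rbinom(13, 20, seq(0.02, 0.98, length.out = 13)))
  for (i in 1:20) {
    pp <- cline_params(center = runif(1, 100, 500), width = runif(1, 20, 500),
                       delta_l = runif(1, 0, 200), tau_l = runif(1),
                       delta_r = runif(1, 0, 200), tau_r = runif(1),
                       tail = sample(c("none", "left", "right", "mirror", "both"), 1))
    fl <- jaycline:::tail_flags(pp$tail)
    ll_cpp <- jaycline:::cline_loglik_cpp(jaycline:::full_vector(pp),
                                          sites$distance,
                                          as.numeric(sites$k_interior),
                                          as.numeric(sites$n),
                                          as.integer(fl[["left"]]),
                                          as.integer(fl[["right"]]))
    expect_equal(cline_loglik(pp, sites), ll_cpp, tolerance = 1e-12)
  }
})

test_that("log-likelihood matches hand and brute-force sums", {
  # single site, n = 2, k = 1, p = 0.5: ln(2 * 0.25)
  one <- tibble::tibble(distance = 300, n = 2L, k_interior = 1L)
  p <- cline_params(center = 300, width = 100)
  expect_equal(cline_loglik(p, one), log(0.5), tolerance = 1e-12)

  # 13-site dataset: term-by-term independent summation via lchoose
  set.seed(11)
  sites <- tibble::tibble(distance = seq(0, 600, length.out = 13),
                          n = rep(25L, 13),
                          k_interior = rbinom(13, 25, seq(0.05, 0.95, length.out = 13)))
  pp <- cline_params(center = 280, width = 150)
  pr <- pmin(pmax(cline_eval(pp, sites$distance), 1e-9), 1 - 1e-9)
  oracle <- sum(lchoose(sites$n, sites$k_interior) +
                  sites$k_interior * log(pr) +
                  (sites$n - sites$k_interior) * log(1 - pr))
  expect_equal(cline_loglik(pp, sites), oracle, tolerance = 1e-10)

  # site order invariance
  shuf <- sites[sample(13), ]
  expect_equal(cline_loglik(pp, shuf), cline_loglik(pp, sites))

  # no parameter beats the saturated fit
  sat <- sum(dbinom(sites$k_interior, sites$n, sites$k_interior / sites$n, log = TRUE))
  expect_lte(cline_loglik(pp, sites), sat)
})

test_that("q_mean data use rounded effective successes", {
  sites <- tibble::tibble(distance = c(0, 300, 600), n = c(10L, 10L, 10L),
                          mean_q = c(0.04, 0.52, 0.97))
  p <- cline_params(center = 300, width = 200)
  pr <- pmin(pmax(cline_eval(p, sites$distance), 1e-9), 1 - 1e-9)
  expect_equal(cline_loglik(p, sites, "q_mean"),
               sum(dbinom(round(sites$n * sites$mean_q), sites$n, pr, log = TRUE)))
})
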