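#' Corrected Akaike information criterion
#'
#' `AICc = -2 maxLL + 2k + 2k(k+1) / (n_obs - k - 1)`. The number of
#' observations is the number of sampling localities, not individuals.
#'
#' @param max_ll Maximum log-likelihood.
#' @param k_params Number of free parameters.
#' @param n_obs Number of observations (sites).
#' @return AICc value.
#' @export
aicc <- function(max_ll, k_params, n_obs) {
  if (n_obs <= k_params + 1)
    stop("AICc undefined: n_obs must exceed k_params + 1", call. = FALSE)
  -2 * max_ll + 2 * k_params + 2 * k_params * (k_params + 1) / (n_obs - k_params - 1)
}

# Free parameter names for a tail/scaling combination. The mirrored model
# shares one delta and one tau across both sides.
model_free_params <- function(tail, scaling) {
  fp <- c("center", "width")
  fp <- c(fp, switch(tail,
    none = character(),
    left = c("delta_L", "tau_L"),
    right = c("delta_R", "tau_R"),
    mirror = c("delta", "tau"),
    both = c("delta_L", "tau_L", "delta_R", "tau_R")
  ))
  if (scaling == "free") fp <- c(fp, "p_min", "p_max")
  fp
}

# Linear map from free parameters into the 8-slot full vector, plus the base
# (fixed) values and box bounds derived from the transect extent.
model_spec <- function(tail, scaling, x, obs_freq) {
  free <- model_free_params(tail, scaling)
  p <- length(free)
  span <- max(x) - min(x)
  base <- c(0, 0, 0, 1, 0, 1, 0, 1)
  if (scaling == "fixed_observed") {
    base[7] <- min(obs_freq)
    base[8] <- max(obs_freq)
  }
  if (scaling == "free") base[7:8] <- 0  # both slots are free parameters
  slot_of <- c(center = 1, width = 2, delta_L = 3, tau_L = 4,
               delta_R = 5, tau_R = 6, p_min = 7, p_max = 8)
  map <- matrix(0, 8, p, dimnames = list(NULL, free))
  lower <- upper <- numeric(p)
  for (j in seq_len(p)) {
    nm <- free[j]
    if (nm == "delta") {
      map[c(3, 5), j] <- 1
    } else if (nm == "tau") {
      map[c(4, 6), j] <- 1
    } else {
      map[slot_of[[nm]], j] <- 1
    }
    bnd <- switch(nm,
      center = c(min(x) - span / 2, max(x) + span / 2),
      width = c(1e-6, 2 * span),
      delta = , delta_L = , delta_R = c(0, span),
      tau = , tau_L = , tau_R = c(0, 1),
      p_min = , p_max = c(0, 1)
    )
    lower[j] <- bnd[1]; upper[j] <- bnd[2]
  }
  # inactive base slots: delta 0 / tau 1 so the full vector is always valid
  fl <- tail_flags(tail)
  list(tail = tail, scaling = scaling, free = free, k = p, map = map,
       base = base, lower = lower, upper = upper,
       left_tail = as.integer(fl[["left"]]), right_tail = as.integer(fl[["right"]]))
}

spec_to_params <- function(spec, theta) {
  full <- spec$base + as.numeric(spec$map %*% theta)
  cline_params(center = full[1], width = full[2],
               delta_l = full[3], tau_l = min(max(full[4], 0), 1),
               delta_r = full[5], tau_r = min(max(full[6], 0), 1),
               p_min = full[7], p_max = full[8],
               tail = spec$tail, scaling = spec$scaling)
}

# Nelder-Mead refinement of the maximum-likelihood point from the best
# sampled draw (bounds enforced by penalty); falls back to the draw itself
# if the refinement does not improve the likelihood.
polish_ml <- function(theta, spec, dat) {
  nll <- function(th) {
    if (any(th < spec$lower) || any(th > spec$upper)) return(1e10)
    full <- spec$base + as.numeric(spec$map %*% th)
    if (full[7] > full[8]) return(1e10)
    ll <- cline_loglik_cpp(full, dat$x, dat$k, dat$n,
                           spec$left_tail, spec$right_tail)
    if (!is.finite(ll)) return(1e10) else -ll
  }
  opt <- tryCatch(
    stats::optim(theta, nll, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12)),
    error = function(e) NULL)
  ll0 <- -nll(theta)
  if (!is.null(opt) && -opt$value > ll0) {
    out <- opt$par
    names(out) <- spec$free
    list(theta = out, ll = -opt$value)
  } else {
    list(theta = theta, ll = ll0)
  }
}

draw_start <- function(spec, x, k, n, max_tries = 100) {
  for (i in seq_len(max_tries)) {
    theta <- runif(spec$k, spec$lower, spec$upper)
    full <- spec$base + as.numeric(spec$map %*% theta)
    if (full[7] > full[8]) next
    ll <- cline_loglik_cpp(full, x, k, n, spec$left_tail, spec$right_tail)
    if (is.finite(ll)) return(theta)
  }
  stop("could not find a finite-likelihood start in 100 draws", call. = FALSE)
}

#' Fit a cline model by Metropolis-Hastings sampling
#'
#' Random-walk Metropolis with multivariate-normal proposals and flat priors
#' on box bounds (`center` within half a span of the transect, `width` in
#' `(0, 2 span]`, `delta` in `[0, span]`, `tau` and scaling parameters in
#' `[0, 1]`, `p_min <= p_max` by rejection). A pilot run with independent
#' proposals estimates the proposal covariance, which is then scaled by
#' `2.38^2 / d`; the main phase runs `n_chains` chains from overdispersed
#' random starts. Inference pools the post-burn-in draws of all chains.
#'
#' @param sites Site table (see [cline_loglik()]).
#' @param model Cline model template: a list with `tail` and `scaling`
#'   entries, e.g. `list(tail = "none", scaling = "fixed_none")`.
#' @param data_kind `"mt_frequency"` or `"q_mean"`.
#' @param tuning_iters Pilot iterations used to estimate the proposal
#'   covariance.
#' @param chain_iters Iterations per main chain.
#' @param n_chains Number of main chains.
#' @param burn_frac Fraction of each main chain discarded as burn-in.
#' @param seed Integer seed; the whole fit is deterministic given it.
#' @param thin Thinning interval for the stored (not the inferential) draws.
#' @param check_convergence Warn when split-R-hat > 1.05 or ESS < 200.
#' @return An object of class `cline_fit`: maximum-likelihood point estimate
#'   (the best sampled draw refined by a deterministic Nelder-Mead pass so
#'   AICc carries no Monte-Carlo noise), AICc, per-parameter
#'   two-log-likelihood support intervals from the pooled draws, pooled
#'   thinned samples, ESS and split-R-hat diagnostics.
#' @export
fit_mh <- function(sites, model = list(tail = "none", scaling = "fixed_none"),
                   data_kind = c("mt_frequency", "q_mean"),
                   tuning_iters = 10000, chain_iters = 50000, n_chains = 3,
                   burn_frac = 0.2, seed, thin = 5, check_convergence = TRUE) {
  data_kind <- match.arg(data_kind)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  stopifnot(tuning_iters >= 1, chain_iters >= 1, n_chains >= 1)
  dat <- site_counts(sites, data_kind)
  if (length(unique(dat$x)) < 3)
    stop("need at least 3 distinct transect positions", call. = FALSE)
  set.seed(seed)
  spec <- model_spec(model$tail, model$scaling, dat$x, dat$k / dat$n)

  # pilot: independent proposals scaled to the box
  pilot_sd <- (spec$upper - spec$lower) / 50
  theta0 <- draw_start(spec, dat$x, dat$k, dat$n)
  pilot <- mh_chain_cpp(theta0, diag(pilot_sd, spec$k), spec$lower, spec$upper,
                        spec$map, spec$base, dat$x, dat$k, dat$n,
                        spec$left_tail, spec$right_tail, as.integer(tuning_iters))
  if (pilot$accepts == 0)
    stop("all pilot proposals rejected; widen the parameter bounds", call. = FALSE)
  keep <- seq(floor(tuning_iters / 2) + 1, tuning_iters)
  pcov <- cov(pilot$samples[keep, , drop = FALSE])
  pcov <- pcov + diag((spec$upper - spec$lower)^2 * 1e-8, spec$k)
  prop_chol <- chol(pcov * 2.38^2 / spec$k)

  burn <- floor(burn_frac * chain_iters)
  samples <- vector("list", n_chains)
  lls <- vector("list", n_chains)
  acc <- numeric(n_chains)
  for (ch in seq_len(n_chains)) {
    start <- draw_start(spec, dat$x, dat$k, dat$n)
    run <- mh_chain_cpp(start, prop_chol, spec$lower, spec$upper,
                        spec$map, spec$base, dat$x, dat$k, dat$n,
                        spec$left_tail, spec$right_tail, as.integer(chain_iters))
    samples[[ch]] <- run$samples[(burn + 1):chain_iters, , drop = FALSE]
    lls[[ch]] <- run$ll[(burn + 1):chain_iters]
    acc[ch] <- run$accepts / chain_iters
  }

  rhat <- split_rhat(samples)
  ess <- sum_ess(samples)
  pooled <- do.call(rbind, samples)
  colnames(pooled) <- spec$free
  ll_all <- unlist(lls)
  imax <- which.max(ll_all)

  # polish the ML point deterministically from the best draw so that the
  # reported maximum (and hence AICc) carries no Monte-Carlo noise
  pol <- polish_ml(pooled[imax, ], spec, dat)
  point <- pol$theta
  max_ll <- pol$ll

  # support set for the 2-LL intervals; the ML point itself is always in it
  pooled <- rbind(pooled, point, deparse.level = 0)
  ll_all <- c(ll_all, max_ll)
  ridge <- ll_all >= max_ll - 2
  ci <- t(apply(pooled[ridge, , drop = FALSE], 2, range))
  colnames(ci) <- c("low", "high")

  idx <- seq(1, nrow(pooled), by = thin)
  k_params <- spec$k
  n_obs <- nrow(sites)
  fit <- structure(list(
    model = model, data_kind = data_kind, free = spec$free, k = k_params,
    n_obs = n_obs, point_estimate = point,
    params_at_max = spec_to_params(spec, point),
    max_ll = max_ll, aicc = aicc(max_ll, k_params, n_obs),
    ci_2ll = ci, samples = cbind(pooled[idx, , drop = FALSE], ll = ll_all[idx]),
    ess = ess, rhat = rhat, acceptance = acc, seed = seed,
    sites = sites
  ), class = "cline_fit")
  if (check_convergence) {
    if (any(rhat > 1.05, na.rm = TRUE))
      warning("split-R-hat > 1.05 for: ",
              paste(spec$free[rhat > 1.05], collapse = ", "),
              "; inspect the traces", call. = FALSE)
    if (any(ess < 200, na.rm = TRUE))
      warning("effective sample size < 200 for: ",
              paste(spec$free[ess < 200], collapse = ", "), call. = FALSE)
  }
  fit
}

#' @export
print.cline_fit <- function(x, ...) {
  cat(sprintf("Cline fit (%s; tails '%s', scaling '%s')\n",
              x$data_kind, x$model$tail, x$model$scaling))
  cat(sprintf("  max log-likelihood %.3f, AICc %.3f (k = %d, n = %d sites)\n",
              x$max_ll, x$aicc, x$k, x$n_obs))
  est <- cbind(estimate = x$point_estimate, x$ci_2ll)
  print(round(est, 3))
  invisible(x)
}

#' Two-log-likelihood support interval
#'
#' Range of a parameter over all retained samples whose log-likelihood is
#' within 2 units of the maximum; approximates a 95% interval under a
#' quadratic likelihood.
#'
#' @param fit A `cline_fit` object.
#' @param parameter Free parameter name.
#' @return Numeric `[low, high]`.
#' @export
ci_2ll <- function(fit, parameter) {
  if (!parameter %in% fit$free)
    stop("parameter `", parameter, "` is not in this model (free: ",
         paste(fit$free, collapse = ", "), ")", call. = FALSE)
  unname(fit$ci_2ll[parameter, ])
}

#' Null model of no clinal transition
#'
#' Constant frequency with closed-form maximum likelihood at the pooled
#' `sum(k) / sum(n)`; one free parameter.
#'
#' @inheritParams fit_mh
#' @return A list with `p_hat`, `max_ll`, `aicc`, `k`, `n_obs`.
#' @export
fit_null <- function(sites, data_kind = c("mt_frequency", "q_mean")) {
  data_kind <- match.arg(data_kind)
  dat <- site_counts(sites, data_kind)
  p_hat <- sum(dat$k) / sum(dat$n)
  p <- min(max(p_hat, 1e-9), 1 - 1e-9)
  max_ll <- sum(dbinom(dat$k, dat$n, p, log = TRUE))
  list(model = list(tail = "null", scaling = "null"), data_kind = data_kind,
       p_hat = p_hat, max_ll = max_ll, k = 1L, n_obs = nrow(sites),
       aicc = aicc(max_ll, 1L, nrow(sites)))
}

#' Fit and rank the full cline model family
#'
#' Fits the fifteen cline models (three scaling sets: none, fixed-observed,
#' free; five tail configurations: none, left, right, mirror, both) plus the
#' null model of no clinal transition, and ranks them by AICc. When a simpler
#' model sits within 2 AICc units of the raw winner it is also reported as
#' the parsimony-preferred model.
#'
#' @inheritParams fit_mh
#' @param ... Passed on to [fit_mh()] (iteration counts etc.).
#' @return An object of class `cline_model_selection` with the ranked
#'   `table`, the winning `cline_fit` (`winner`), the parsimony-preferred
#'   model name, and all `fits`.
#' @export
model_select <- function(sites, data_kind = c("mt_frequency", "q_mean"),
                         seed, ...) {
  data_kind <- match.arg(data_kind)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  scalings <- c("fixed_none", "fixed_observed", "free")
  tails <- c("none", "left", "right", "mirror", "both")
  grid <- expand.grid(tail = tails, scaling = scalings,
                      stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$scaling, scalings)), ]
  fits <- vector("list", nrow(grid) + 1)
  rows <- vector("list", nrow(grid) + 1)
  dots <- list(...)
  # the scan routinely includes overparameterised models whose tail
  # parameters mix slowly; their diagnostics are not individually warned
  if (is.null(dots$check_convergence)) dots$check_convergence <- FALSE
  for (i in seq_len(nrow(grid))) {
    nm <- sprintf("set%d_%s", match(grid$scaling[i], scalings), grid$tail[i])
    fit <- tryCatch(
      do.call(fit_mh,
              c(list(sites = sites,
                     model = list(tail = grid$tail[i], scaling = grid$scaling[i]),
                     data_kind = data_kind, seed = seed + i), dots)),
      error = function(e) e
    )
    fits[[i]] <- fit
    names(fits)[i] <- nm
    if (inherits(fit, "error")) {
      rows[[i]] <- tibble(model = nm, set = match(grid$scaling[i], scalings),
                          tail = grid$tail[i], scaling = grid$scaling[i],
                          k = NA_integer_, max_ll = NA_real_, aicc = NA_real_,
                          note = conditionMessage(fit))
    } else {
      rows[[i]] <- tibble(model = nm, set = match(grid$scaling[i], scalings),
                          tail = grid$tail[i], scaling = grid$scaling[i],
                          k = fit$k, max_ll = fit$max_ll, aicc = fit$aicc,
                          note = "")
    }
  }
  null <- fit_null(sites, data_kind)
  fits[[nrow(grid) + 1]] <- null
  names(fits)[nrow(grid) + 1] <- "null"
  rows[[nrow(grid) + 1]] <- tibble(model = "null", set = NA_integer_,
                                   tail = "null", scaling = "null", k = 1L,
                                   max_ll = null$max_ll, aicc = null$aicc,
                                   note = "")
  tab <- do.call(rbind, rows)
  # AICc differences far below any meaningful resolution (< 0.01) are ties;
  # ties rank the earlier model set, then the simpler tail structure, first
  set_key <- ifelse(is.na(tab$set), 99L, tab$set)
  tail_key <- match(tab$tail, c(tails, "null"))
  ord <- order(round(tab$aicc, 2), set_key, tail_key, na.last = TRUE)
  tab <- tab[ord, ]
  tab$delta_aicc <- tab$aicc - tab$aicc[1]
  winner_name <- tab$model[1]
  near <- tab[!is.na(tab$delta_aicc) & tab$delta_aicc < 2, ]
  preferred <- near$model[which.min(near$k)]
  structure(list(table = tab, winner = fits[[winner_name]],
                 winner_name = winner_name, preferred = preferred,
                 fits = fits, data_kind = data_kind, seed = seed),
            class = "cline_model_selection")
}

#' @export
print.cline_model_selection <- function(x, ...) {
  cat("Cline model selection (", x$data_kind, "), AICc-ranked:\n", sep = "")
  print(as.data.frame(x$table[, c("model", "k", "max_ll", "aicc", "delta_aicc")]),
        row.names = FALSE, digits = 5)
  if (x$preferred != x$winner_name)
    cat("parsimony-preferred within 2 AICc units:", x$preferred, "\n")
  invisible(x)
}

#' Point estimate with a support interval
#'
#' Light-weight container so published estimates can be compared with
#' [compare_clines()] without refitting.
#'
#' @param point Point estimate.
#' @param ci Length-2 interval `[low, high]`.
#' @param parameter Optional parameter name.
#' @export
cline_estimate <- function(point, ci, parameter = NA_character_) {
  stopifnot(length(ci) == 2, ci[1] <= ci[2])
  structure(list(point = point, ci = as.numeric(ci), parameter = parameter),
            class = "cline_estimate")
}

estimate_of <- function(x, parameter) {
  if (inherits(x, "cline_estimate")) return(x)
  if (inherits(x, "cline_fit"))
    return(cline_estimate(unname(x$point_estimate[parameter]),
                          ci_2ll(x, parameter), parameter))
  stop("expected a cline_fit or cline_estimate", call. = FALSE)
}

#' Compare a parameter between two cline fits
#'
#' Reciprocal support-interval rule: the estimates differ significantly iff
#' each dataset's point estimate falls outside the other dataset's
#' two-log-likelihood interval (both directions must fail to overlap).
#'
#' @param fit_a,fit_b `cline_fit` or [cline_estimate()] objects.
#' @param parameter Parameter name (used when fits are passed).
#' @return List with `significantly_different` and the points/intervals.
#' @export
compare_clines <- function(fit_a, fit_b, parameter = "width") {
  a <- estimate_of(fit_a, parameter)
  b <- estimate_of(fit_b, parameter)
  a_out <- a$point < b$ci[1] || a$point > b$ci[2]
  b_out <- b$point < a$ci[1] || b$point > a$ci[2]
  list(significantly_different = a_out && b_out,
       parameter = parameter,
       point_a = a$point, ci_a = a$ci, a_outside_ci_b = a_out,
       point_b = b$point, ci_b = b$ci, b_outside_ci_a = b_out)
}

# --- MCMC diagnostics (pooled-chain inference, split-R-hat and a Geyer
# initial-monotone ESS; standard formulas) ---

split_rhat <- function(chains) {
  p <- ncol(chains[[1]])
  halves <- list()
  for (ch in chains) {
    n <- nrow(ch)
    h <- floor(n / 2)
    halves <- c(halves, list(ch[1:h, , drop = FALSE],
                             ch[(h + 1):(2 * h), , drop = FALSE]))
  }
  vapply(seq_len(p), function(j) {
    m <- length(halves)
    n <- nrow(halves[[1]])
    means <- vapply(halves, function(h) mean(h[, j]), 0)
    vars <- vapply(halves, function(h) var(h[, j]), 0)
    W <- mean(vars)
    B <- n * var(means)
    if (W == 0) return(NA_real_)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, 0)
}

sum_ess <- function(chains) {
  p <- ncol(chains[[1]])
  vapply(seq_len(p), function(j) {
    sum(vapply(chains, function(ch) single_ess(ch[, j]), 0))
  }, 0)
}

single_ess <- function(x) {
  n <- length(x)
  if (var(x) == 0) return(NA_real_)
  rho <- as.numeric(acf(x, lag.max = min(1000, n - 1), plot = FALSE,
                        demean = TRUE)$acf)[-1]
  # Geyer: sum consecutive pairs while the pair sum stays positive
  s <- 0
  i <- 1
  while (i + 1 <= length(rho)) {
    pair <- rho[i] + rho[i + 1]
    if (pair <= 0) break
    s <- s + pair
    i <- i + 2
  }
  n / (1 + 2 * s)
}
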