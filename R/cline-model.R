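#' Cline parameter set
#'
#' Container for the parameters of a sigmoid geographic cline with optional
#' exponential tails. The central shape is
#' \deqn{f(x) = \frac{1}{1 + e^{-4 (x - c) / w}}}
#' where `center` (c) is the transect position at which the unscaled cline
#' crosses 0.5 and `width` (w) is the inverse of the maximum slope. An
#' exponential left tail replaces the sigmoid for `x < c - delta_l`:
#' \deqn{f(x) = f(c-\delta_L)\, e^{\theta_L (x - c + \delta_L)},\qquad
#'       \theta_L = \frac{4\tau_L/w}{1 + e^{-4\delta_L/w}}}
#' and symmetrically on the right. `tau` is the ratio of the tail slope to
#' the sigmoid slope at the junction, so the curve is continuously
#' differentiable there exactly when `tau = 1`. The observed frequency is the
#' scaled shape `p(x) = p_min + (p_max - p_min) f(x)`.
#'
#' @param center Cline center c, km along the transect.
#' @param width Cline width w, km; must be positive.
#' @param delta_l,delta_r Distance from the center at which each exponential
#'   tail takes over, km, non-negative. Only used when `tail` activates that
#'   side; under `tail = "mirror"` the left values are used for both sides.
#' @param tau_l,tau_r Tail slope ratios in `[0, 1]`.
#' @param p_min,p_max Asymptotic minimum and maximum frequencies in `[0, 1]`
#'   with `p_min <= p_max`.
#' @param tail Tail configuration: `"none"`, `"left"`, `"right"`, `"mirror"`
#'   (shared delta/tau on both sides) or `"both"`.
#' @param scaling How p_min/p_max are treated when fitting: `"fixed_none"`
#'   (0 and 1), `"fixed_observed"`, or `"free"`.
#' @return An object of class `cline_params`.
#' @export
cline_params <- function(center, width, delta_l = 0, tau_l = 1,
                         delta_r = 0, tau_r = 1, p_min = 0, p_max = 1,
                         tail = c("none", "left", "right", "mirror", "both"),
                         scaling = c("fixed_none", "fixed_observed", "free")) {
  tail <- match.arg(tail)
  scaling <- match.arg(scaling)
  if (!is.numeric(width) || length(width) != 1L || !is.finite(width) || width <= 0)
    stop("`width` must be a single positive number", call. = FALSE)
  if (!is.numeric(center) || length(center) != 1L || !is.finite(center))
    stop("`center` must be a single finite number", call. = FALSE)
  for (nm in c("delta_l", "delta_r")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 0) stop("`", nm, "` must be >= 0", call. = FALSE)
  }
  for (nm in c("tau_l", "tau_r", "p_min", "p_max")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 0 || v > 1)
      stop("`", nm, "` must be in [0, 1]", call. = FALSE)
  }
  if (p_min > p_max) stop("`p_min` must not exceed `p_max`", call. = FALSE)
  if (tail == "mirror") {
    delta_r <- delta_l
    tau_r <- tau_l
  }
  structure(
    list(center = center, width = width, delta_l = delta_l, tau_l = tau_l,
         delta_r = delta_r, tau_r = tau_r, p_min = p_min, p_max = p_max,
         tail = tail, scaling = scaling),
    class = "cline_params"
  )
}

#' @export
print.cline_params <- function(x, ...) {
  cat(sprintf("Cline: center %.4g km, width %.4g km, tails '%s', scaling '%s'\n",
              x$center, x$width, x$tail, x$scaling))
  if (x$tail != "none")
    cat(sprintf("  delta (%.4g, %.4g) km, tau (%.3g, %.3g)\n",
                x$delta_l, x$delta_r, x$tau_l, x$tau_r))
  if (x$p_min != 0 || x$p_max != 1)
    cat(sprintf("  scaled to [%.3g, %.3g]\n", x$p_min, x$p_max))
  invisible(x)
}

# pack a cline_params object into the 8-slot numeric layout shared with the
# compiled sampler: c, w, dL, tL, dR, tR, p_min, p_max
full_vector <- function(params) {
  c(params$center, params$width, params$delta_l, params$tau_l,
    params$delta_r, params$tau_r, params$p_min, params$p_max)
}

tail_flags <- function(tail) {
  c(left = tail %in% c("left", "mirror", "both"),
    right = tail %in% c("right", "mirror", "both"))
}

#' Evaluate a geographic cline
#'
#' Expected frequency of the focal (interior) class at transect positions
#' `x`. Continuous everywhere; continuously differentiable at the tail
#' junctions iff `tau = 1`.
#'
#' @param params A [cline_params()] object.
#' @param x Numeric vector of transect positions, km.
#' @return Numeric vector of frequencies in `[p_min, p_max]`.
#' @export
cline_eval <- function(params, x) {
  stopifnot(inherits(params, "cline_params"))
  if (params$width <= 0) stop("cline width must be positive", call. = FALSE)
  fl <- tail_flags(params$tail)
  th <- full_vector(params)
  cvt <- th[1]; w <- th[2]
  f <- 1 / (1 + exp(-4 * (x - cvt) / w))
  if (fl["left"]) {
    i <- x < cvt - th[3]
    if (any(i)) {
      f0 <- 1 / (1 + exp(4 * th[3] / w))
      slope <- (4 * th[4] / w) / (1 + exp(-4 * th[3] / w))
      f[i] <- f0 * exp(slope * (x[i] - cvt + th[3]))
    }
  }
  if (fl["right"]) {
    i <- x > cvt + th[5]
    if (any(i)) {
      f1 <- 1 / (1 + exp(-4 * th[5] / w))
      slope <- (4 * th[6] / w) / (1 + exp(-4 * th[5] / w))
      f[i] <- 1 - (1 - f1) * exp(-slope * (x[i] - cvt - th[5]))
    }
  }
  params$p_min + (params$p_max - params$p_min) * f
}

#' Binomial log-likelihood of site data under a cline
#'
#' For mtDNA haplotype frequencies the data are the per-site counts
#' `k_interior` of `n`; for site-mean ancestry (`data_kind = "q_mean"`) the
#' same binomial form is used with effective successes `round(n * mean_q)`.
#' Expected frequencies are clamped to `[1e-9, 1 - 1e-9]` so that structural
#' zeros in the model cannot produce `-Inf` against mismatched data.
#'
#' @param params A [cline_params()] object.
#' @param sites Site table with columns `distance`, `n`, and `k_interior` or
#'   `mean_q` depending on `data_kind`.
#' @param data_kind `"mt_frequency"` or `"q_mean"`.
#' @param q_likelihood For `q_mean` data only: `"binomial"` (default, the
#'   effective-successes form used throughout the fitting machinery) or
#'   `"gaussian"`, a sensitivity alternative treating the site mean as
#'   Normal with standard error `sqrt(var_q / n)` (requires `var_q`).
#' @return Log-likelihood (scalar).
#' @export
cline_loglik <- function(params, sites, data_kind = c("mt_frequency", "q_mean"),
                         q_likelihood = c("binomial", "gaussian")) {
  data_kind <- match.arg(data_kind)
  q_likelihood <- match.arg(q_likelihood)
  stopifnot(inherits(params, "cline_params"))
  if (data_kind == "q_mean" && q_likelihood == "gaussian") {
    if (!all(c("mean_q", "var_q", "n") %in% names(sites)))
      stop("gaussian q likelihood needs `mean_q`, `var_q` and `n`", call. = FALSE)
    keep <- sites$n > 0
    se <- sqrt(pmax(sites$var_q[keep], 1e-6) / sites$n[keep])
    p <- cline_eval(params, sites$distance[keep])
    return(sum(stats::dnorm(sites$mean_q[keep], p, se, log = TRUE)))
  }
  dat <- site_counts(sites, data_kind)
  p <- pmin(pmax(cline_eval(params, dat$x), 1e-9), 1 - 1e-9)
  sum(dbinom(dat$k, dat$n, p, log = TRUE))
}

# Extract (x, k, n) from a site table, dropping n = 0 sites with a warning.
site_counts <- function(sites, data_kind) {
  if (nrow(sites) == 0) stop("site table is empty", call. = FALSE)
  if (!"distance" %in% names(sites)) stop("site table needs `distance`", call. = FALSE)
  n <- sites$n
  if (any(n == 0)) {
    warning(sum(n == 0), " site(s) with n = 0 excluded", call. = FALSE)
    sites <- sites[n > 0, , drop = FALSE]
    n <- sites$n
  }
  if (data_kind == "mt_frequency") {
    if (!"k_interior" %in% names(sites))
      stop("mt_frequency data need `k_interior`", call. = FALSE)
    k <- sites$k_interior
  } else {
    if (!"mean_q" %in% names(sites))
      stop("q_mean data need `mean_q`", call. = FALSE)
    k <- round(n * sites$mean_q)
  }
  stopifnot(all(k >= 0), all(k <= n))
  list(x = sites$distance, k = as.numeric(k), n = as.numeric(n))
}
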