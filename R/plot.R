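#' Plot a fitted cline with its support band
#'
#' Observed site frequencies, the maximum-likelihood cline, and the
#' pointwise envelope of all sampled clines within two log-likelihood units
#' of the maximum.
#'
#' @param fit A `cline_fit` object.
#' @param n_grid Number of positions at which to evaluate the curves.
#' @return A ggplot object.
#' @export
plot_cline <- function(fit, n_grid = 200) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_cline needs the ggplot2 package", call. = FALSE)
  stopifnot(inherits(fit, "cline_fit"))
  sites <- fit$sites
  dat <- site_counts(sites, fit$data_kind)
  xs <- seq(min(dat$x), max(dat$x), length.out = n_grid)

  best <- cline_eval(fit$params_at_max, xs)
  ridge <- fit$samples[fit$samples[, "ll"] >= fit$max_ll - 2, , drop = FALSE]
  spec <- model_spec(fit$model$tail, fit$model$scaling, dat$x, dat$k / dat$n)
  env <- apply(ridge[, fit$free, drop = FALSE], 1, function(theta)
    cline_eval(spec_to_params(spec, theta), xs))
  band <- apply(env, 1, range)

  df_fit <- tibble(distance = xs, p = best, lo = band[1, ], hi = band[2, ])
  df_obs <- tibble(distance = dat$x, freq = dat$k / dat$n, n = dat$n)
  ggplot2::ggplot(df_fit, ggplot2::aes(x = .data$distance)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$p), linewidth = 0.8) +
    ggplot2::geom_point(data = df_obs,
                        ggplot2::aes(y = .data$freq, size = .data$n),
                        shape = 21, fill = "white") +
    ggplot2::scale_size_area(max_size = 4) +
    ggplot2::labs(x = "transect distance (km)",
                  y = if (fit$data_kind == "mt_frequency")
                        "interior mtDNA frequency" else "mean interior Q",
                  size = "n") +
    ggplot2::theme_minimal()
}
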