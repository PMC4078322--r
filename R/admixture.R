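#' Configuration for the Bayesian admixture model
#'
#' @param K Number of ancestral clusters (>= 1).
#' @param alpha Dirichlet hyperparameter of per-individual ancestry (fixed,
#'   not sampled).
#' @param lambda Dirichlet hyperparameter of per-cluster allele frequencies
#'   (independent-frequency prior).
#' @param burn_in Burn-in sweeps.
#' @param n_iter Post-burn-in sweeps.
#' @param seed Integer seed.
#' @return An object of class `admixture_config`.
#' @export
admixture_config <- function(K = 2, alpha = 1.0, lambda = 1.0,
                             burn_in = 5000, n_iter = 20000, seed = 1L) {
  if (K < 1) stop("K must be >= 1", call. = FALSE)
  stopifnot(alpha > 0, lambda > 0, burn_in >= 0, n_iter >= 1)
  structure(list(K = as.integer(K), alpha = alpha, lambda = lambda,
                 burn_in = as.integer(burn_in), n_iter = as.integer(n_iter),
                 seed = as.integer(seed)),
            class = "admixture_config")
}

#' Fit the admixture model by Gibbs sampling
#'
#' Standard admixture model for multiallelic genotypes: each allele copy has
#' a latent cluster of origin; per-cluster per-locus allele frequencies have
#' a Dirichlet(lambda) prior, per-individual ancestry proportions a
#' symmetric Dirichlet(alpha) prior. Missing calls are skipped in the
#' likelihood. Returns posterior-mean ancestry (Q), posterior-mean allele
#' frequencies and a thinned log-likelihood trace. Deterministic given
#' `config$seed`.
#'
#' @param gt A [genotype_table()] with at least 2 individuals.
#' @param config An [admixture_config()].
#' @return An object of class `admixture_fit` with `Q` (individuals x K,
#'   rows summing to 1), `freqs` (per-locus K x alleles matrices),
#'   `ll_trace`, and the config.
#' @export
fit_admixture <- function(gt, config = admixture_config()) {
  stopifnot(inherits(gt, "genotype_table"), inherits(config, "admixture_config"))
  if (length(gt$individuals) < 2) stop("need at least 2 individuals", call. = FALSE)
  enc <- encode_genotypes(gt)
  set.seed(config$seed)
  ll_every <- max(1L, (config$burn_in + config$n_iter) %/% 2000L)
  res <- gibbs_admixture_cpp(enc$geno, enc$n_alleles, config$K, config$alpha,
                             config$lambda, config$burn_in, config$n_iter,
                             ll_every)
  Q <- res$Q
  rownames(Q) <- gt$individuals
  colnames(Q) <- paste0("cluster", seq_len(config$K))
  offs <- cumsum(c(0, enc$n_alleles))
  freqs <- lapply(seq_along(gt$loci), function(l) {
    f <- matrix(res$freq, nrow = config$K, byrow = TRUE)[,
      (offs[l] + 1):offs[l + 1], drop = FALSE]
    dimnames(f) <- list(paste0("cluster", seq_len(config$K)),
                        enc$allele_sets[[l]])
    f
  })
  names(freqs) <- gt$loci
  structure(list(Q = Q, freqs = freqs,
                 ll_trace = tibble(iteration = res$ll_iter, loglik = res$ll),
                 config = config, populations = gt$populations),
            class = "admixture_fit")
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf("Admixture fit: K = %d, %d individuals, alpha = %.3g\n",
              x$config$K, nrow(x$Q), x$config$alpha))
  cat(sprintf("  mean max-Q %.3f; final log-likelihood %.2f\n",
              mean(apply(x$Q, 1, max)), tail(x$ll_trace$loglik, 1)))
  invisible(x)
}

#' Repair label switching across admixture runs
#'
#' Cluster labels are arbitrary per run. Relabels every run by the column
#' permutation minimising the summed absolute Q difference to the first run
#' (exhaustive over permutations for K <= 6, greedy otherwise).
#'
#' @param runs List of Q matrices (or `admixture_fit` objects) over the same
#'   individuals and K.
#' @return List of relabeled Q matrices.
#' @export
align_labels <- function(runs) {
  qs <- lapply(runs, function(r) if (inherits(r, "admixture_fit")) r$Q else r)
  dims <- vapply(qs, dim, c(0L, 0L))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all runs must share individuals and K", call. = FALSE)
  ref <- qs[[1]]
  K <- ncol(ref)
  perms <- all_permutations(K)
  lapply(qs, function(q) {
    if (K <= 6) {
      costs <- vapply(perms, function(pm) sum(abs(q[, pm] - ref)), 0)
      q[, perms[[which.min(costs)]], drop = FALSE]
    } else {
      pm <- greedy_assign(q, ref)
      q[, pm, drop = FALSE]
    }
  })
}

all_permutations <- function(k) {
  if (k == 1) return(list(1L))
  sub <- all_permutations(k - 1)
  out <- list()
  for (p in sub)
    for (pos in seq_len(k))
      out[[length(out) + 1]] <- append(p, k, after = pos - 1)
  out
}

greedy_assign <- function(q, ref) {
  K <- ncol(ref)
  taken <- integer(0)
  pm <- integer(K)
  for (j in seq_len(K)) {
    costs <- vapply(seq_len(K), function(i)
      if (i %in% taken) Inf else sum(abs(q[, i] - ref[, j])), 0)
    pm[j] <- which.min(costs)
    taken <- c(taken, pm[j])
  }
  pm
}

#' Successive K = 2 splitting of genetic clusters
#'
#' Runs the admixture model at K = 2, and when the split is well supported
#' partitions the strongly assigned individuals by majority ancestry and
#' recurses on each part; admixed individuals (max-Q below
#' `split_threshold`) are set aside at each split rather than forced into a
#' child. A node stops splitting when fewer than `min_assigned` of its
#' individuals are strongly assigned, when either child would be nearly
#' empty, or when fewer than 4 individuals remain.
#'
#' @param gt A [genotype_table()].
#' @param config An [admixture_config()]; K is forced to 2.
#' @param split_threshold Max-Q needed to count as strongly assigned.
#' @param min_assigned Minimum fraction of strongly assigned individuals for
#'   a split to be accepted.
#' @return A nested cluster tree (class `split_node`): each node carries the
#'   individual ids, the node's Q matrix (NULL for unfit leaves), the
#'   admixed ids set aside, and `children`.
#' @export
successive_split <- function(gt, config = admixture_config(),
                             split_threshold = 0.80, min_assigned = 0.50) {
  stopifnot(inherits(gt, "genotype_table"))
  counter <- new.env()
  counter$n <- 0L
  split_node(gt, config, split_threshold, min_assigned, counter)
}

split_node <- function(gt, config, split_threshold, min_assigned, counter) {
  ids <- gt$individuals
  node <- list(individuals = ids, n = length(ids), q = NULL,
               admixed = character(0), children = NULL)
  if (length(ids) < 4) return(structure(node, class = "split_node"))
  counter$n <- counter$n + 1L
  cfg <- config
  cfg$K <- 2L
  cfg$seed <- config$seed + counter$n
  fit <- fit_admixture(gt, cfg)
  node$q <- fit$Q
  maxq <- apply(fit$Q, 1, max)
  assigned <- maxq >= split_threshold
  grp <- apply(fit$Q, 1, which.max)
  ok <- mean(assigned) >= min_assigned &&
    sum(assigned & grp == 1) >= 2 && sum(assigned & grp == 2) >= 2
  if (ok) {
    node$admixed <- ids[!assigned]
    node$children <- lapply(1:2, function(g) {
      split_node(subset_individuals(gt, assigned & grp == g), config,
                 split_threshold, min_assigned, counter)
    })
  }
  structure(node, class = "split_node")
}

#' Leaf partition of a split tree
#'
#' @param node A `split_node` tree from [successive_split()].
#' @return List of character vectors, one per leaf cluster.
#' @export
split_leaves <- function(node) {
  if (is.null(node$children)) return(list(node$individuals))
  do.call(c, lapply(node$children, split_leaves))
}

#' @export
print.split_node <- function(x, ..., indent = 0) {
  pad <- strrep("  ", indent)
  kind <- if (is.null(x$children)) "leaf" else
    sprintf("split (%d admixed set aside)", length(x$admixed))
  cat(sprintf("%s- %d individuals: %s\n", pad, x$n, kind))
  for (ch in x$children %||% list()) print(ch, indent = indent + 1)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-site mean ancestry
#'
#' Arithmetic mean of the focal-cluster Q-score per site, with per-site n
#' and sample variance, the quantity fitted by the nuclear cline.
#'
#' @param q A Q matrix (or `admixture_fit`).
#' @param site_labels Per-individual site id covering all individuals.
#' @param focal_cluster Column (index or name) whose ancestry is averaged.
#' @return Tibble with `site_id`, `n`, `mean_q`, `var_q` in order of first
#'   appearance.
#' @export
site_mean_q <- function(q, site_labels, focal_cluster = 1) {
  if (inherits(q, "admixture_fit")) q <- q$Q
  if (nrow(q) != length(site_labels))
    stop("site_labels must cover all individuals", call. = FALSE)
  qf <- q[, focal_cluster]
  sites <- unique(site_labels)
  tibble(
    site_id = sites,
    n = unname(vapply(sites, function(s) sum(site_labels == s), 0L)),
    mean_q = unname(vapply(sites, function(s) mean(qf[site_labels == s]), 0)),
    var_q = unname(vapply(sites, function(s) {
      v <- qf[site_labels == s]
      if (length(v) > 1) var(v) else 0
    }, 0))
  )
}
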