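#' Exact test for Hardy-Weinberg equilibrium at one locus
#'
#' Conditional on the observed allele pool, random mating makes every
#' re-pairing of the `2n` allele copies equally likely. The test statistic
#' is the heterozygote count, ordered towards deficit (the common signature
#' of null alleles and inbreeding-like artifacts): low observed
#' heterozygosity gives a small p.
#'
#' Two computational routes target the same conditional null. The
#' Monte-Carlo route draws `n_permutations` random re-pairings and reports
#' `p = (1 + #\{het_perm <= het_obs\}) / (1 + n_permutations)`. The
#' enumeration route (biallelic loci only) evaluates the exact conditional
#' distribution of the heterozygote count (Levene's distribution) and
#' reports `P(het <= het_obs)` with no sampling error.
#'
#' @param genotypes Two-column matrix of allele labels, one row per
#'   individual; `NA` rows are missing and dropped.
#' @param n_permutations Monte-Carlo replicates (default 9999).
#' @param seed Integer seed, required for the Monte-Carlo route.
#' @param method `"monte_carlo"` or `"enumeration"`.
#' @return p-value with attributes `het_obs` and `degenerate` (TRUE for a
#'   monomorphic locus, where p is 1 by convention).
#' @export
hwe_exact_test <- function(genotypes, n_permutations = 9999, seed = NULL,
                           method = c("monte_carlo", "enumeration")) {
  method <- match.arg(method)
  g <- as.matrix(genotypes)
  stopifnot(ncol(g) == 2)
  keep <- !is.na(g[, 1]) & !is.na(g[, 2])
  g <- g[keep, , drop = FALSE]
  if (nrow(g) == 0) stop("all genotypes missing", call. = FALSE)
  if (nrow(g) < 2) stop("need at least 2 non-missing individuals", call. = FALSE)
  pool <- as.integer(factor(c(g[, 1], g[, 2])))
  het_obs <- sum(g[, 1] != g[, 2])
  n_all <- max(pool)
  if (n_all == 1L)
    return(structure(1, het_obs = het_obs, degenerate = TRUE))

  if (method == "enumeration") {
    if (n_all != 2L)
      stop("enumeration is implemented for biallelic loci only", call. = FALSE)
    d <- levene_het_distribution(sum(pool == 1L), nrow(g))
    p <- sum(d$prob[d$het <= het_obs])
  } else {
    if (n_permutations < 1) stop("n_permutations must be >= 1", call. = FALSE)
    if (is.null(seed)) stop("`seed` is required for the Monte-Carlo test", call. = FALSE)
    set.seed(seed)
    perm <- perm_het_counts_cpp(pool, as.integer(n_permutations))
    p <- (1 + sum(perm <= het_obs)) / (1 + n_permutations)
  }
  structure(p, het_obs = het_obs, degenerate = FALSE)
}

# Exact conditional distribution of the heterozygote count for a biallelic
# locus given the minor-allele copy number (Levene 1949): support has the
# parity of nA, probabilities computed on the log scale and renormalised.
levene_het_distribution <- function(n_a, n_ind) {
  n_a <- min(n_a, 2 * n_ind - n_a)
  hs <- seq(n_a %% 2, n_a, by = 2)
  lp <- lfactorial(n_ind) - lfactorial((n_a - hs) / 2) - lfactorial(hs) -
    lfactorial(n_ind - (n_a + hs) / 2) + hs * log(2) +
    lfactorial(n_a) + lfactorial(2 * n_ind - n_a) - lfactorial(2 * n_ind)
  pr <- exp(lp - max(lp))
  list(het = hs, prob = pr / sum(pr))
}

#' Bonferroni decisions for a family of tests
#'
#' Rejects `p < alpha / m` where `m` is the size of the declared family
#' (by default the number of p-values supplied, i.e. all population-by-locus
#' tests treated as one family).
#'
#' @param pvalues Numeric p-values (NA entries are never rejected).
#' @param alpha Nominal family-wise level in (0, 1).
#' @param m Family size; defaults to `length(pvalues)`.
#' @return Logical rejection vector with attributes `threshold` and `m`.
#' @export
bonferroni <- function(pvalues, alpha = 0.05, m = length(pvalues)) {
  stopifnot(alpha > 0, alpha < 1)
  if (length(pvalues) == 0)
    return(structure(logical(0), threshold = numeric(0), m = 0L))
  rej <- !is.na(pvalues) & pvalues < alpha / m
  structure(rej, threshold = alpha / m, m = as.integer(m))
}

#' Permutation test of linkage disequilibrium between two loci
#'
#' Association between the genotype classes of two loci measured by the
#' G-statistic of the two-locus genotype contingency table; the null
#' distribution is generated by permuting individuals at the second locus.
#'
#' @param genotypes_a,genotypes_b Two-column allele matrices over the same
#'   individuals.
#' @param n_permutations Permutation replicates.
#' @param seed Integer seed.
#' @return p-value with attribute `g_obs`; `degenerate = TRUE` and p = 1
#'   when either locus is monomorphic.
#' @export
ld_test <- function(genotypes_a, genotypes_b, n_permutations = 9999, seed) {
  ga <- as.matrix(genotypes_a); gb <- as.matrix(genotypes_b)
  stopifnot(ncol(ga) == 2, ncol(gb) == 2, nrow(ga) == nrow(gb))
  keep <- !is.na(ga[, 1]) & !is.na(ga[, 2]) & !is.na(gb[, 1]) & !is.na(gb[, 2])
  ga <- ga[keep, , drop = FALSE]; gb <- gb[keep, , drop = FALSE]
  if (nrow(ga) < 2) stop("need at least 2 complete genotype pairs", call. = FALSE)
  if (length(unique(c(ga))) < 2 || length(unique(c(gb))) < 2)
    return(structure(1, g_obs = 0, degenerate = TRUE))
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  cls <- function(g) {
    lab <- paste(pmin(g[, 1], g[, 2]), pmax(g[, 1], g[, 2]), sep = "/")
    as.integer(factor(lab))
  }
  ca <- cls(ga); cb <- cls(gb)
  ka <- max(ca); kb <- max(cb)
  if (ka < 2 || kb < 2)
    return(structure(1, g_obs = 0, degenerate = TRUE))
  g_obs <- g_stat_cpp(ca, cb, ka, kb)
  set.seed(seed)
  perm <- perm_g_stats_cpp(ca, cb, ka, kb, as.integer(n_permutations))
  p <- (1 + sum(perm >= g_obs)) / (1 + n_permutations)
  structure(p, g_obs = g_obs, degenerate = FALSE)
}

#' Per-population, per-locus quality control report
#'
#' Runs the Hardy-Weinberg exact test in every population at every locus
#' (populations with fewer than 2 scored individuals at a locus are skipped
#' as NA), applies a joint Bonferroni correction across all tests, and runs
#' the pairwise linkage test within each population, combining populations
#' by Fisher's method (pooled-sample linkage would reflect admixture LD in
#' a hybrid zone rather than physical linkage).
#'
#' @param gt A [genotype_table()].
#' @param n_permutations Monte-Carlo replicates per test.
#' @param seed Integer seed.
#' @param alpha Nominal family-wise level.
#' @param ld Whether to run the pairwise linkage tests.
#' @return An object of class `qc_report`: `hwe` (population x locus
#'   p-value matrix), `reject` (Bonferroni decisions), `bonferroni_alpha`,
#'   `ld` (locus-pair table or NULL).
#' @export
qc_report <- function(gt, n_permutations = 999, seed, alpha = 0.05, ld = TRUE) {
  stopifnot(inherits(gt, "genotype_table"))
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  pops <- unique(gt$populations)
  L <- length(gt$loci)
  pv <- matrix(NA_real_, length(pops), L, dimnames = list(pops, gt$loci))
  s <- seed
  for (i in seq_along(pops)) {
    idx <- gt$populations == pops[i]
    for (l in seq_len(L)) {
      pairs <- locus_pairs(gt, l)[idx, , drop = FALSE]
      ok <- sum(!is.na(pairs[, 1]))
      if (ok >= 2) {
        s <- s + 1
        pv[i, l] <- as.numeric(hwe_exact_test(pairs, n_permutations, seed = s))
      }
    }
  }
  tested <- sum(!is.na(pv))
  rej <- matrix(as.logical(bonferroni(as.numeric(pv), alpha, m = tested)),
                nrow(pv), ncol(pv), dimnames = dimnames(pv))
  # linkage is tested within populations (pooling individuals across a
  # hybrid zone would detect admixture LD, not physical linkage) and the
  # per-population p-values are combined by Fisher's method
  ld_tab <- NULL
  if (ld && L >= 2) {
    prs <- combn(L, 2)
    ld_p <- numeric(ncol(prs))
    for (j in seq_len(ncol(prs))) {
      pvals <- c()
      for (i in seq_along(pops)) {
        idx <- gt$populations == pops[i]
        ga <- locus_pairs(gt, prs[1, j])[idx, , drop = FALSE]
        gb <- locus_pairs(gt, prs[2, j])[idx, , drop = FALSE]
        if (sum(stats::complete.cases(cbind(ga, gb))) < 5) next
        s <- s + 1
        p <- ld_test(ga, gb, n_permutations, seed = s)
        if (!attr(p, "degenerate")) pvals <- c(pvals, as.numeric(p))
      }
      ld_p[j] <- if (length(pvals) == 0) NA_real_ else
        stats::pchisq(-2 * sum(log(pvals)), df = 2 * length(pvals),
                      lower.tail = FALSE)
    }
    ld_tab <- tibble(locus_a = gt$loci[prs[1, ]], locus_b = gt$loci[prs[2, ]],
                     p_value = ld_p)
  }
  structure(list(hwe = pv, reject = rej, bonferroni_alpha = alpha / tested,
                 alpha = alpha, m = tested, ld = ld_tab, seed = seed),
            class = "qc_report")
}

#' Locus retention after quality control
#'
#' Drops loci whose Bonferroni-significant Hardy-Weinberg failures occur in
#' more than `max_failing_populations` populations; loci with at least one
#' failure but not more than the threshold form the borderline set, kept but
#' reported for sensitivity reruns.
#'
#' @param report A [qc_report()].
#' @param max_failing_populations Failure-count threshold (default 5).
#' @return List with `retained`, `dropped`, `borderline` locus ids and the
#'   per-locus failure counts.
#' @export
flag_loci <- function(report, max_failing_populations = 5) {
  stopifnot(inherits(report, "qc_report"))
  fails <- colSums(report$reject, na.rm = TRUE)
  dropped <- names(fails)[fails > max_failing_populations]
  borderline <- names(fails)[fails > 0 & fails <= max_failing_populations]
  retained <- setdiff(colnames(report$hwe), dropped)
  list(retained = retained, dropped = dropped, borderline = borderline,
       failures = fails)
}
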