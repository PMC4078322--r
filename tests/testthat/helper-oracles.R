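# Independent oracles and small fixture builders used across the suite.
# Everything here is deliberately written from first principles, separate
# from the package's own code paths.

# brute-force motif scan: leftmost non-overlapping occurrences on one strand
scan_motif <- function(sequence, motif) {
  n <- 0L
  i <- 1L
  while (i + nchar(motif) - 1L <= nchar(sequence)) {
    if (substr(sequence, i, i + nchar(motif) - 1L) == motif) {
      n <- n + 1L
      i <- i + nchar(motif)
    } else {
      i <- i + 1L
    }
  }
  n
}

revcomp_chr <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

# grid-search maximum likelihood for the plain sigmoid cline (no tails,
# unscaled) -- the oracle for fit_mh's max_ll, 200 x 200 over (center, width)
grid_ml_fast <- function(x, k, n, n_grid = 200) {
  span <- max(x) - min(x)
  cs <- seq(min(x) - span / 2, max(x) + span / 2, length.out = n_grid)
  ws <- seq(1e-3, 2 * span, length.out = n_grid)
  best <- -Inf
  for (w0 in ws) {
    # sites x centers matrix of expected frequencies
    pr <- 1 / (1 + exp(-4 * outer(x, cs, "-") / w0))
    pr <- pmin(pmax(pr, 1e-9), 1 - 1e-9)
    ll <- colSums(dbinom(k, n, pr, log = TRUE))
    m <- max(ll)
    if (m > best) best <- m
  }
  best
}

# exact null distribution of the heterozygote count by enumerating every
# arrangement of a biallelic allele pool (positions of the minor allele via
# combn, consecutive elements paired) -- feasible up to 2n ~ 20
enumerate_het_pvalue <- function(pool, het_obs) {
  m <- length(pool)
  stopifnot(m %% 2 == 0)
  codes <- as.integer(factor(pool))
  stopifnot(max(codes) == 2)
  na <- sum(codes == 1)
  pos <- combn(m, na)
  hets <- apply(pos, 2, function(idx) {
    v <- rep(2L, m)
    v[idx] <- 1L
    sum(v[seq(1, m, 2)] != v[seq(2, m, 2)])
  })
  mean(hets <= het_obs)
}

# two-pool genotype fixture: n1 + n2 individuals drawn from explicit
# allele-frequency matrices (loci x alleles)
draw_pool_genotypes <- function(freq, n_ind) {
  L <- nrow(freq)
  a1 <- a2 <- matrix(NA_integer_, n_ind, L)
  for (l in seq_len(L)) {
    a1[, l] <- sample.int(ncol(freq), n_ind, TRUE, prob = freq[l, ])
    a2[, l] <- sample.int(ncol(freq), n_ind, TRUE, prob = freq[l, ])
  }
  list(a1 = a1, a2 = a2)
}

# genotypes at one locus under random mating with inbreeding-like
# heterozygote deficit F (F = 0 is Hardy-Weinberg)
draw_hwe_locus <- function(n_ind, freqs, F = 0) {
  a1 <- sample.int(length(freqs), n_ind, TRUE, prob = freqs)
  a2 <- ifelse(runif(n_ind) < F, a1,
               sample.int(length(freqs), n_ind, TRUE, prob = freqs))
  cbind(a1, a2)
}

# deterministic small transect for fitting tests
mt_sites_from_zone <- function(seed, n_per_site = 20, w_mt = 131, w_nuc = 331,
                               center = 300) {
  cfg <- zone_config(n_per_site = n_per_site, seed = seed,
                     cline_mt = cline_params(center = center, width = w_mt),
                     cline_nuc = cline_params(center = center, width = w_nuc))
  simulate_zone(cfg)
}
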