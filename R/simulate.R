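#' Configuration for a synthetic secondary-contact zone
#'
#' Bundles the truth parameters of a simulated hybrid zone: transect layout,
#' marker counts, parental differentiation, independent mtDNA and nuclear
#' clines (the generator imposes marker-specific cline widths directly rather
#' than simulating sex-linked selection), phenotype effects and the seed.
#'
#' @param n_sites Number of transect populations.
#' @param site_positions Positions along the transect, km, nondecreasing.
#' @param n_per_site Individuals per site: a single value, a vector of
#'   length `n_sites`, or `NULL` to draw each site's n uniformly from 1-28
#'   (the sampling range of a realistic jay transect).
#' @param n_loci Number of unlinked microsatellite loci.
#' @param n_alleles_per_locus Alleles per locus (>= 2).
#' @param divergence Expected allele-frequency differential (total variation
#'   distance) between the parental pools, in `[0, 1]`; 1 gives fully private
#'   alleles.
#' @param cline_mt,cline_nuc [cline_params()] for the mtDNA haplotype
#'   frequency and the expected nuclear ancestry.
#' @param nu Beta concentration of within-site ancestry: individual ancestry
#'   is `Beta(m nu, (1 - m) nu)` with mean `m = cline_nuc(x)`. `Inf` makes
#'   ancestry exactly equal to the cline mean (noise-free limit).
#' @param phenotype_effects Data frame with columns `trait`, `intercept`,
#'   `slope`, `sd`, `type` (`"continuous"` or `"ordinal"`); traits are linear
#'   in ancestry plus Gaussian noise, ordinal traits then rounded to 1-6.
#' @param seed Integer seed; all randomness flows from it.
#' @return An object of class `zone_config`.
#' @export
zone_config <- function(n_sites = 13,
                        site_positions = seq(0, 600, length.out = n_sites),
                        n_per_site = NULL,
                        n_loci = 13, n_alleles_per_locus = 8,
                        divergence = 0.9,
                        cline_mt = cline_params(center = 300, width = 131),
                        cline_nuc = cline_params(center = 300, width = 331),
                        nu = 10,
                        phenotype_effects = default_phenotype_effects(),
                        seed = 1L) {
  fail <- function(field, msg) stop("invalid `", field, "`: ", msg, call. = FALSE)
  if (!is.numeric(n_sites) || n_sites < 1) fail("n_sites", "must be a positive count")
  if (length(site_positions) != n_sites) fail("site_positions", "length must equal n_sites")
  if (is.unsorted(site_positions)) fail("site_positions", "must be nondecreasing")
  if (!is.null(n_per_site)) {
    if (length(n_per_site) == 1) n_per_site <- rep(n_per_site, n_sites)
    if (length(n_per_site) != n_sites) fail("n_per_site", "length must be 1 or n_sites")
    if (any(n_per_site < 1)) fail("n_per_site", "all counts must be positive")
  }
  if (!is.numeric(n_loci) || n_loci < 1) fail("n_loci", "must be a positive count")
  if (!is.numeric(n_alleles_per_locus) || n_alleles_per_locus < 2)
    fail("n_alleles_per_locus", "must be >= 2")
  if (!is.numeric(divergence) || divergence < 0 || divergence > 1)
    fail("divergence", "must be in [0, 1]")
  if (!inherits(cline_mt, "cline_params")) fail("cline_mt", "must be a cline_params object")
  if (!inherits(cline_nuc, "cline_params")) fail("cline_nuc", "must be a cline_params object")
  if (!is.numeric(nu) || nu <= 0) fail("nu", "must be positive (possibly Inf)")
  req <- c("trait", "intercept", "slope", "sd", "type")
  if (!all(req %in% names(phenotype_effects)))
    fail("phenotype_effects", paste("needs columns", paste(req, collapse = ", ")))
  if (!is.numeric(seed) || length(seed) != 1) fail("seed", "must be a single integer")
  structure(list(n_sites = as.integer(n_sites), site_positions = site_positions,
                 n_per_site = n_per_site, n_loci = as.integer(n_loci),
                 n_alleles_per_locus = as.integer(n_alleles_per_locus),
                 divergence = divergence, cline_mt = cline_mt,
                 cline_nuc = cline_nuc, nu = nu,
                 phenotype_effects = as_tibble(phenotype_effects),
                 seed = as.integer(seed)),
            class = "zone_config")
}

#' Default phenotype effect sizes
#'
#' Six morphometric traits (mm) with no ancestry effect and three ordinal
#' plumage scores with a strong ancestry effect: interior ancestry (q -> 1)
#' reduces the collar, eyestripe and undertail whiteness, so plumage tracks
#' the nuclear genome while morphology is environmental noise.
#'
#' @export
default_phenotype_effects <- function() {
  tibble(
    trait = c("wing", "tail", "tarsus", "bill_length", "bill_depth",
              "bill_width", "collar", "vent", "eyestripe"),
    intercept = c(122, 116, 38, 22.5, 8.4, 9.1, 5.4, 5.4, 5.4),
    slope = c(0, 0, 0, 0, 0, 0, -4, -4, -4),
    sd = c(3, 3, 1.4, 0.9, 0.45, 0.45, 0.8, 0.8, 0.8),
    type = c(rep("continuous", 6), rep("ordinal", 3))
  )
}

# Parental allele-frequency pools. Per locus a Dirichlet(1,...,1) base vector
# is drawn and mass `d` is reallocated to disjoint halves of the allele set,
# so the total-variation distance between the pools equals `d` exactly and
# d = 1 gives disjoint supports.
parental_pools <- function(n_loci, n_alleles, d) {
  coastal <- interior <- matrix(0, n_loci, n_alleles)
  s1 <- seq(1, n_alleles, by = 2)
  s2 <- seq(2, n_alleles, by = 2)
  for (l in seq_len(n_loci)) {
    b <- rgamma(n_alleles, 1)
    b <- b / sum(b)
    b1 <- b2 <- numeric(n_alleles)
    b1[s1] <- b[s1] / sum(b[s1])
    b2[s2] <- b[s2] / sum(b[s2])
    coastal[l, ] <- (1 - d) * b + d * b1
    interior[l, ] <- (1 - d) * b + d * b2
  }
  list(coastal = coastal, interior = interior)
}

#' Simulate a synthetic secondary-contact zone
#'
#' For an individual at position x: true ancestry `q` is Beta-distributed
#' with mean `cline_nuc(x)` and concentration `nu`; each of its two allele
#' copies per locus comes from the interior pool with probability q and the
#' coastal pool otherwise; its mtDNA class is interior with probability
#' `cline_mt(x)`; its phenotypes are linear in q plus Gaussian noise.
#' Deterministic given `config$seed`.
#'
#' @param config A [zone_config()].
#' @return An object of class `synthetic_zone` with elements `genotypes`
#'   (a [genotype_table()]), `sites` (per-site counts and ancestry means),
#'   `individuals`, `mt_types`, `q_true`, `phenotypes`, `truth`.
#' @export
simulate_zone <- function(config) {
  stopifnot(inherits(config, "zone_config"))
  set.seed(config$seed)
  ns <- config$n_sites
  n_per <- config$n_per_site
  if (is.null(n_per)) n_per <- sample(1:28, ns, replace = TRUE)
  site_ids <- sprintf("S%02d", seq_len(ns))
  pools <- parental_pools(config$n_loci, config$n_alleles_per_locus,
                          config$divergence)

  site_of <- rep(seq_len(ns), n_per)
  x_of <- config$site_positions[site_of]
  N <- length(site_of)
  ids <- sprintf("ind%03d", seq_len(N))

  m_nuc <- cline_eval(config$cline_nuc, x_of)
  q <- if (is.infinite(config$nu)) m_nuc else rbeta_mean(m_nuc, config$nu)
  p_mt <- cline_eval(config$cline_mt, x_of)
  mt <- ifelse(runif(N) < p_mt, "interior", "coastal")

  L <- config$n_loci
  A <- config$n_alleles_per_locus
  a1 <- a2 <- matrix(NA_integer_, N, L)
  for (i in seq_len(N)) {
    from_int <- runif(2 * L) < q[i]
    for (l in seq_len(L)) {
      p1 <- if (from_int[2 * l - 1]) pools$interior[l, ] else pools$coastal[l, ]
      p2 <- if (from_int[2 * l]) pools$interior[l, ] else pools$coastal[l, ]
      a1[i, l] <- sample.int(A, 1, prob = p1)
      a2[i, l] <- sample.int(A, 1, prob = p2)
    }
  }
  geno <- genotype_table(a1, a2, individuals = ids, populations = site_ids[site_of],
                         loci = sprintf("loc%02d", seq_len(L)))

  eff <- config$phenotype_effects
  ph <- tibble(specimen_id = ids)
  for (r in seq_len(nrow(eff))) {
    v <- eff$intercept[r] + eff$slope[r] * q + rnorm(N, 0, eff$sd[r])
    if (eff$type[r] == "ordinal") v <- pmin(pmax(round(v), 1L), 6L)
    ph[[eff$trait[r]]] <- v
  }
  ph$q_score <- q
  ctr <- config$cline_nuc$center
  ph$transect <- abs(x_of - ctr) <= 250
  ph$core <- abs(x_of - ctr) <= 100
  ph$site <- site_ids[site_of]

  sites <- tibble(
    site_id = site_ids, distance = config$site_positions,
    n = as.integer(n_per),
    k_interior = vapply(seq_len(ns), function(s) sum(mt[site_of == s] == "interior"), 0L),
    mean_q = vapply(seq_len(ns), function(s) mean(q[site_of == s]), 0),
    var_q = vapply(seq_len(ns), function(s) {
      qs <- q[site_of == s]
      if (length(qs) > 1) var(qs) else 0
    }, 0)
  )

  structure(list(
    genotypes = geno,
    sites = sites,
    individuals = tibble(id = ids, site = site_ids[site_of], distance = x_of,
                         mt_type = mt, q_true = q),
    mt_types = setNames(mt, ids),
    q_true = setNames(q, ids),
    phenotypes = ph,
    sequences = NULL,
    truth = config
  ), class = "synthetic_zone")
}

# Beta draws with mean m and concentration nu; degenerate means map to
# point masses at 0/1 (Beta shape parameters would vanish there).
rbeta_mean <- function(m, nu) {
  q <- numeric(length(m))
  inner <- m > 0 & m < 1
  q[inner] <- rbeta(sum(inner), m[inner] * nu, (1 - m[inner]) * nu)
  q[m >= 1] <- 1
  q[m <= 0] <- 0
  q
}

#' @export
print.synthetic_zone <- function(x, ...) {
  cat(sprintf("Synthetic contact zone: %d individuals, %d sites, %d loci\n",
              nrow(x$individuals), nrow(x$sites), length(x$genotypes$loci)))
  cat(sprintf("  truth: mt width %.4g km, nuclear width %.4g km, divergence %.3g\n",
              x$truth$cline_mt$width, x$truth$cline_nuc$width, x$truth$divergence))
  if (!is.null(x$sequences)) cat(sprintf("  %d sequences attached\n", length(x$sequences)))
  invisible(x)
}

#' Attach diagnostic mtDNA sequences to a synthetic zone
#'
#' Generates one nucleotide sequence per individual emulating a diagnostic
#' restriction assay: coastal individuals carry exactly one occurrence of the
#' recognition motif (counting both strands), interior individuals carry
#' none, so an in-silico digest recovers the simulated classes exactly.
#'
#' @param dataset A `synthetic_zone`.
#' @param motif Recognition motif (default the BsrDI site `GCAATG`).
#' @param length Sequence length, must exceed the motif length.
#' @param seed Integer seed.
#' @return The dataset with a named character vector `sequences` attached.
#' @export
simulate_sequences <- function(dataset, motif = "GCAATG", length = 400,
                               seed = dataset$truth$seed + 1L) {
  stopifnot(inherits(dataset, "synthetic_zone"))
  if (!nzchar(motif)) stop("`motif` must be nonempty", call. = FALSE)
  if (length <= nchar(motif)) stop("`length` must exceed the motif length", call. = FALSE)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  n_hits <- function(s) digest(s, motif)$n_cut_sites
  rand_seq <- function() paste(sample(bases, length, replace = TRUE), collapse = "")
  seqs <- character(length(dataset$mt_types))
  for (i in seq_along(seqs)) {
    target <- if (dataset$mt_types[i] == "coastal") 1L else 0L
    for (try in 1:1000) {
      s <- rand_seq()
      if (target == 1L) {
        pos <- sample.int(length - nchar(motif) + 1, 1)
        substr(s, pos, pos + nchar(motif) - 1) <- motif
      }
      if (n_hits(s) == target) break
      if (try == 1000) stop("failed to generate a sequence with the required motif count",
                            call. = FALSE)
    }
    seqs[i] <- s
  }
  dataset$sequences <- setNames(seqs, names(dataset$mt_types))
  dataset
}
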