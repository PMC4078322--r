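#' Diploid multiallelic genotype table
#'
#' Holds unordered allele pairs per individual and locus, with population
#' labels. Missing calls are `NA` in both allele matrices (never a sentinel
#' allele); the Structure-style `-9` code is translated at the file boundary
#' by [read_genotypes()]/[write_genotypes()].
#'
#' @param a1,a2 Integer matrices (individuals x loci) of allele labels;
#'   `NA` marks a missing call (both copies must be `NA` together).
#' @param individuals Character ids, one per row.
#' @param populations Per-individual population label.
#' @param loci Character locus ids, one per column.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(a1, a2, individuals, populations, loci) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  stopifnot(identical(dim(a1), dim(a2)),
            nrow(a1) == length(individuals),
            nrow(a1) == length(populations),
            ncol(a1) == length(loci))
  half_missing <- xor(is.na(a1), is.na(a2))
  if (any(half_missing))
    stop("half-missing genotype calls: both allele copies must be present or absent",
         call. = FALSE)
  structure(list(a1 = a1, a2 = a2,
                 individuals = as.character(individuals),
                 populations = as.character(populations),
                 loci = as.character(loci)),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("Genotype table: %d individuals x %d loci, %d populations, %.1f%% missing\n",
              length(x$individuals), length(x$loci),
              length(unique(x$populations)),
              100 * mean(is.na(x$a1))))
  invisible(x)
}

# allele pairs at one locus as a 2-column matrix (NA rows = missing)
locus_pairs <- function(gt, locus) {
  j <- if (is.character(locus)) match(locus, gt$loci) else locus
  if (is.na(j)) stop("unknown locus: ", locus, call. = FALSE)
  cbind(gt$a1[, j], gt$a2[, j])
}

# subset individuals by logical/integer index
subset_individuals <- function(gt, idx) {
  genotype_table(gt$a1[idx, , drop = FALSE], gt$a2[idx, , drop = FALSE],
                 gt$individuals[idx], gt$populations[idx], gt$loci)
}

# integer-coded genotype matrix (N x 2L) for the Gibbs sampler: alleles
# recoded 1..A_l per locus from the observed allele set, 0 = missing
encode_genotypes <- function(gt) {
  L <- length(gt$loci)
  N <- length(gt$individuals)
  out <- matrix(0L, N, 2 * L)
  n_alleles <- integer(L)
  allele_sets <- vector("list", L)
  for (l in seq_len(L)) {
    obs <- sort(unique(c(gt$a1[, l], gt$a2[, l])))
    obs <- obs[!is.na(obs)]
    if (length(obs) == 0)
      stop("locus ", gt$loci[l], " has zero observed alleles", call. = FALSE)
    allele_sets[[l]] <- obs
    n_alleles[l] <- length(obs)
    c1 <- match(gt$a1[, l], obs); c2 <- match(gt$a2[, l], obs)
    out[, 2 * l - 1] <- ifelse(is.na(c1), 0L, c1)
    out[, 2 * l] <- ifelse(is.na(c2), 0L, c2)
  }
  list(geno = out, n_alleles = n_alleles, allele_sets = allele_sets)
}
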