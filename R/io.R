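#' Write a genotype table in the two-column Structure-style dialect
#'
#' One row per individual: id, population, then two columns per locus with
#' missing calls written as `-9`. Tab-delimited with a header row.
#'
#' @param gt A [genotype_table()].
#' @param path Output file.
#' @export
write_genotypes <- function(gt, path) {
  stopifnot(inherits(gt, "genotype_table"))
  L <- length(gt$loci)
  out <- data.frame(individual = gt$individuals, population = gt$populations,
                    stringsAsFactors = FALSE)
  for (l in seq_len(L)) {
    c1 <- gt$a1[, l]; c2 <- gt$a2[, l]
    c1[is.na(c1)] <- -9L; c2[is.na(c2)] <- -9L
    out[[paste0(gt$loci[l], "_1")]] <- c1
    out[[paste0(gt$loci[l], "_2")]] <- c2
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a Structure-style genotype table
#'
#' Expects the dialect written by [write_genotypes()]: individual,
#' population, then an even number of allele columns (two per locus) with
#' `-9` for missing. Ragged rows and half-missing calls are rejected with
#' the offending line/entry named.
#'
#' @param path Input file.
#' @return A [genotype_table()].
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  nf <- count.fields(path, sep = "\t")
  if (length(unique(nf)) > 1) {
    bad <- which(nf != nf[1])[1]
    stop("ragged genotype file: line ", bad, " has ", nf[bad],
         " fields, expected ", nf[1], call. = FALSE)
  }
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  allele_cols <- setdiff(names(df), c("individual", "population"))
  if (length(allele_cols) == 0 || length(allele_cols) %% 2 != 0)
    stop("expected an even number of allele columns (two per locus), got ",
         length(allele_cols), call. = FALSE)
  loci <- unique(sub("_[12]$", "", allele_cols))
  a1 <- as.matrix(df[, paste0(loci, "_1"), drop = FALSE])
  a2 <- as.matrix(df[, paste0(loci, "_2"), drop = FALSE])
  if (!is.numeric(a1) || !is.numeric(a2))
    stop("allele calls must be integers (missing = -9)", call. = FALSE)
  a1[a1 == -9] <- NA; a2[a2 == -9] <- NA
  dimnames(a1) <- dimnames(a2) <- NULL
  genotype_table(a1, a2, df$individual, df$population, loci)
}

#' Write / read a transect site table
#'
#' Tab-delimited site tables with whatever of the standard columns are
#' present (`site_id`, `latitude`, `longitude`, `distance`, `n`,
#' `k_interior`, `mean_q`, `var_q`).
#'
#' @param sites Site tibble.
#' @param path File path.
#' @export
write_sites <- function(sites, path) {
  write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sites
#' @export
read_sites <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}

#' Write / read FASTA sequences
#'
#' Thin wrappers over Biostrings keeping the package's named-character
#' representation.
#'
#' @param sequences Named character vector of nucleotide sequences.
#' @param path FASTA file path.
#' @export
write_fasta <- function(sequences, path) {
  ds <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(ds, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  ds <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ds), names(ds))
}

#' Serialize a zone configuration
#'
#' The truth sidecar of a synthetic dataset, written as YAML so a run can be
#' reproduced from its outputs alone.
#'
#' @param config A [zone_config()].
#' @param path File path.
#' @export
write_zone_config <- function(config, path) {
  stopifnot(inherits(config, "zone_config"))
  x <- unclass(config)
  x$cline_mt <- unclass(x$cline_mt)
  x$cline_nuc <- unclass(x$cline_nuc)
  x$phenotype_effects <- as.data.frame(x$phenotype_effects)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_zone_config
#' @export
read_zone_config <- function(path) {
  x <- yaml::read_yaml(path)
  mk_cline <- function(cp) cline_params(
    center = cp$center, width = cp$width, delta_l = cp$delta_l,
    tau_l = cp$tau_l, delta_r = cp$delta_r, tau_r = cp$tau_r,
    p_min = cp$p_min, p_max = cp$p_max, tail = cp$tail, scaling = cp$scaling)
  zone_config(
    n_sites = x$n_sites, site_positions = unlist(x$site_positions),
    n_per_site = if (is.null(x$n_per_site)) NULL else unlist(x$n_per_site),
    n_loci = x$n_loci, n_alleles_per_locus = x$n_alleles_per_locus,
    divergence = x$divergence, cline_mt = mk_cline(x$cline_mt),
    cline_nuc = mk_cline(x$cline_nuc), nu = x$nu,
    phenotype_effects = as_tibble(as.data.frame(x$phenotype_effects)),
    seed = x$seed)
}
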