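#' In-silico restriction digest of a linear amplicon
#'
#' Counts non-overlapping leftmost occurrences of the recognition motif on
#' the given strand plus occurrences of its reverse complement (a physical
#' enzyme cuts both orientations of a double-stranded amplicon; for a
#' palindromic motif the two strands describe the same site, counted once).
#' `N` bases never match. The band-count rule of the diagnostic assay maps
#' fragment counts to haplotype calls: two bands (one cut) is coastal, one
#' band (no cut) is interior, anything else is ambiguous.
#'
#' @param sequence Nucleotide string over `A,C,G,T,N`.
#' @param motif Recognition motif over `A,C,G,T` (degenerate IUPAC codes are
#'   rejected rather than silently mismatched).
#' @return An object of class `digest_result`: `n_cut_sites`,
#'   `n_fragments` (= cut sites + 1, linear amplicon) and `call` in
#'   `{coastal, interior, ambiguous}`.
#' @export
digest <- function(sequence, motif = "GCAATG") {
  if (!is.character(sequence) || length(sequence) != 1 || !nzchar(sequence))
    stop("`sequence` must be a single nonempty string", call. = FALSE)
  if (!is.character(motif) || length(motif) != 1 || !nzchar(motif))
    stop("`motif` must be a single nonempty string", call. = FALSE)
  sequence <- toupper(sequence)
  motif <- toupper(motif)
  bad <- setdiff(unique(strsplit(sequence, "")[[1]]), c("A", "C", "G", "T", "N"))
  if (length(bad) > 0)
    stop("invalid symbol in sequence: ", paste(bad, collapse = ", "), call. = FALSE)
  bad_m <- setdiff(unique(strsplit(motif, "")[[1]]), c("A", "C", "G", "T"))
  if (length(bad_m) > 0)
    stop("invalid symbol in motif (IUPAC degeneracy unsupported): ",
         paste(bad_m, collapse = ", "), call. = FALSE)

  rc <- reverse_complement(motif)
  n_fwd <- count_nonoverlapping(sequence, motif)
  n_cut <- if (identical(rc, motif)) n_fwd else n_fwd + count_nonoverlapping(sequence, rc)
  call <- if (n_cut == 1L) "coastal" else if (n_cut == 0L) "interior" else "ambiguous"
  structure(list(n_cut_sites = n_cut, n_fragments = n_cut + 1L, call = call),
            class = "digest_result")
}

#' @export
print.digest_result <- function(x, ...) {
  cat(sprintf("Digest: %d cut site(s) -> %d fragment(s) -> %s\n",
              x$n_cut_sites, x$n_fragments, x$call))
  invisible(x)
}

# leftmost non-overlapping count (each recognition site is cut once)
count_nonoverlapping <- function(sequence, motif) {
  hits <- gregexpr(motif, sequence, fixed = TRUE)[[1]]
  if (hits[1] == -1L) 0L else length(hits)
}

reverse_complement <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

#' Digest many sequences
#'
#' @param sequences Named character vector of sequences.
#' @param motif Recognition motif.
#' @return Tibble with `id`, `n_cut_sites`, `n_fragments`, `call`.
#' @export
digest_all <- function(sequences, motif = "GCAATG") {
  res <- lapply(sequences, digest, motif = motif)
  tibble(id = if (is.null(names(sequences))) as.character(seq_along(sequences))
              else names(sequences),
         n_cut_sites = unname(vapply(res, `[[`, 0L, "n_cut_sites")),
         n_fragments = unname(vapply(res, `[[`, 0L, "n_fragments")),
         call = unname(vapply(res, `[[`, "", "call")))
}

#' Per-site mtDNA haplotype counts
#'
#' Tabulates interior-haplotype counts per site from per-individual calls.
#' Ambiguous calls are excluded with a warning giving their count.
#'
#' @param calls Per-individual calls in `{coastal, interior, ambiguous}`.
#' @param site_labels Per-individual site id, same length.
#' @return Tibble with `site_id`, `n` (non-ambiguous calls), `k_interior`
#'   and `freq_interior`, in order of first appearance of each site.
#' @export
site_haplotype_counts <- function(calls, site_labels) {
  if (length(calls) != length(site_labels))
    stop("`calls` and `site_labels` must have equal length", call. = FALSE)
  n_amb <- sum(calls == "ambiguous")
  if (n_amb > 0) {
    warning(n_amb, " ambiguous call(s) excluded", call. = FALSE)
    keep <- calls != "ambiguous"
    calls <- calls[keep]
    site_labels <- site_labels[keep]
  }
  stopifnot(all(calls %in% c("coastal", "interior")))
  sites <- unique(site_labels)
  k <- unname(vapply(sites, function(s) sum(calls[site_labels == s] == "interior"), 0L))
  n <- unname(vapply(sites, function(s) sum(site_labels == s), 0L))
  tibble(site_id = sites, n = n, k_interior = k, freq_interior = k / n)
}
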