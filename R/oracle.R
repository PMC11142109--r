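#' Canonical k-mers of a DNA string
#'
#' A canonical k-mer is the lexicographic minimum of a k-mer and its reverse
#' complement, which makes presence strand-symmetric. k-mers containing
#' non-ACGT residues are excluded (they can never participate in a match).
#'
#' @param s DNA string.
#' @param k k-mer length.
#' @return Character vector of canonical k-mers (with repeats, in order);
#'   positions with excluded k-mers are dropped.
#' @export
canonical_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  km <- substring(s, seq_len(n - k + 1L), k:n)
  km <- km[grepl("^[ACGT]+$", km)]
  if (length(km) == 0L) return(character(0))
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(km)))
  ifelse(km <= rc, km, rc)
}

#' Canonical k-mer set of a genome
#'
#' The brute-force comparator: enumerates every canonical k-mer across all
#' sequences of a genome. Used as ground truth for membership and
#' conservation queries in tests.
#'
#' @param genome A `genome_seq`.
#' @param k k-mer length (>= 1).
#' @return A `kmer_set`: list with `genome`, `k`, and unique `kmers`.
#' @export
build_kmer_set <- function(genome, k) {
  stopifnot(inherits(genome, "genome_seq"), k >= 1L)
  km <- unlist(lapply(genome$sequences, canonical_kmers, k = k),
               use.names = FALSE)
  structure(list(genome = genome$name, k = as.integer(k),
                 kmers = unique(km)),
            class = "kmer_set")
}

oracle_pivot_kmers <- function(pivot, region) {
  s <- pivot$sequences[[region$chrom]]
  starts <- region_starts(region)
  km <- substring(s, starts + 1L, starts + region$k)
  valid <- grepl("^[ACGT]+$", km)
  canon <- rep(NA_character_, length(km))
  if (any(valid)) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(km[valid])))
    canon[valid] <- ifelse(km[valid] <= rc, km[valid], rc)
  }
  list(starts = starts, canon = canon, valid = valid)
}

#' Brute-force membership query
#'
#' Ground-truth comparator: for every k-mer start in the region and every
#' non-pivot genome, tests whether the canonical pivot k-mer is in the
#' genome's canonical k-mer set. Pivot k-mers containing non-ACGT residues
#' are absent everywhere.
#'
#' @param pangenome A `pangenome` (first genome = pivot) or list of
#'   `genome_seq` with the pivot first.
#' @param region A [query_region()].
#' @param k k-mer length (defaults to `region$k`).
#' @return A `membership_result`.
#' @export
oracle_membership <- function(pangenome, region, k = region$k) {
  genomes <- if (inherits(pangenome, "pangenome")) pangenome$genomes
             else pangenome
  stopifnot(inherits(region, "query_region"), k == region$k)
  pivot <- genomes[[1L]]
  others <- genomes[-1L]
  pk <- oracle_pivot_kmers(pivot, region)
  A <- matrix(FALSE, nrow = length(pk$starts), ncol = length(others))
  for (g in seq_along(others)) {
    set <- build_kmer_set(others[[g]], region$k)
    A[pk$valid, g] <- pk$canon[pk$valid] %in% set$kmers
  }
  colnames(A) <- vapply(others, `[[`, character(1), "name")
  structure(list(chrom = region$chrom, k = region$k, starts = pk$starts,
                 present = A),
            class = "membership_result")
}

#' Brute-force conservation query
#'
#' Sum of per-genome presence across non-pivot genomes, plus one for the
#' pivot when `include_pivot`.
#'
#' @inheritParams oracle_membership
#' @param include_pivot Count the pivot itself (default `TRUE`).
#' @return A `conservation_result`.
#' @export
oracle_conservation <- function(pangenome, region, include_pivot = TRUE) {
  mem <- oracle_membership(pangenome, region)
  cnt <- as.integer(rowSums(mem$present))
  structure(list(chrom = region$chrom, k = region$k, starts = mem$starts,
                 count_others = cnt,
                 count = cnt + as.integer(include_pivot)),
            class = "conservation_result")
}
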