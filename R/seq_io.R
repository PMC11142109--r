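#' Construct a genome object
#'
#' A genome is an ordered collection of named DNA sequences (e.g. chromosomes
#' or contigs). Residues are uppercased; anything outside `{A,C,G,T}` is kept
#' verbatim but treated as unmatchable by every matching routine.
#'
#' @param name Label for the genome (used as the genome/document identifier).
#' @param sequences Named character vector of DNA sequences.
#' @return An object of class `genome_seq`.
#' @export
genome_seq <- function(name, sequences) {
  stopifnot(is.character(name), length(name) == 1L, is.character(sequences))
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("every sequence must be named")
  if (anyDuplicated(names(sequences)))
    stop("duplicate sequence names within genome '", name, "'")
  structure(list(name = name, sequences = toupper(sequences)),
            class = "genome_seq")
}

#' @export
print.genome_seq <- function(x, ...) {
  cat("<genome_seq> ", x$name, ": ", length(x$sequences), " sequence(s), ",
      sum(nchar(x$sequences)), " bp total\n", sep = "")
  invisible(x)
}

#' Read a genome from a FASTA file
#'
#' Reads a (possibly gzip-compressed, possibly multi-record) FASTA file into a
#' [genome_seq()]. Record order is preserved and residues are uppercased.
#' Record names are taken up to the first whitespace.
#'
#' @param path Path to the FASTA file.
#' @param name Genome label; defaults to the file name without extension.
#' @return A `genome_seq`.
#' @export
load_fasta <- function(path, name = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (is.null(name)) {
    name <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(path),
                ignore.case = TRUE)
  }
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e)))
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(names(seqs)))
    stop("duplicate record names in FASTA '", path, "'")
  genome_seq(name, seqs)
}

#' Write a genome to a FASTA file
#'
#' @param genome A `genome_seq`.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  stopifnot(inherits(genome, "genome_seq"))
  set <- Biostrings::BStringSet(genome$sequences)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Reverse complement of a DNA string
#'
#' Tolerant of residues outside the IUPAC alphabet: IUPAC codes are
#' complemented, anything else maps to itself (such residues never participate
#' in a match anyway).
#'
#' @param s Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(s) {
  comp <- chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
                 "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", s)
  vapply(comp, function(x) {
    intToUtf8(rev(utf8ToInt(x)))
  }, character(1), USE.NAMES = FALSE)
}

#' Build the searchable target text of a genome
#'
#' Concatenates, for every sequence S of the genome, `S $ revcomp(S) $`, where
#' `$` is a separator that matches nothing (including itself). A substring
#' query against the result is true iff the substring occurs on either strand
#' of the genome without crossing a sequence boundary.
#'
#' @param genome A `genome_seq`.
#' @return An object of class `target_text` with elements `text` (single
#'   string) and `genome_name`.
#' @export
build_target_text <- function(genome) {
  stopifnot(inherits(genome, "genome_seq"))
  parts <- character(0)
  for (s in genome$sequences) parts <- c(parts, s, "$", revcomp(s), "$")
  structure(list(text = paste0(parts, collapse = ""),
                 genome_name = genome$name),
            class = "target_text")
}

# Integer coding used by the matching engine: A,C,G,T -> 1..4; every other
# text symbol (separators included) gets a unique negative code so it matches
# nothing; unmatchable pattern symbols become 0.
encode_text <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  v <- match(chars, c("A", "C", "G", "T"))
  na <- which(is.na(v))
  v[na] <- -seq_along(na)
  as.integer(v)
}

encode_pattern <- function(pattern) {
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  v <- match(chars, c("A", "C", "G", "T"))
  v[is.na(v)] <- 0L
  as.integer(v)
}
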