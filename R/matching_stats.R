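#' Matching statistics of a pattern against a target text
#'
#' `ms[j]` (1-based) is the length of the longest suffix of `pattern[1..j]`
#' that occurs as a substring of the target text without crossing a separator
#' or touching an unmatchable (non-ACGT) residue on either side. Computed by
#' streaming the pattern through a suffix automaton of the target text.
#'
#' The result always satisfies the sawtooth property
#' `ms[j] - ms[j-1] <= 1`: extending the pattern prefix by one character can
#' lengthen its longest matched suffix by at most one.
#'
#' @param pattern DNA string (the pivot sequence), length >= 1.
#' @param target A `target_text` from [build_target_text()].
#' @return Integer vector of length `nchar(pattern)`.
#' @seealso [ms_oracle()] for the brute-force reference implementation.
#' @export
compute_ms <- function(pattern, target) {
  stopifnot(inherits(target, "target_text"))
  if (!is.character(pattern) || length(pattern) != 1L || nchar(pattern) < 1L)
    stop("pattern must be a single non-empty string")
  compute_ms_multi(pattern, target)[[1]]
}

# Shared-automaton variant: all patterns are scanned against one automaton
# built once from the target text.
compute_ms_multi <- function(patterns, target) {
  stopifnot(inherits(target, "target_text"))
  if (any(nchar(patterns) < 1L)) stop("pattern must be a single non-empty string")
  codes <- lapply(patterns, encode_pattern)
  .sam_matching_statistics(encode_text(target$text), codes)
}

#' Brute-force matching statistics (verification oracle)
#'
#' Same contract as [compute_ms()], computed by the O(n*m) dynamic program
#' over longest common suffixes: `D[p, j] = D[p-1, j-1] + 1` when text
#' position `p` and pattern position `j` hold the same ACGT residue, else 0,
#' and `ms[j] = max_p D[p, j]`. Used in tests as an independent check of the
#' suffix-automaton engine; not intended for large inputs.
#'
#' @inheritParams compute_ms
#' @return Integer vector of length `nchar(pattern)`.
#' @export
ms_oracle <- function(pattern, target) {
  stopifnot(inherits(target, "target_text"))
  if (!is.character(pattern) || length(pattern) != 1L || nchar(pattern) < 1L)
    stop("pattern must be a single non-empty string")
  base <- c("A", "C", "G", "T")
  pc <- match(strsplit(pattern, "", fixed = TRUE)[[1]], base)
  tc <- match(strsplit(target$text, "", fixed = TRUE)[[1]], base)
  m <- length(pc)
  n <- length(tc)
  ms <- integer(m)
  prev <- integer(n)
  for (j in seq_len(m)) {
    if (is.na(pc[j])) {
      cur <- integer(n)
    } else {
      eq <- !is.na(tc) & tc == pc[j]
      cur <- integer(n)
      cur[eq] <- c(0L, prev[-n])[eq] + 1L
    }
    ms[j] <- if (n > 0L) max(cur) else 0L
    prev <- cur
  }
  ms
}

#' Check the sawtooth property of a matching-statistics vector
#'
#' @param ms Integer vector of matching statistics.
#' @return `TRUE` if consecutive values increase by at most 1.
#' @export
is_sawtooth <- function(ms) {
  length(ms) < 2L || all(diff(ms) <= 1L)
}

#' Dump matching statistics as TSV
#'
#' Debug helper: writes `(position, length)` pairs, positions 0-based.
#'
#' @param ms Integer vector from [compute_ms()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ms_tsv <- function(ms, path) {
  utils::write.table(
    data.frame(position = seq_along(ms) - 1L, length = ms),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
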