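#' MEM peaks of a matching-statistics vector
#'
#' A position `j` (0-based) is a peak iff `ms[j] >= ms[j+1]` or `j` is the
#' last position, and `ms[j] > 0`. Peaks map one-to-one to maximal exact
#' matches (MEMs): a zero value is never a peak since a zero-length exact
#' match is degenerate.
#'
#' @param ms Integer vector of matching statistics.
#' @return Data frame with columns `pos` (0-based position) and `len`.
#' @export
ms_peaks <- function(ms) {
  m <- length(ms)
  if (m == 0L) return(data.frame(pos = integer(0), len = integer(0)))
  is_peak <- ms > 0L & (seq_len(m) == m | ms >= c(ms[-1], 0L))
  idx <- which(is_peak)
  data.frame(pos = idx - 1L, len = ms[idx])
}

#' Derive MEM intervals from matching statistics
#'
#' Each peak `(j, l)` maps to the 0-based half-open pivot interval
#' `[j + 1 - l, j + 1)`. The output is sorted by start, with strictly
#' increasing starts and ends (no MEM contains another).
#'
#' @param ms Integer vector of matching statistics.
#' @param chrom Pivot sequence name attached to every interval.
#' @param annotation Integer annotation (genome id or order rank).
#' @return Data frame with columns `chrom`, `start`, `end`, `annotation`.
#' @export
mems_from_ms <- function(ms, chrom = "chr", annotation = 1L) {
  pk <- ms_peaks(ms)
  mem_df(chrom, pk$pos + 1L - pk$len, pk$pos + 1L, annotation)
}

mem_df <- function(chrom, start, end, annotation) {
  data.frame(chrom = rep_len(as.character(chrom), length(start)),
             start = as.integer(start), end = as.integer(end),
             annotation = rep_len(as.integer(annotation), length(start)),
             stringsAsFactors = FALSE)
}

#' Overlap records between consecutive MEMs
#'
#' For each consecutive MEM pair within one track, stores the interval from
#' the start of the later MEM to the end of the earlier MEM (0-based,
#' half-open). Adjoining MEMs yield a zero-length record (`start == end`);
#' non-overlapping MEMs yield an inverted record (`start > end`), which every
#' k-mer straddles. Two sentinels are added so k-mers extending past the
#' first/last MEM test absent: a leading record `(first start, 0)` and a
#' trailing record `(pivot_len, last end)`. An empty MEM track yields the
#' single record `(pivot_len, 0)`, under which every k-mer tests absent.
#'
#' @param mems Data frame of MEM intervals for one `(chrom, annotation)`
#'   track, sorted by start with no containment.
#' @param pivot_len Length of the pivot sequence.
#' @param annotation Annotation for the emitted records (defaults to the
#'   track's).
#' @return Data frame with columns `chrom`, `start`, `end`, `annotation`.
#' @export
overlaps_from_mems <- function(mems, pivot_len,
                               annotation = NULL, chrom = NULL) {
  pivot_len <- as.integer(pivot_len)
  if (nrow(mems) == 0L) {
    if (is.null(annotation) || is.null(chrom))
      stop("annotation and chrom are required for an empty MEM track")
    return(mem_df(chrom, pivot_len, 0L, annotation))
  }
  if (is.null(annotation)) annotation <- mems$annotation[1L]
  if (is.null(chrom)) chrom <- mems$chrom[1L]
  if (is.unsorted(mems$start, strictly = TRUE) ||
      is.unsorted(mems$end, strictly = TRUE))
    stop("MEMs must be sorted with strictly increasing starts and ends")
  n <- nrow(mems)
  starts <- c(mems$start[1L], if (n > 1L) mems$start[-1L], pivot_len)
  ends <- c(0L, if (n > 1L) mems$end[-n], mems$end[n])
  mem_df(chrom, starts, ends, annotation)
}

#' Drop overlap records irrelevant below a maximum k-mer length
#'
#' A k-mer straddles an overlap record `(s, e)` (overhang on both sides) only
#' when `k >= (e - s) + 2`; records with `e - s > k_max - 2` can therefore
#' never affect a query with `k <= k_max` and are discarded. Sentinels and
#' inverted (gap) records have `e - s <= 0` and are always kept. Queries with
#' `k <= k_max` on the filtered set equal queries on the full set.
#'
#' @param records Overlap-record data frame.
#' @param k_max Largest k-mer length the filtered index must support
#'   (`>= 2`); `Inf` keeps everything.
#' @return Filtered records.
#' @export
filter_overlaps_for_max_k <- function(records, k_max) {
  if (is.infinite(k_max)) return(records)
  k_max <- as.integer(k_max)
  if (is.na(k_max) || k_max < 2L) stop("k_max must be >= 2")
  records[records$end - records$start <= k_max - 2L, , drop = FALSE]
}

#' Drop MEMs too short to contain a minimum k-mer length
#'
#' A MEM of length `< k_min` cannot contain any k-mer with `k >= k_min`;
#' containment queries with `k >= k_min` are unchanged by discarding them.
#'
#' @param mems MEM data frame.
#' @param k_min Smallest k-mer length the filtered index must support.
#' @return Filtered MEMs.
#' @export
filter_mems_for_min_k <- function(mems, k_min) {
  k_min <- as.integer(k_min)
  if (is.na(k_min) || k_min < 1L) stop("k_min must be >= 1")
  mems[mems$end - mems$start >= k_min, , drop = FALSE]
}
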