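#' Order matching-statistics matrix
#'
#' Sorts the matching-statistics matrix column-wise in descending order.
#' Row `r` of the result no longer tracks one genome; its value at pivot
#' position `j` is the r-th largest match length across genomes, so a k-mer
#' contained in a MEM of row `r` occurs in at least `r` non-pivot genomes.
#' Column-wise sorting preserves the sawtooth property: each output row again
#' satisfies `O[r, j] - O[r, j-1] <= 1`.
#'
#' @param L Integer matrix, one row per non-pivot genome, one column per
#'   pivot position; every row must satisfy the sawtooth property.
#' @return Integer matrix of the same shape, columns sorted descending.
#' @export
order_ms <- function(L) {
  if (is.list(L)) {
    if (length(unique(lengths(L))) > 1L) stop("ragged rows in MS matrix")
    L <- do.call(rbind, L)
  }
  stopifnot(is.matrix(L))
  if (nrow(L) == 0L || ncol(L) == 0L) return(L)
  if (nrow(L) == 1L) return(L)
  O <- apply(L, 2L, sort.int, decreasing = TRUE, method = "radix")
  dimnames(O) <- NULL
  O
}

#' Order-MEMs of an order matching-statistics matrix
#'
#' Applies the peak-to-MEM mapping to every row of the order-MS matrix; the
#' intervals of row `r` are annotated with order rank `r`.
#'
#' @param O Matrix from [order_ms()].
#' @param chrom Pivot sequence name.
#' @return Data frame of MEM intervals with `annotation` = order rank.
#' @export
order_mems <- function(O, chrom = "chr") {
  tracks <- lapply(seq_len(nrow(O)), function(r)
    mems_from_ms(O[r, ], chrom = chrom, annotation = r))
  do.call(rbind, c(tracks, list(make.row.names = FALSE)))
}

#' Overlap records of order-MEM tracks
#'
#' Applies [overlaps_from_mems()] independently to every order rank present
#' in `ranks` (each track gets its own sentinels; an empty track yields the
#' all-absent record).
#'
#' @param omems Data frame from [order_mems()].
#' @param pivot_len Pivot sequence length.
#' @param ranks Order ranks to emit (defaults to those present).
#' @param chrom Pivot sequence name for empty tracks.
#' @return Data frame of overlap records annotated by order rank.
#' @export
order_overlaps <- function(omems, pivot_len, ranks = NULL, chrom = "chr") {
  if (is.null(ranks)) ranks <- sort(unique(omems$annotation))
  tracks <- lapply(ranks, function(r) {
    tr <- omems[omems$annotation == r, , drop = FALSE]
    overlaps_from_mems(tr, pivot_len, annotation = r, chrom = chrom)
  })
  do.call(rbind, c(tracks, list(make.row.names = FALSE)))
}

#' Order ranks retained under quantile sampling
#'
#' For each requested quantile `q`, the retained rank is the smallest integer
#' `x` with `x >= q * t_prime`: the rank whose order-MEMs certify presence in
#' at least a fraction `q` of the non-pivot samples. For 89 samples and
#' deciles this yields ranks 9, 18, 27, ..., 81, 89.
#'
#' @param t_prime Number of non-pivot genomes (>= 1).
#' @param quantiles Fractions in (0, 1], e.g. `seq(0.1, 1, by = 0.1)`.
#' @return Sorted integer vector of unique retained ranks.
#' @export
quantile_rows <- function(t_prime, quantiles = seq(0.1, 1, by = 0.1)) {
  stopifnot(t_prime >= 1L)
  if (any(quantiles <= 0 | quantiles > 1))
    stop("quantiles must lie in (0, 1]")
  ranks <- as.integer(ceiling(quantiles * t_prime - 1e-9))
  sort(unique(pmax(ranks, 1L)))
}

#' Subsample order tracks to retained ranks
#'
#' Keeps only records whose order annotation is among the retained ranks;
#' each retained track is preserved in full.
#'
#' @param records Order-annotated record data frame.
#' @param retained_ranks Integer vector of ranks to keep.
#' @return Subsampled records.
#' @export
subsample_orders <- function(records, retained_ranks) {
  records[records$annotation %in% retained_ranks, , drop = FALSE]
}
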