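#' Construct a query region
#'
#' @param chrom Pivot sequence name.
#' @param i,j 0-based half-open window on the pivot; k-mer starts range over
#'   `[i, j - k]`.
#' @param k k-mer length, `1 <= k <= j - i`.
#' @return A `query_region`.
#' @export
query_region <- function(chrom, i, j, k) {
  i <- as.integer(i); j <- as.integer(j); k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be >= 1")
  if (!(i >= 0L && i < j)) stop("require 0 <= i < j")
  if (j - i < k) stop("region shorter than k")
  structure(list(chrom = as.character(chrom), i = i, j = j, k = k),
            class = "query_region")
}

region_starts <- function(region) region$i:(region$j - region$k)

# Mark the k-mer starts straddling each record: a record (s, e) is straddled
# by the k-mer at x iff x < s and x + k > e, i.e. x in [e - (k - 1), s).
mark_straddles <- function(A, records, region, value) {
  k <- region$k
  x0 <- region$i
  x1 <- region$j - k
  rec <- records[records$chrom == region$chrom, , drop = FALSE]
  e2 <- rec$end - (k - 1L)
  fire <- which(e2 < rec$start & rec$annotation <= ncol(A) &
                  rec$annotation >= 1L)
  for (r in fire) {
    lo <- max(e2[r], x0)
    hi <- min(rec$start[r] - 1L, x1)
    if (lo <= hi) A[(lo:hi) - x0 + 1L, rec$annotation[r]] <- value
  }
  A
}

#' k-mer membership query over overlap records
#'
#' For every k-mer start `x` in `[i, j - k]` and every non-pivot genome,
#' reports whether the pivot k-mer `pivot[x, x + k)` occurs (on either strand)
#' in that genome. A k-mer is absent from a genome iff it straddles one of
#' the genome's overlap records with overhang on both sides; all starts
#' begin as present and straddled ones are switched off.
#'
#' @param records Membership-flavor overlap records covering the region (from
#'   [read_region()] or a full scan).
#' @param region A [query_region()].
#' @param t_prime Number of non-pivot genomes.
#' @return A `membership_result`: list with `chrom`, `k`, `starts`, and
#'   logical matrix `present` (starts x genomes). The pivot's own column is
#'   implicit (always present).
#' @export
membership <- function(records, region, t_prime) {
  stopifnot(inherits(region, "query_region"))
  starts <- region_starts(region)
  A <- matrix(TRUE, nrow = length(starts), ncol = t_prime)
  A <- mark_straddles(A, records, region, FALSE)
  structure(list(chrom = region$chrom, k = region$k, starts = starts,
                 present = A),
            class = "membership_result")
}

#' k-mer membership query over MEM intervals
#'
#' Equivalent alternative to [membership()]: a k-mer is present in a genome
#' iff its interval is entirely contained in one of the genome's MEMs.
#'
#' @param mems Membership-flavor MEM intervals covering the region.
#' @inheritParams membership
#' @return A `membership_result`.
#' @export
membership_via_mems <- function(mems, region, t_prime) {
  stopifnot(inherits(region, "query_region"))
  starts <- region_starts(region)
  k <- region$k
  A <- matrix(FALSE, nrow = length(starts), ncol = t_prime)
  rec <- mems[mems$chrom == region$chrom, , drop = FALSE]
  cover <- which(rec$end - rec$start >= k & rec$annotation <= t_prime)
  for (r in cover) {
    lo <- max(rec$start[r], region$i)
    hi <- min(rec$end[r] - k, region$j - k)
    if (lo <= hi) A[(lo:hi) - region$i + 1L, rec$annotation[r]] <- TRUE
  }
  structure(list(chrom = region$chrom, k = region$k, starts = starts,
                 present = A),
            class = "membership_result")
}

#' k-mer conservation query over order overlap records
#'
#' For every k-mer start, counts the genomes containing the pivot k-mer.
#' Presence at order rank `r` certifies occurrence in at least `r` non-pivot
#' genomes and is monotone in `r`, so the count of other genomes is
#' `(smallest failing order) - 1`, or `t_prime` when no order fails.
#'
#' @param records Conservation-flavor (order-annotated) overlap records, all
#'   ranks `1..t_prime` present.
#' @inheritParams membership
#' @param include_pivot Add 1 for the pivot so counts lie in `[1, N]`
#'   (default); the raw other-genome count is reported in `count_others`
#'   either way.
#' @return A `conservation_result`: list with `chrom`, `k`, `starts`,
#'   `count_others`, `count`.
#' @export
conservation <- function(records, region, t_prime, include_pivot = TRUE) {
  stopifnot(inherits(region, "query_region"))
  starts <- region_starts(region)
  fails <- matrix(FALSE, nrow = length(starts), ncol = t_prime)
  fails <- mark_straddles(fails, records, region, TRUE)
  count_others <- first_failing_order(fails, t_prime)
  structure(list(chrom = region$chrom, k = region$k, starts = starts,
                 count_others = count_others,
                 count = count_others + as.integer(include_pivot)),
            class = "conservation_result")
}

first_failing_order <- function(fails, t_prime) {
  if (t_prime == 0L || nrow(fails) == 0L)
    return(rep.int(0L, nrow(fails)))
  ff <- max.col(fails, ties.method = "first")
  any_fail <- fails[cbind(seq_len(nrow(fails)), ff)]
  ifelse(any_fail, ff - 1L, t_prime)
}

#' Quantile (e.g. decile) conservation query
#'
#' Over a quantile-subsampled index, reports per k-mer start the largest
#' retained order rank whose track the k-mer does not fail — i.e. the largest
#' retained quantile of samples the k-mer is certified to occur in. A start
#' failing even the smallest retained rank gets rank 0 and the below-lowest
#' label. Equals the full-resolution other-genome count floored onto the
#' retained ranks.
#'
#' @param records Order overlap records restricted to the retained ranks.
#' @inheritParams membership
#' @param retained_ranks Sorted integer vector of retained order ranks.
#' @param quantiles Optional quantile fractions used at build time (for
#'   labels).
#' @return A `quantile_conservation_result`: list with `chrom`, `k`,
#'   `starts`, `order` (certified rank, 0 = below lowest), `fraction`
#'   (`order / t_prime`), `label`.
#' @export
quantile_conservation <- function(records, region, retained_ranks, t_prime,
                                  quantiles = NULL) {
  stopifnot(inherits(region, "query_region"))
  retained_ranks <- sort(unique(as.integer(retained_ranks)))
  starts <- region_starts(region)
  nr <- length(retained_ranks)
  fails <- matrix(FALSE, nrow = length(starts), ncol = nr)
  # compact the rank annotations onto columns 1..nr
  rec <- records
  rec$annotation <- match(rec$annotation, retained_ranks)
  if (anyNA(rec$annotation)) stop("record rank outside retained_ranks")
  fails <- mark_straddles(fails, rec, region, TRUE)
  ffidx <- first_failing_order(fails, nr)  # index into retained_ranks
  cert <- ifelse(ffidx == 0L, 0L, retained_ranks[pmax(ffidx, 1L)])
  labels <- quantile_labels(cert, retained_ranks, t_prime, quantiles)
  structure(list(chrom = region$chrom, k = region$k, starts = starts,
                 order = as.integer(cert),
                 fraction = cert / max(t_prime, 1L), label = labels),
            class = "quantile_conservation_result")
}

quantile_labels <- function(cert, retained_ranks, t_prime, quantiles) {
  if (is.null(quantiles)) {
    lab <- sprintf(">=%d/%d", cert, t_prime)
  } else {
    quantiles <- sort(quantiles)
    qrank <- quantile_rows(t_prime, quantiles)
    # largest quantile certified by each retained rank
    qlab <- vapply(retained_ranks, function(r)
      max(quantiles[qrank <= r]), numeric(1))
    lab <- ifelse(cert == 0L, sprintf("<%d%%", round(100 * min(quantiles))),
                  sprintf(">=%d%%",
                          round(100 * qlab[match(cert, retained_ranks)])))
  }
  lab[cert == 0L & is.null(quantiles)] <- sprintf("<%d/%d",
                                                  min(retained_ranks), t_prime)
  lab
}

validate_query_k <- function(md, k) {
  k_max <- if (is.null(md$k_max)) Inf else md$k_max
  if (k > k_max) stop("k = ", k, " exceeds this index's k_max = ", k_max)
  if (k < md$k_min) stop("k = ", k, " below this index's k_min = ", md$k_min)
}

query_prep <- function(index, chrom, i, j, k, want_flavor) {
  if (is.character(index)) index <- read_index(index)
  stopifnot(inherits(index, "panmemo_index"))
  md <- index$metadata
  if (!startsWith(md$flavor, want_flavor))
    stop("index flavor is ", md$flavor, "; need a ", want_flavor, " index")
  if (!chrom %in% names(md$pivot_seq_lengths))
    stop("unknown pivot sequence: ", chrom)
  if (j > md$pivot_seq_lengths[[chrom]])
    stop("region end exceeds pivot sequence length")
  validate_query_k(md, k)
  list(index = index, region = query_region(chrom, i, j, k),
       records = read_region(index, chrom, i, j))
}

#' Membership query against an index
#'
#' @param index A membership-flavor `panmemo_index` (or path to one).
#' @param chrom,i,j Query window, 0-based half-open.
#' @param k k-mer length (validated against the index's permitted k-range).
#' @return A `membership_result` with genome names on the columns.
#' @export
query_membership <- function(index, chrom, i, j, k) {
  qp <- query_prep(index, chrom, i, j, k, "membership")
  md <- qp$index$metadata
  res <- if (endsWith(md$flavor, "-mem")) {
    membership_via_mems(qp$records, qp$region, md$t_prime)
  } else {
    membership(qp$records, qp$region, md$t_prime)
  }
  colnames(res$present) <- md$genome_names[-1L]
  res
}

#' Conservation query against an index
#'
#' @inheritParams query_membership
#' @param include_pivot Count the pivot itself (default `TRUE`).
#' @return A `conservation_result`, or a `quantile_conservation_result` when
#'   the index is quantile-subsampled.
#' @export
query_conservation <- function(index, chrom, i, j, k, include_pivot = TRUE) {
  qp <- query_prep(index, chrom, i, j, k, "conservation")
  md <- qp$index$metadata
  if (endsWith(md$flavor, "-mem")) {
    # derive straddle records equivalently from order-MEM containment
    return(conservation_via_mems(qp$records, qp$region, md, include_pivot))
  }
  if (identical(md$retained_orders, "all")) {
    conservation(qp$records, qp$region, md$t_prime, include_pivot)
  } else {
    quantile_conservation(qp$records, qp$region, md$retained_orders,
                          md$t_prime, md$quantiles)
  }
}

conservation_via_mems <- function(mems, region, md, include_pivot) {
  ranks <- if (identical(md$retained_orders, "all")) seq_len(md$t_prime)
           else md$retained_orders
  starts <- region_starts(region)
  contained <- matrix(FALSE, length(starts), length(ranks))
  rec <- mems
  rec$annotation <- match(rec$annotation, ranks)
  rec <- rec[!is.na(rec$annotation), , drop = FALSE]
  res <- membership_via_mems(rec, region, length(ranks))
  contained <- res$present
  if (identical(md$retained_orders, "all")) {
    # count = largest contiguous rank prefix present
    cnt <- apply_rank_prefix(contained)
    structure(list(chrom = region$chrom, k = region$k, starts = starts,
                   count_others = cnt,
                   count = cnt + as.integer(include_pivot)),
              class = "conservation_result")
  } else {
    idx <- apply_rank_prefix(contained)
    cert <- ifelse(idx == 0L, 0L, ranks[pmax(idx, 1L)])
    structure(list(chrom = region$chrom, k = region$k, starts = starts,
                   order = as.integer(cert),
                   fraction = cert / max(md$t_prime, 1L),
                   label = quantile_labels(cert, ranks, md$t_prime,
                                           md$quantiles)),
              class = "quantile_conservation_result")
  }
}

# per row: number of leading TRUE columns (containment is monotone in rank)
apply_rank_prefix <- function(present) {
  if (ncol(present) == 0L) return(rep.int(0L, nrow(present)))
  fails <- !present
  first_failing_order(fails, ncol(present))
}

#' Write a query result as TSV
#'
#' Membership results get one 0/1 column per genome; conservation results a
#' `count` column; quantile results `order`, `fraction` and `label` columns.
#'
#' @param result A result object from the query functions.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_query_tsv <- function(result, path) {
  df <- as.data.frame(result)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @exportS3Method base::as.data.frame
as.data.frame.membership_result <- function(x, ...) {
  out <- data.frame(chrom = x$chrom, start = x$starts,
                    stringsAsFactors = FALSE)
  pres <- x$present * 1L
  if (is.null(colnames(pres)) && ncol(pres) > 0L)
    colnames(pres) <- paste0("genome_", seq_len(ncol(pres)))
  cbind(out, as.data.frame(pres))
}

#' @exportS3Method base::as.data.frame
as.data.frame.conservation_result <- function(x, ...) {
  data.frame(chrom = x$chrom, start = x$starts,
             count_others = x$count_others, count = x$count,
             stringsAsFactors = FALSE)
}

#' @exportS3Method base::as.data.frame
as.data.frame.quantile_conservation_result <- function(x, ...) {
  data.frame(chrom = x$chrom, start = x$starts, order = x$order,
             fraction = x$fraction, label = x$label,
             stringsAsFactors = FALSE)
}

#' Write a conservation result as BedGraph
#'
#' One `(chrom, start, start + 1, count)` line per k-mer start, for
#' genome-browser loading.
#'
#' @param result A `conservation_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(result, path) {
  stopifnot(inherits(result, "conservation_result"))
  df <- data.frame(result$chrom, result$starts, result$starts + 1L,
                   result$count)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
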