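#' Build a pangenome MEM index
#'
#' Computes matching statistics of every pivot sequence against every other
#' genome (each genome indexed together with its reverse complement), derives
#' MEM intervals, and assembles one of four index flavors:
#'
#' * `membership-overlap` — overlaps between consecutive MEMs, annotated by
#'   genome id (the default; what the on-disk index stores).
#' * `membership-mem` — the MEM intervals themselves, annotated by genome id.
#' * `conservation-overlap` — overlaps between consecutive order-MEMs,
#'   annotated by order rank.
#' * `conservation-mem` — order-MEM intervals, annotated by order rank.
#'
#' Genome ids are 0-based positions in the genome roster, with the pivot at
#' id 0 (never stored). Order ranks are 1-based and count non-pivot genomes.
#'
#' @param pivot A `genome_seq` (the pivot), or a `pangenome` object from
#'   [simulate_pangenome()] (its first genome is the pivot and `genomes` is
#'   ignored).
#' @param genomes List of non-pivot `genome_seq` objects.
#' @param flavor `"membership"` or `"conservation"`.
#' @param store `"overlap"` (store overlap records) or `"mem"` (store MEMs).
#' @param quantiles Optional fractions in (0, 1] for lossy quantile sampling
#'   of order ranks (conservation flavor only), e.g. `seq(0.1, 1, 0.1)` for
#'   deciles.
#' @param k_max Largest supported k-mer length (overlap store only);
#'   `Inf` = unbounded.
#' @param k_min Smallest supported k-mer length (mem store only).
#' @param row_block_target_bytes Target on-disk row-block size; desk-scale
#'   default 16 MB.
#' @return A `panmemo_index`: list with `records` (data frame `chrom`,
#'   `start`, `end`, `annotation`, sorted) and `metadata`.
#' @export
build_index <- function(pivot, genomes = NULL,
                        flavor = c("membership", "conservation"),
                        store = c("overlap", "mem"),
                        quantiles = NULL, k_max = Inf, k_min = 1L,
                        row_block_target_bytes = 16L * 1024L^2) {
  if (inherits(pivot, "pangenome")) {
    genomes <- pivot$genomes[-1L]
    pivot <- pivot$genomes[[1L]]
  }
  stopifnot(inherits(pivot, "genome_seq"))
  if (is.null(genomes)) genomes <- list()
  stopifnot(all(vapply(genomes, inherits, logical(1), "genome_seq")))
  flavor <- match.arg(flavor)
  store <- match.arg(store)
  if (!is.null(quantiles) && flavor != "conservation")
    stop("quantile sampling applies only to conservation indexes")
  if (is.finite(k_max) && store != "overlap")
    stop("k_max filtering applies only to overlap-record indexes")
  if (k_min > 1L && store != "mem")
    stop("k_min filtering applies only to MEM-interval indexes")

  t_prime <- length(genomes)
  chroms <- names(pivot$sequences)
  pivot_lens <- stats::setNames(as.integer(nchar(pivot$sequences)), chroms)

  # MS of every pivot sequence against every other genome: one automaton per
  # genome, all pivot sequences streamed through it.
  ms_by_genome <- lapply(genomes, function(g) {
    tt <- build_target_text(g)
    stats::setNames(compute_ms_multi(unname(pivot$sequences), tt), chroms)
  })

  retained <- "all"
  records <- vector("list", 0L)
  for (chrom in chroms) {
    plen <- pivot_lens[[chrom]]
    if (flavor == "membership") {
      for (g in seq_len(t_prime)) {
        mems <- mems_from_ms(ms_by_genome[[g]][[chrom]], chrom = chrom,
                             annotation = g)
        records[[length(records) + 1L]] <- if (store == "mem") {
          filter_mems_for_min_k(mems, k_min)
        } else {
          filter_overlaps_for_max_k(
            overlaps_from_mems(mems, plen, annotation = g, chrom = chrom),
            k_max)
        }
      }
    } else {
      L <- do.call(rbind, lapply(ms_by_genome, function(msl) msl[[chrom]]))
      if (is.null(L)) L <- matrix(integer(0), nrow = 0L, ncol = plen)
      O <- order_ms(L)
      omems <- order_mems(O, chrom = chrom)
      ranks <- if (is.null(quantiles)) seq_len(t_prime)
               else quantile_rows(t_prime, quantiles)
      if (!is.null(quantiles)) retained <- ranks
      if (t_prime > 0L) {
        records[[length(records) + 1L]] <- if (store == "mem") {
          filter_mems_for_min_k(subsample_orders(omems, ranks), k_min)
        } else {
          order_overlaps(omems, plen, ranks = ranks, chrom = chrom)
        }
      }
    }
  }
  records <- if (length(records)) {
    do.call(rbind, c(records, list(make.row.names = FALSE)))
  } else {
    mem_df(character(0), integer(0), integer(0), integer(0))
  }
  records <- sort_records(records, chroms)

  metadata <- list(
    schema_version = 1L,
    flavor = paste(flavor, store, sep = "-"),
    pivot_name = pivot$name,
    genome_names = c(pivot$name, vapply(genomes, `[[`, character(1), "name")),
    t_prime = t_prime,
    retained_orders = retained,
    k_max = if (is.finite(k_max)) as.integer(k_max) else NULL,
    k_min = as.integer(k_min),
    quantiles = quantiles,
    pivot_seq_lengths = as.list(pivot_lens),
    row_block_target_bytes = as.integer(row_block_target_bytes))
  new_panmemo_index(records, metadata)
}

new_panmemo_index <- function(records, metadata) {
  structure(list(records = records, metadata = metadata),
            class = "panmemo_index")
}

#' @export
print.panmemo_index <- function(x, ...) {
  md <- x$metadata
  cat("<panmemo_index> flavor=", md$flavor,
      " pivot=", md$pivot_name,
      " genomes=", length(md$genome_names),
      " records=", nrow(x$records), "\n", sep = "")
  invisible(x)
}

sort_records <- function(records, chrom_levels) {
  ord <- order(match(records$chrom, chrom_levels),
               records$start, records$end, records$annotation,
               method = "radix")
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  records
}

records_sorted <- function(records, chrom_levels) {
  key <- order(match(records$chrom, chrom_levels),
               records$start, records$end, records$annotation,
               method = "radix")
  !is.unsorted(key, strictly = FALSE) && all(key == seq_along(key))
}
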