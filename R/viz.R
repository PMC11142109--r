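#' Bin a conservation track for plotting
#'
#' Partitions the k-mer starts into `n_bins` near-equal contiguous bins and
#' computes, within each bin, the fraction of starts at every conservation
#' level. Fractions within a bin sum to 1.
#'
#' @param counts A `conservation_result`, or a data frame with columns
#'   `start` and `count`.
#' @param n_bins Number of bins (`1 <= n_bins <= number of starts`).
#' @param t Total number of genomes (top conservation level).
#' @return Data frame with columns `bin`, `bin_start`, `bin_end`, `level`,
#'   `fraction`; attribute `t` carries the top level.
#' @export
bin_conservation <- function(counts, n_bins, t) {
  if (inherits(counts, "conservation_result"))
    counts <- data.frame(start = counts$starts, count = counts$count)
  stopifnot(nrow(counts) > 0L, n_bins >= 1L)
  if (n_bins > nrow(counts))
    stop("n_bins exceeds the number of k-mer starts")
  counts <- counts[order(counts$start), , drop = FALSE]
  n <- nrow(counts)
  bin <- floor((seq_len(n) - 1L) * n_bins / n) + 1L
  pieces <- lapply(seq_len(n_bins), function(b) {
    sub <- counts[bin == b, , drop = FALSE]
    tab <- table(sub$count)
    data.frame(bin = b,
               bin_start = min(sub$start), bin_end = max(sub$start) + 1L,
               level = as.integer(names(tab)),
               fraction = as.numeric(tab) / nrow(sub))
  })
  out <- do.call(rbind, c(pieces, list(make.row.names = FALSE)))
  attr(out, "t") <- as.integer(t)
  out
}

#' Plot specification for a conservation track
#'
#' @param region A [query_region()] (used for axis labelling).
#' @param k k-mer length.
#' @param n_bins Histogram bin count.
#' @param path Output image path (`.png`).
#' @param mode `"full"` (full-resolution counts) or `"quantile"`.
#' @return A `plot_spec`.
#' @export
plot_spec <- function(region, k, n_bins, path, mode = c("full", "quantile")) {
  stopifnot(n_bins >= 1L)
  if (!is.null(region) && region$j - region$i < k)
    stop("region shorter than k")
  structure(list(region = region, k = as.integer(k),
                 n_bins = as.integer(n_bins), path = path,
                 mode = match.arg(mode)),
            class = "plot_spec")
}

#' Render a stacked conservation plot
#'
#' Draws, per bin, stacked fractions of k-mer starts at each conservation
#' level below the maximum; the white area left above the stack is the
#' fraction of k-mers conserved across all genomes.
#'
#' @param binned Output of [bin_conservation()].
#' @param spec A [plot_spec()].
#' @return The output path, invisibly.
#' @export
render_plot <- function(binned, spec) {
  stopifnot(inherits(spec, "plot_spec"))
  if (any(binned$fraction < 0 | binned$fraction > 1))
    stop("binned fractions must lie in [0, 1]")
  t <- attr(binned, "t")
  sub <- binned[binned$level < t, , drop = FALSE]
  levs <- sort(unique(binned$level))
  pal <- grDevices::hcl.colors(max(length(levs), 2L), "Viridis")[seq_along(levs)]
  names(pal) <- levs
  title <- if (is.null(spec$region)) sprintf("%d-mer conservation", spec$k)
           else sprintf("%d-mer conservation, %s:%d-%d", spec$k,
                        spec$region$chrom, spec$region$i, spec$region$j)
  p <- ggplot2::ggplot() +
    ggplot2::scale_y_continuous(limits = c(0, 1), expand = c(0, 0)) +
    ggplot2::scale_x_continuous(limits = c(0.5, max(binned$bin) + 0.5)) +
    ggplot2::labs(x = "bin along region", y = "fraction of k-mer starts",
                  title = title,
                  subtitle = "white area above stacks = conserved in all genomes") +
    ggplot2::theme_classic()
  if (nrow(sub) > 0L) {
    # fully conserved bins contribute no bars: all-white columns
    p <- p +
      ggplot2::geom_col(
        data = sub,
        ggplot2::aes(x = .data$bin, y = .data$fraction,
                     fill = factor(.data$level, levels = levs)),
        width = 1, position = "stack") +
      ggplot2::scale_fill_manual(values = pal, name = "genomes",
                                 drop = FALSE)
  }
  ggplot2::ggsave(spec$path, p, width = 8, height = 4, dpi = 150)
  invisible(spec$path)
}

#' Query, bin and plot conservation over a region
#'
#' Convenience wrapper chaining [query_conservation()],
#' [bin_conservation()] and [render_plot()]. For quantile-subsampled indexes
#' the certified-order track (counting the pivot) is binned.
#'
#' @inheritParams query_membership
#' @param n_bins Histogram bin count.
#' @param path Output image path.
#' @return The output path, invisibly.
#' @export
conservation_plot <- function(index, chrom, i, j, k, n_bins, path) {
  if (is.character(index)) index <- read_index(index)
  res <- query_conservation(index, chrom, i, j, k)
  t <- length(index$metadata$genome_names)
  mode <- "full"
  if (inherits(res, "quantile_conservation_result")) {
    res <- structure(list(chrom = res$chrom, k = res$k, starts = res$starts,
                          count_others = res$order, count = res$order + 1L),
                     class = "conservation_result")
    mode <- "quantile"
  }
  binned <- bin_conservation(res, n_bins, t)
  spec <- plot_spec(query_region(chrom, i, j, k), k, n_bins, path, mode)
  render_plot(binned, spec)
}
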