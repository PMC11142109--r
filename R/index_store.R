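#' Write an index to a columnar-compressed Parquet file
#'
#' Records are stored column-major (chrom dictionary-encoded, start/end/
#' annotation as unsigned 32-bit integers), compressed with the ZSTD codec,
#' and factored into row blocks of roughly `row_block_target_bytes` each.
#' The index metadata travels in the file's key-value footer as JSON.
#'
#' @param index A `panmemo_index` from [build_index()] or [read_index()].
#' @param path Output path (conventionally `.parquet`).
#' @return `path`, invisibly.
#' @export
write_index <- function(index, path) {
  stopifnot(inherits(index, "panmemo_index"))
  records <- index$records
  md <- index$metadata
  chrom_levels <- names(md$pivot_seq_lengths)
  if (!records_sorted(records, chrom_levels))
    stop("records must be sorted by (chrom, start, end, annotation)")
  if (nrow(records) > 0L) {
    if (startsWith(md$flavor, "membership")) {
      if (any(records$annotation < 1L |
              records$annotation >= length(md$genome_names)))
        stop("genome-id annotation outside the genome roster")
    } else if (!identical(md$retained_orders, "all")) {
      if (!all(records$annotation %in% md$retained_orders))
        stop("order annotation outside the retained ranks")
    } else if (any(records$annotation < 1L | records$annotation > md$t_prime)) {
      stop("order annotation outside [1, t_prime]")
    }
  }
  tb <- arrow::arrow_table(
    chrom = arrow::Array$create(factor(records$chrom, levels = chrom_levels)),
    start = arrow::Array$create(records$start, type = arrow::uint32()),
    end = arrow::Array$create(records$end, type = arrow::uint32()),
    annotation = arrow::Array$create(records$annotation,
                                     type = arrow::uint32()))
  tb$metadata$panmemo <- as.character(
    jsonlite::toJSON(md, auto_unbox = TRUE, null = "null"))
  # ~16 bytes per row uncompressed across the four columns
  chunk_rows <- max(1L, index$metadata$row_block_target_bytes %/% 16L)
  arrow::write_parquet(tb, path, compression = "zstd",
                       chunk_size = chunk_rows)
  invisible(path)
}

#' Read an index from a Parquet file
#'
#' @param path Path written by [write_index()].
#' @return A `panmemo_index`.
#' @export
read_index <- function(path) {
  tb <- arrow::read_parquet(path, as_data_frame = FALSE)
  json <- tb$metadata$panmemo
  if (is.null(json)) stop("not a panmemo index (missing footer metadata): ", path)
  md <- jsonlite::fromJSON(json)
  md$pivot_seq_lengths <- lapply(md$pivot_seq_lengths, as.integer)
  if (!is.null(md$retained_orders) && !identical(md$retained_orders, "all"))
    md$retained_orders <- as.integer(md$retained_orders)
  df <- as.data.frame(tb)
  records <- data.frame(chrom = as.character(df$chrom),
                        start = as.integer(df$start),
                        end = as.integer(df$end),
                        annotation = as.integer(df$annotation),
                        stringsAsFactors = FALSE)
  new_panmemo_index(records, md)
}

#' Fetch the records relevant to queries within a pivot region
#'
#' Returns exactly the records that can influence any k-mer query inside the
#' 0-based half-open window `[i, j)` of `chrom`: a record `(s, e)` marks
#' absences only for k-mer starts `x` with `x < s` and `x + k > e`, so only
#' records with `s > i` and `e < j` matter. Sentinel records of each track
#' are included as well (they are inert when irrelevant). Queries over the
#' fetched subset equal queries over a full scan.
#'
#' @param index A `panmemo_index` or a path to one.
#' @param chrom Pivot sequence name.
#' @param i,j 0-based half-open window bounds, `0 <= i < j`.
#' @return Record data frame.
#' @export
read_region <- function(index, chrom, i, j) {
  if (is.character(index)) index <- read_index(index)
  stopifnot(inherits(index, "panmemo_index"))
  md <- index$metadata
  if (!chrom %in% names(md$pivot_seq_lengths))
    stop("unknown pivot sequence: ", chrom)
  if (!(i >= 0 && i < j)) stop("require 0 <= i < j")
  m <- md$pivot_seq_lengths[[chrom]]
  r <- index$records
  keep <- if (endsWith(md$flavor, "-mem")) {
    # containment queries: any MEM intersecting the window can matter
    r$chrom == chrom & r$start < j & r$end > i
  } else {
    r$chrom == chrom &
      ((r$start > i & r$end < j) | r$start == m | r$end == 0L)
  }
  r[keep, , drop = FALSE]
}

#' Export index records as a BED4 track
#'
#' Writes `(chrom, start, end, annotation)` in 0-based half-open coordinates.
#' Overlap-record tracks may contain inverted records (`start > end`, the gap
#' between non-adjacent consecutive MEMs) and boundary sentinels; these are a
#' nonstandard BED dialect and are flagged in the header comment.
#'
#' @param index A `panmemo_index`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_bed <- function(index, path) {
  stopifnot(inherits(index, "panmemo_index"))
  r <- index$records
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# panmemo %s track; 0-based half-open",
                     index$metadata$flavor), con)
  if (any(r$start > r$end))
    writeLines(paste("# nonstandard BED dialect: records with start > end",
                     "are gap/sentinel records of the overlap encoding"), con)
  if (nrow(r) > 0L)
    utils::write.table(r, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Dump index metadata as a JSON sidecar
#'
#' @param index A `panmemo_index`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_metadata_json <- function(index, path) {
  stopifnot(inherits(index, "panmemo_index"))
  jsonlite::write_json(index$metadata, path, auto_unbox = TRUE,
                       null = "null", pretty = TRUE)
  invisible(path)
}
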