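#' Simulation configuration for a synthetic pangenome
#'
#' Describes a star-phylogeny pangenome: a random pivot plus `t - 1` genomes
#' derived from it by independent substitutions and short indels. Defaults
#' are desk-scale but structurally realistic for intra-species divergence:
#' ~1% SNP heterozygosity and sparse indels up to 10 bp.
#'
#' @param pivot_length Total pivot length in bp, split near-equally across
#'   `n_sequences` sequences.
#' @param n_sequences Number of pivot sequences (chromosomes).
#' @param t Total number of genomes including the pivot.
#' @param snp_rate Per-base substitution probability in each derived genome.
#' @param indel_rate Per-base probability of an indel event (insertion or
#'   deletion, equally likely).
#' @param max_indel_len Maximum indel length in bp.
#' @param seed Integer RNG seed; output is reproducible given the seed.
#' @return A `sim_config`.
#' @export
sim_config <- function(pivot_length = 5000L, n_sequences = 1L, t = 4L,
                       snp_rate = 0.01, indel_rate = 0.001,
                       max_indel_len = 10L, seed = 1L) {
  stopifnot(pivot_length >= 1L, n_sequences >= 1L, t >= 1L,
            max_indel_len >= 1L)
  if (snp_rate < 0 || snp_rate > 1 || indel_rate < 0 || indel_rate > 1)
    stop("mutation rates must lie in [0, 1]")
  structure(list(pivot_length = as.integer(pivot_length),
                 n_sequences = as.integer(n_sequences),
                 t = as.integer(t), snp_rate = snp_rate,
                 indel_rate = indel_rate,
                 max_indel_len = as.integer(max_indel_len),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a synthetic pangenome
#'
#' Draws the pivot uniformly over `{A,C,G,T}` and derives each other genome
#' from it with independent SNPs (substitution to a different base) and
#' indels at the configured rates. Deterministic given the seed. When
#' `out_dir` is given, one FASTA per genome plus a JSON mutation manifest are
#' written there.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory for FASTA + manifest output.
#' @return A `pangenome`: list with `genomes` (list of `genome_seq`, pivot
#'   first), `config`, `manifest` (per-genome mutation events), and `files`
#'   (paths, when written).
#' @export
simulate_pangenome <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  bases <- c("A", "C", "G", "T")
  per_seq <- diff(round(seq(0, config$pivot_length,
                            length.out = config$n_sequences + 1L)))
  per_seq <- pmax(as.integer(per_seq), 1L)
  pivot_seqs <- stats::setNames(
    vapply(per_seq, function(n)
      paste0(sample(bases, n, replace = TRUE), collapse = ""), character(1)),
    paste0("chr", seq_along(per_seq)))
  genomes <- vector("list", config$t)
  genomes[[1L]] <- genome_seq("pivot", pivot_seqs)
  manifest <- list()
  if (config$t > 1L) {
    for (g in 2L:config$t) {
      name <- paste0("g", g)
      mut <- lapply(pivot_seqs, mutate_sequence,
                    snp_rate = config$snp_rate,
                    indel_rate = config$indel_rate,
                    max_indel_len = config$max_indel_len)
      seqs <- stats::setNames(vapply(mut, `[[`, character(1), "seq"),
                              names(pivot_seqs))
      genomes[[g]] <- genome_seq(name, seqs)
      events <- do.call(rbind, c(Map(function(m, chrom) {
        if (nrow(m$events)) cbind(chrom = chrom, m$events) else NULL
      }, mut, names(pivot_seqs)), list(make.row.names = FALSE)))
      manifest[[name]] <- events
    }
  }
  pg <- structure(list(genomes = genomes, config = config,
                       manifest = manifest, files = NULL),
                  class = "pangenome")
  if (!is.null(out_dir)) pg <- write_pangenome(pg, out_dir)
  pg
}

# SNPs first (on original coordinates), then indels applied right-to-left.
mutate_sequence <- function(s, snp_rate, indel_rate, max_indel_len) {
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  events <- data.frame(pos = integer(0), type = character(0),
                       ref = character(0), alt = character(0),
                       stringsAsFactors = FALSE)
  snp_idx <- which(stats::runif(n) < snp_rate)
  if (length(snp_idx)) {
    cur <- match(chars[snp_idx], bases)
    shift <- sample.int(3L, length(snp_idx), replace = TRUE)
    alt <- bases[((cur - 1L + shift) %% 4L) + 1L]
    events <- rbind(events, data.frame(
      pos = snp_idx - 1L, type = "snp", ref = chars[snp_idx], alt = alt,
      stringsAsFactors = FALSE))
    chars[snp_idx] <- alt
  }
  ev_idx <- which(stats::runif(n) < indel_rate)
  if (length(ev_idx)) {
    is_ins <- stats::runif(length(ev_idx)) < 0.5
    lens <- sample.int(max_indel_len, length(ev_idx), replace = TRUE)
    ins_seq <- vapply(lens, function(l)
      paste0(sample(bases, l, replace = TRUE), collapse = ""), character(1))
    for (e in rev(seq_along(ev_idx))) {  # right-to-left keeps positions valid
      p <- ev_idx[e]
      if (is_ins[e]) {
        chars <- append(chars, strsplit(ins_seq[e], "")[[1]], after = p - 1L)
        events <- rbind(events, data.frame(
          pos = p - 1L, type = "ins", ref = "", alt = ins_seq[e],
          stringsAsFactors = FALSE))
      } else {
        del_to <- min(p + lens[e] - 1L, length(chars))
        ref <- paste0(chars[p:del_to], collapse = "")
        chars <- chars[-(p:del_to)]
        events <- rbind(events, data.frame(
          pos = p - 1L, type = "del", ref = ref, alt = "",
          stringsAsFactors = FALSE))
      }
    }
  }
  list(seq = paste0(chars, collapse = ""), events = events)
}

#' Write a simulated pangenome to FASTA files plus manifest
#'
#' @param pg A `pangenome`.
#' @param dir Output directory (created if missing).
#' @return The `pangenome` with `files` filled in, invisibly.
#' @export
write_pangenome <- function(pg, dir) {
  stopifnot(inherits(pg, "pangenome"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- vapply(pg$genomes, function(g) {
    p <- file.path(dir, paste0(g$name, ".fa"))
    write_fasta(g, p)
    p
  }, character(1))
  manifest_path <- file.path(dir, "mutations.json")
  jsonlite::write_json(pg$manifest, manifest_path, dataframe = "rows",
                       auto_unbox = TRUE, pretty = TRUE)
  pg$files <- c(files, manifest = manifest_path)
  invisible(pg)
}

#' @export
print.pangenome <- function(x, ...) {
  cat("<pangenome> ", length(x$genomes), " genomes; pivot '",
      x$genomes[[1]]$name, "' with ",
      length(x$genomes[[1]]$sequences), " sequence(s), ",
      sum(nchar(x$genomes[[1]]$sequences)), " bp\n", sep = "")
  invisible(x)
}
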