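# Shared fixtures, all built in code.

# Hand-checkable three-genome example: pivot ACGTT, with
# MS(pivot, g2) = 1 2 3 4 1 and MS(pivot, g3) = 1 2 3 3 4.
worked_example <- function() {
  list(pivot = genome_seq("pivot", c(chr = "ACGTT")),
       g2 = genome_seq("g2", c(chr = "ACGTA")),
       g3 = genome_seq("g3", c(chr = "CGTTG")))
}

worked_pangenome <- function() {
  we <- worked_example()
  structure(list(genomes = list(we$pivot, we$g2, we$g3)),
            class = "pangenome")
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste0(sample(alphabet, n, replace = TRUE), collapse = "")
}

# A random row obeying the sawtooth constraint diff <= 1, values >= 0.
random_sawtooth_row <- function(m) {
  v <- integer(m)
  v[1] <- sample(0:3, 1)
  if (m > 1) {
    for (j in 2:m) {
      v[j] <- if (stats::runif(1) < 0.6) v[j - 1] + 1L
              else sample(0:max(v[j - 1], 0L), 1)
    }
  }
  v
}

mem_df_for_test <- function(chrom, start, end, annotation) {
  data.frame(chrom = rep_len(as.character(chrom), length(start)),
             start = as.integer(start), end = as.integer(end),
             annotation = rep_len(as.integer(annotation), length(start)),
             stringsAsFactors = FALSE)
}

# Occurrence test honouring unmatchable residues: a substring containing a
# non-ACGT symbol occurs nowhere by definition; pure-ACGT substrings can be
# searched literally (they can never match an N or a separator).
occurs_in_target <- function(sub, target_text) {
  grepl("^[ACGT]+$", sub) && grepl(sub, target_text, fixed = TRUE)
}

# Every MEM must occur in the target while neither one-character extension
# does. Returns TRUE when all MEMs on the pivot are maximal.
check_mem_maximality <- function(mems, pivot_seq, target) {
  m <- nchar(pivot_seq)
  for (r in seq_len(nrow(mems))) {
    s <- mems$start[r]; e <- mems$end[r]
    if (!occurs_in_target(substr(pivot_seq, s + 1L, e), target$text))
      return(FALSE)
    if (s > 0L && occurs_in_target(substr(pivot_seq, s, e), target$text))
      return(FALSE)
    if (e < m && occurs_in_target(substr(pivot_seq, s + 1L, e + 1L),
                                  target$text))
      return(FALSE)
  }
  TRUE
}

# All four index flavors of one pangenome.
all_indexes <- function(pg) {
  list(mo = build_index(pg, flavor = "membership", store = "overlap"),
       mm = build_index(pg, flavor = "membership", store = "mem"),
       co = build_index(pg, flavor = "conservation", store = "overlap"),
       cm = build_index(pg, flavor = "conservation", store = "mem"))
}
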