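Package: panmemo
Title: Maximal-Exact-Match Pangenome Index for Arbitrary-Length k-mer
    Membership and Conservation Queries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a compressed pangenome index from maximal exact matches
    (MEMs) between a pivot genome and every other genome in a collection, and
    answers k-mer membership and conservation queries over pivot regions for
    any k-mer length from that single index. Matching statistics are computed
    with a suffix automaton over each genome and its reverse complement;
    MEMs are derived from matching-statistic peaks and stored either directly
    or as the overlaps between consecutive MEMs. Conservation queries use
    order-MEMs obtained by column-wise sorting of the matching-statistics
    matrix, optionally quantile-subsampled for lossy compression. Indexes are
    persisted as ZSTD-compressed columnar Parquet files. Includes a synthetic
    pangenome simulator, brute-force canonical k-mer oracles for validation,
    conservation-track visualization, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    arrow,
    Biostrings,
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    grDevices,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
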