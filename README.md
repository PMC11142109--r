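# panmemo

`panmemo` indexes a pangenome by the **maximal exact matches (MEMs)** between
one designated *pivot* genome and every other genome in the collection, and
answers k-mer **membership** and **conservation** queries over pivot regions
for *any* k-mer length — all from a single compressed index. k-mer-based
indexes (KMC-style databases, presence/absence bitmaps) fix k at build time;
a MEM index does not, because whether a pivot k-mer occurs in another genome
is fully determined by whether its interval fits inside a MEM.

It is aimed at people studying sequence composition and conservation across
collections of assemblies — e.g. which windows of a reference haplotype are
shared by most samples of a species and which are private — without the
multiple-alignment step a graph pangenome requires.

## The method in brief

For a pivot `P[1..m]` and another genome's text `T` (the genome plus its
reverse complement, each terminated by a separator `$`), the *matching
statistics* vector `MS[1..m]` gives, at every position `j`, the length of the
longest suffix of `P[1..j]` occurring in `T`. Successive values satisfy the
sawtooth property `MS[j] − MS[j−1] ≤ 1`. Positions where `MS[j] ≥ MS[j+1]`
(or `j = m`) are peaks, and peaks map one-to-one onto MEMs: the peak `(j, ℓ)`
is the half-open pivot interval `[j+1−ℓ, j+1)`.

* A pivot k-mer at start `x` is **present** in a genome iff `[x, x+k)` is
  contained in one of that genome's MEMs.
* Equivalently (and smaller on disk), store only the *overlaps* between
  consecutive MEMs: the k-mer is **absent** iff it straddles an overlap
  record with overhang on both sides (`x < start` and `x + k > end`).
* Stacking the MS vectors of all `t−1` non-pivot genomes into a matrix and
  sorting each column in descending order gives *order matching statistics*;
  sorted rows keep the sawtooth property, so the same peak rule yields
  **order-MEMs**: containment in the rank-`r` track certifies presence in at
  least `r` other genomes. That turns conservation counting into finding the
  smallest failing rank.
* Order tracks can be *quantile-sampled* (e.g. deciles) for a lossy,
  much smaller index that answers conservation to the nearest lower
  quantile; for 89 samples the decile ranks are 9, 18, 27, …, 81, 89.

Records `(chrom, start, end, annotation)` are stored columnar in a
ZSTD-compressed Parquet file with the index metadata in the footer. All
coordinates everywhere (R API, files, CLI) are 0-based half-open.

## Worked example

```r
library(panmemo)

pg  <- simulate_pangenome(sim_config(pivot_length = 5000, t = 6,
                                     snp_rate = 0.01, indel_rate = 0.001,
                                     seed = 42))
idx <- build_index(pg, flavor = "conservation")
idx
#> <panmemo_index> flavor=conservation-overlap pivot=pivot genomes=6 records=1979

res <- query_conservation(idx, "chr1", 1000, 1200, 31)
table(res$count)
#>  3  4  5  6
#> 16 64 66 24
```

Of the 170 31-mers starting in `chr1:[1000,1200)`, 24 occur in all six
genomes (the pivot plus all five derived genomes), 66 in five, and so on —
counts include the pivot, so they lie in `[1, 6]`.

```r
mem_idx <- build_index(pg, flavor = "membership")
mem <- query_membership(mem_idx, "chr1", 1000, 1200, 31)
colMeans(mem$present)
#>        g2        g3        g4        g5        g6
#> 1.0000000 0.4823529 0.7235294 0.8176471 0.5529412
```

The membership query resolves the same window per genome: every 31-mer of
the window survives in `g2`, but only 48% survive in `g3`.

```r
dec <- build_index(pg, flavor = "conservation", quantiles = seq(0.2, 1, 0.2))
dec$metadata$retained_orders
#> [1] 1 2 3 4 5
head(as.data.frame(query_conservation(dec, "chr1", 1000, 1200, 31)), 3)
#>   chrom start order fraction label
#> 1  chr1  1000     2      0.4 >=40%
#> 2  chr1  1001     2      0.4 >=40%
#> 3  chr1  1002     2      0.4 >=40%
```

With quintile sampling (here every rank survives because `t' = 5`), the
query reports the largest retained rank each k-mer is certified for.

`conservation_plot(idx, "chr1", 0, 5000, 31, n_bins = 50, "cons.png")`
renders the stacked conservation histogram: per bin, stacked fractions of
k-mer starts at each conservation level, with the white area above the
stacks showing the fraction conserved in all genomes.

## Command line

The same pipeline is scriptable via the installed `exec/panmemo` Rscript
(all coordinates 0-based half-open):

```sh
panmemo simulate --length 2000 --genomes 5 --snp-rate 0.01 \
        --indel-rate 0.001 --seed 7 --out-dir pg
panmemo index --pivot pg/pivot.fa --genomes pg/g2.fa pg/g3.fa pg/g4.fa pg/g5.fa \
        --flavor conservation --out cons.parquet
panmemo query --index cons.parquet --region chr1:0-2000 --k 31 \
        --type conservation --out cons.tsv
panmemo viz --index cons.parquet --region chr1:0-2000 --k 31 --bins 40 \
        --out cons.png
panmemo export-bed --index cons.parquet --out cons.bed
```

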