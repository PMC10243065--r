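# mitobreaks

Detection of gene **dislocation** and **inversion** breakpoints between
complete mitochondrial genome sequences, directly from nucleotide
sequence — no gene annotations required.

Animal mitogenomes (~16 kb, circular, 13 protein genes + 22 tRNAs +
2 rRNAs) are frequently rearranged, and heavily rearranged genomes are
usually also heavily substituted, so the collinearity breaks between two
species' genomes are hard to locate by alignment alone — especially
breaks involving short, poorly conserved tRNA genes. `mitobreaks` is for
researchers studying mitochondrial gene-order evolution who need
breakpoint coordinates for genomes whose annotations are absent or
untrustworthy.

## Method in brief

All genomes are indexed in a **position-annotated colored de Bruijn
graph**: k-mer vertices, and one edge per (k+1)-mer occurrence annotated
with genome ("color"), end position *p* (the edge spans `[p-k, p]`,
circularly) and optionally strand. A dislocation breakpoint — an
adjacent gene pair `(g_i, g_j)` of one genome whose members are not
adjacent in that order in the other — appears as a *breakpoint bulge*: a
short single-color branch (the breakpoint genome's transition
(k+1)-mers) against a long color-alternating branch. Each breakpoint
`(g_i, g_j)` is accompanied by two *entangled* breakpoints of the
opposite direction, whose bulges share its defining paths; the detector
exploits this to assemble bulges without graph traversal, then filters
candidates through banded local alignments of the bulge flanks
(accepted iff E-value ≤ 1e-5 with ≥ 20 perfectly matching nucleotides),
anchor chaining on the alternating branch, a homology screen of the
single-color branch, and complete-linkage clustering of shifted
duplicates. Inversions are found on a two-stranded graph as paired
opposite-strand (k+1)-mer runs whose spans agree within δ = 10% and
whose segments pass a normalized global alignment score
`(a - a_min)/(a_max - a_min) ≥ 0.8`. The k-mer size is chosen
automatically as the smallest k with per-genome (k+1)-mer repeat rate
≤ 0.15.

The package also ships the synthetic benchmark the method is validated
on (HKY-substituted children of a typical metazoan parent, random gene
dislocations and inversions with exact ground truth) and the evaluation
machinery (one-to-one matching with max-aggregated circular positional
error, empirical distribution functions, 75%-overlap inversion scoring,
breakpoint plots). See the vignette `vignettes/breakpoint-detection.Rmd`
for the full model description and parameter rationale.

## Worked example

Simulate two children of one parent at substitution rate 3 per 100
sites with one random gene dislocation each, detect breakpoints, and
score them against the exact truth:

```r
library(mitobreaks)
library(data.table)

set <- make_dislocation_benchmark(r_sub = 3, n_ra = 1, n_children = 2,
                                  seed = 42)
preds <- detect_dislocations(set$children)
head(preds[, 1:7], 3)
#>        r_b     r_o break_start break_end break_len other_left other_right
#> 1: child01 child02        4429      4449        20       4439        6397
#> 2: child01 child02        4503      4533        30       6471        4441
#> 3: child01 child02        6461      6480        19       6400        6470
nrow(preds)
#> [1] 12

reports <- lapply(unique(paste(set$truth$r_b, set$truth$r_o)), function(key) {
  ids <- strsplit(key, " ")[[1]]
  match_predictions(preds[r_b == ids[1] & r_o == ids[2]],
                    set$truth[r_b == ids[1] & r_o == ids[2]],
                    set$children[[ids[1]]]$length,
                    set$children[[ids[2]]]$length)
})
edf <- breakpoint_edf(reports)
edf
#> <breakpoint_edf> 12/12 matched; EDF(0)=0.000 EDF(50)=1.000
edf(50)
#> [1] 1
```

The two children differ by two gene moves, i.e. 6 true breakpoints per
direction (12 ordered-pair breakpoints); all 12 are recovered with
positional error below 50 nt — `EDF(d)` is the fraction of true
breakpoints matched within `d` nt, normalized by the number of true
breakpoints.

Inversions, analogously:

```r
set <- make_inversion_benchmark(r_sub = 3, seed = 1)   # 8 true blocks
ibs <- detect_inversions(set$children)
evaluate_inversions(ibs, set$truth, set$children)      # 75%-overlap rule
#> [1] 8
```

A command-line interface wraps the same functions
(`exec/mitobreaks auto-k | detect-dislocations | detect-inversions |
simulate | evaluate | plot`); every run writes a JSON manifest of its
parameters.

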