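# qpcrStability

Choosing reference genes for qRT-PCR normalization in a multi-organ,
multi-stage experimental design. The package is aimed at molecular
biologists validating normalization panels (the motivating system is a
perennial medicinal plant sampled over 3 vegetative organs × 5 growth
stages): it screens candidate genes from an RNA-seq abundance matrix and
ranks them for expression stability from replicate Ct tables, using the
three algorithms the field treats as standard plus a consensus ranking.

## What it computes

**Screening** (from an RPKM-like gene × sample matrix): per-group
coefficient of variation and maximum fold change,

    CV = 100 · SD / mean        MFC = max / min

per gene within each organ (across stages) and each stage (across
organs), an abundance window filter (default 50–500), and a threshold
screen (CV ≤ 20 %, MFC ≤ 1.50 at printed precision) whose per-group union
defines the candidate set.

**Stability ranking** (from a gene × well Ct matrix with technical
replicates):

* *geNorm* — relative quantities `Q = E^(minCt − Ct)`, M values (mean
  pairwise SD of log2 quantity ratios), stepwise exclusion to the most
  stable pair, and the pairwise variation `V(n/n+1)` of successive
  normalization factors, with the conventional 0.15 cutoff deciding how
  many reference genes are needed.
* *NormFinder-style model* — per-sample centering on the log2 scale,
  bias-corrected intra-group variance estimates, shrunken inter-group
  differences, and a combined stability value
  `ρ = mean_g(|d̃| + sqrt(γ̂²/K))` (grouped) or `ρ = γ̂` (ungrouped).
* *BestKeeper* — per-gene Ct dispersion (SD as mean absolute deviation,
  CV %), the geometric-mean Ct index, and each gene's Pearson r against
  it; ranking by (CV, SD) with the classic 10-gene input cap.
* *Consensus* — geometric mean of the available per-method ranks.

A synthetic-data generator (`simTruth()`, `simulateExpression()`,
`simulateCt()`) plants per-gene log2 noise, organ/stage offsets and
replicate error with a known implied stability order (`truthRanking()`),
so every algorithm is validated against ground truth. See the vignette
`vignettes/reference-gene-stability.Rmd` for the models, parameter
meanings and design choices.

## Worked example

```r
library(qpcrStability)

# Screen the shipped published per-group CV/MFC table: the 10 classical
# housekeeping genes are exempted, the screen recovers the 10 novel genes.
fx  <- table1Fixture()
screenCandidates(fx, exclude = unique(fx$gene[fx$housekeeping]))
#> ScreeningReport: 108 (gene, group) cells, 10 candidate gene(s)
#>   thresholds: CV <= 20.00%, MFC <= 1.50 (rounded to 2 dp), >= 1 group(s)
#>   exempt from screen: ACT1, GAPDH, 18S rRNA, UBQ, bTUB, aTUB, CYP, eIF-5A, F-box, EF-1a
#>   candidates: CDP, 30S RPS20, SAR1, 6-PG, ARF, V-ATP, 60S RPL13, QCR, pol IIa, TCTP

# Full pipeline on a synthetic 20-gene, 3 organ x 5 stage x 3 replicate
# Ct table with planted stability structure:
tr  <- defaultSimTruth(seed = 7)
res <- runPipeline(simulateCt(tr))
res$sets$total$genorm
#> GenormResult: 20 genes
#>   most stable pair: 6-PG / 60S RPL13 (M = 0.1373)
#>   recommended number of reference genes (V < 0.15): 2
res$sets$total$normfinder
#> NormfinderResult (grouped): 20 genes; most stable: 30S RPS20 (0.0753)
res$sets$total$bestkeeper
#> BestkeeperResult: 10 genes, 15 samples in index; best: 6-PG (CV 0.315% +/- SD 0.071)
head(res$sets$total$ranking@table[
  order(res$sets$total$ranking@table$final_rank), ], 5)
#>         gene genorm normfinder bestkeeper aggregate final_rank
#> 13 30S RPS20      3          1          2  1.817121          1
#> 12      6-PG      1          7          1  1.912931          2
#> 14 60S RPL13      1         10          4  3.419952          3
#> 20      TCTP      6          5          3  4.481405          4
#> 11       CDP      8          2          7  4.820285          5
```

Reading the output: the geNorm M of 0.137 for the most stable pair is
well under the usual 1.5 acceptability bound, and V2/3 below 0.15 says
two reference genes suffice for this (synthetic) data set. All three
methods put planted low-noise candidates at the top — here `30S RPS20`
and `6-PG`, whose planted log2 SDs (0.12, 0.15) are among the smallest —
while the noisy housekeeping genes fall to the bottom. `res$sets` also
holds the per-organ and per-stage analyses (nine sets in total).

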