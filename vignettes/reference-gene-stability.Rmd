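---
title: "Selecting stable qRT-PCR reference genes: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting stable qRT-PCR reference genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpcrStability)
```

# The problem

Relative quantification by qRT-PCR divides every measurement by the signal
of one or more *reference genes* assumed to be constitutively expressed.
When that assumption fails, every downstream fold change inherits the
reference's instability. This package implements the standard two-step
workflow for choosing references in a multi-organ, multi-stage plant
design (the motivating system is a perennial medicinal herb sampled over
three vegetative organs and five growth stages, 15 libraries in total):

1. **Screening** candidate genes from an RNA-seq abundance matrix
   (RPKM-like units) by an expression window and per-group dispersion
   statistics.
2. **Stability ranking** of the shortlisted candidates from replicate Ct
   measurements by three complementary algorithms — geNorm, a
   NormFinder-style variance model, and BestKeeper — combined into a
   consensus order.

Because the motivating study's raw RPKM and Ct matrices were never
deposited, the package ships (a) the study's printed per-group CV/MFC
screening table as a data fixture (`table1Fixture()`), and (b) a
synthetic-data generator with planted ground truth
(`simTruth()` / `defaultSimTruth()`) so that every algorithm can be
validated against a known stability order. The study's downstream
headline values (e.g. its all-sample geNorm M range 0.31–0.89 or
V2/3 = 0.145) are consequently *not* reproducible and are nowhere
asserted; what the tests pin down instead is the in-table screening
recomputation and the algorithms' behaviour on data with known truth.

# Screening model

For gene $i$ in sample group $g$ (one organ across all stages, or one
stage across all organs) with abundances $x_1, \dots, x_k$:

$$\mathrm{CV}_{ig} = 100\,\frac{s_{ig}}{\bar x_{ig}}, \qquad
  \mathrm{MFC}_{ig} = \frac{\max_j x_j}{\min_j x_j},$$

with $s$ the $n-1$ sample SD (a population-SD switch exists,
`sdDenominator = "n"`; the choice is not derivable from printed tables,
and $n-1$ is the convention). A gene is a candidate when, in at least
`minGroups` groups, both statistics — *rounded to two decimals* — are
$\le$ the thresholds (defaults CV ≤ 20 %, MFC ≤ 1.50).

Two deliberate choices here:

* **Rounded `<=` rather than strict `<` at full precision.** Published
  screening tables list passing genes whose printed MFC is exactly 1.50;
  a strict comparison at full precision would contradict the very tables
  the thresholds produced. Comparing at printed precision reproduces the
  published candidate sets and makes the rule well-defined for users who
  type thresholds as decimals.
* **Housekeeping exemption.** Classical housekeeping genes are typically
  carried into the qPCR panel regardless of their screening statistics
  (they are the incumbents being challenged). `screenCandidates()`
  therefore takes an `exclude` list: those genes are reported but not
  eligible as "novel" candidates.

The expression window (default 50–500 RPKM-like units) is applied to
*per-group means* (`scope = "group_means"`); applying it per sample is
available but stricter than the screening tables imply. The window's
purpose is to drop both weakly expressed genes (noisy Ct) and
rRNA-scale transcripts whose abundance saturates cDNA input.

# geNorm

Relative quantities are
$Q_{is} = E_i^{\,\min_s \mathrm{Ct}_{is} - \mathrm{Ct}_{is}}$ with $E_i$
the amplification efficiency (default 2.0, perfect doubling, used when no
efficiency file is supplied). The pairwise stability of genes $j,k$ is
$V_{jk} = \mathrm{SD}_s\!\left[\log_2 (Q_{js}/Q_{ks})\right]$ and the M
value of a gene is the mean of its pairwise stabilities within the active
set. The least stable gene (highest M) is removed and M recomputed until
two genes remain — the most stable pair, which shares rank 1 (the pair
cannot be ordered internally by this criterion, so rank 1 is *not*
split; within the pair, genes are listed in input order).

Normalization factors are geometric means of the top-$n$ genes'
quantities, and $V(n/n{+}1) = \mathrm{SD}_s\!\left[\log_2
(\mathrm{NF}_n / \mathrm{NF}_{n+1})\right]$; the smallest $n$ with
$V < 0.15$ (the conventional cutoff, configurable) is the recommended
number of reference genes, with an explicit "not achieved" state (NA)
when no $n$ reaches it.

Numerical choices: ties on M (exactly proportional genes) are broken by
excluding the gene *later in input order*, which makes the full analysis
deterministic and order-stable; genes with missing wells are dropped
before analysis with a warning (the algorithm requires a complete
matrix), and an all-missing gene is an error rather than a silent drop.

# NormFinder-style variance model

Working on a log2 scale ($y = -\mathrm{Ct}$ by default, which equals
log2 expression up to a per-gene constant when $E = 2$; an
efficiency-corrected $y = \log_2 Q$ input is available), every sample is
centered across genes: $z_{is} = y_{is} - \bar y_{\cdot s}$. Centering
removes the sample's loading but mixes a $1/n$ share of every gene's
noise into every other gene, so the naive within-group variance
$v_{ig}$ of a centered row is biased:

$$\mathbb E[v_{ig}] = \gamma^2_{ig}\left(1 - \tfrac{2}{n}\right)
  + \tfrac{1}{n^2} \sum_k \gamma^2_{kg}.$$

Inverting this gives the estimator implemented here,

$$\hat\gamma^2_{ig} = \max\!\left(0,\;
  \frac{v_{ig} - \frac{1}{n(n-1)}\sum_k v_{kg}}{1 - 2/n}\right),$$

which is unbiased before the flooring at zero (the package's Monte-Carlo
test checks the simulation mean over 10,000 draws against the planted
variance to within 2 %; flooring is a reporting choice, disabled via
`floor = FALSE`, and the number of floored cells is attached to the
result). The correction denominator $1 - 2/n$ is why at least three
genes are required.

Inter-group differences $\hat d_{ig}$ (group means of $z$ minus their
per-gene average; zero-sum across groups) are shrunken toward zero by
$\tilde d_{ig} = \hat d_{ig}\,\hat\tau^2_i / (\hat\tau^2_i +
\hat\gamma^2_{ig}/K_g)$, where $\hat\tau^2_i$ is the excess of the
observed between-group variance of $\hat d_{ig}$ over its sampling noise
(floored at zero; the $n-1$ sample variance over groups is used, a
convention this package fixes and tests since it is not derivable from
published material). The stability value is

$$\rho_i = \frac{1}{G}\sum_g \left( |\tilde d_{ig}| +
  \sqrt{\hat\gamma^2_{ig}/K_g} \right)$$

in grouped mode, and $\rho_i = \hat\gamma_i$ (all samples as one group)
in ungrouped mode. The exact shrinkage constant of the original
closed-source applet is unverifiable; this package's variant is fully
documented above and pinned by its own tests rather than by fidelity to
the applet's numeric output.

# BestKeeper

Descriptive per-gene Ct statistics with `sd` defined as the *mean
absolute deviation around the arithmetic mean* (the method's convention;
classic $n-1$ SD via `sdMethod = "classic"`), CV as percent of the mean
Ct, the per-sample index as the geometric mean Ct of the candidate set,
and each gene's Pearson correlation with the index (two-sided p from the
t distribution with $n-2$ df). Ranking is by CV with SD as tie-break.
The historical 10-gene limit of the original tool is enforced as a
default cap but is configurable — the limit is a software artifact, not
statistics; the pipeline mirrors common practice by feeding BestKeeper
the top 10 genes of each set's geNorm ranking, and genes outside that
capped input appear as missing ranks in the comparison table.

# Consensus and pipeline

The per-method ranks (geNorm pair sharing rank 1; NormFinder and
BestKeeper ranks ascending in their stability values) are aggregated by
the geometric mean of the ranks available for each gene —
RefFinder-style; an arithmetic-mean option exists — with ties broken by
the geNorm rank, then input order. Aggregation is monotone: improving
any single rank can only improve the aggregate.

`runPipeline()` derives the sample sets from the design table rather
than hard-coding them: the total set plus one set per organ and one per
stage (nine sets under the 3 × 5 design). The total set runs NormFinder
grouped by organ; the single-organ and single-stage subsets run
ungrouped, because their design cells contain one sample each and
grouped variances would be undefined. Reports are written with fixed
formatting through binary-mode connections, so identical inputs yield
byte-identical files — reproducibility is testable at the byte level.

# The synthetic-data generator

`simTruth()` plants, per gene: a baseline abundance (and a baseline Ct,
by default tied to abundance via $\mathrm{Ct} = 34 - 1.7\log_2(\text{RPKM})$,
placing typical genes at 19–24 cycles and an rRNA-scale gene near 15),
a log2-scale residual SD $\gamma_i$, additive organ and stage offsets
(log2), a shared per-sample effect (SD 0.05 log2 units), and technical
replicate noise on the Ct scale (SD 0.15 cycles; triplicates). Noise is
Gaussian on the log2/Ct scale — the standard qPCR error model — with an
optional heavy-tail contamination (`tailProb`) for robustness checks.
The implied truth (`truthRanking()`) orders genes by
$\gamma_i^2$ plus the population variance of their summed group offsets
across design cells.

`defaultSimTruth()` emulates the motivating study's structure: 20 genes
(10 classical housekeeping genes with larger residual SDs, 0.30–0.90,
and modest organ/stage shifts; 10 novel candidates with SDs 0.08–0.15
and no planted shifts), the rRNA gene's abundance baseline in the
thousands so the 50–500 window excludes it, 3 organs × 5 stages × 3
technical replicates. These values were fixed once as a realistic
emulation of the study's qualitative description (housekeeping CVs
ranging from a few percent to near 90 %, novel candidates under 20 %)
and are deliberately not tuned per analysis.

What the generator does *not* emulate — and therefore what passing tests
cannot certify about real data: count-based sampling noise at low
abundance, amplification inhibition and efficiency drift across runs,
plate/batch effects, correlated co-regulation between genes, and
non-factorial or unbalanced designs. Recovery results on synthetic data
show the algorithms are implemented correctly, not that any particular
real gene is stable.

# Problem sizes and numerical tolerances

The test suite validates the geNorm quantities against a brute-force
oracle on 200 random matrices of up to 6 genes × 8 samples (agreement to
1e-10), checks the variance estimator's unbiasedness over 10,000
3-gene draws and its median relative bias (< 5 %) at 10 genes × 50
samples over planted variances {0.01, 0.1, 0.5}, and measures
planted-worst-gene recovery over 200 seeded runs of a 6-gene × 15-sample
design (≥ 95 % required per method). These sizes keep the full suite
within a couple of minutes on one CPU while leaving the Monte-Carlo
standard errors well below the asserted margins.

# Known limitations

* Single-factor grouping only: the variance model treats organ *or*
  stage as the grouping factor, not an organ × stage interaction model.
* Ct values are assumed already baseline-corrected by the instrument;
  no raw fluorescence processing.
* The NormFinder-style values are this package's documented variant and
  will not numerically match the original Excel applet; rankings on
  clearly separated data agree (tested via rank correlation with geNorm).
* Screening operates on printed-precision statistics when fed published
  tables; recomputation from raw matrices uses full precision ahead of
  the final rounded comparison.
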