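---
title: "Partitioning super-enhancers by methylation dynamics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning super-enhancers by methylation dynamics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model, the fixed thresholds and their
rationale, the synthetic-data generator, and the numerical and design
decisions made where the underlying methodology leaves room for
interpretation. It states no empirical results; all quantitative claims about
the package's behaviour are established by the test suite
(`tests/testthat/`) and the acceptance script (`scripts/acceptance.R`).

## The segmentation model

Bulk bisulfite sequencing yields, per CpG, a methylated read count and a
total read count. We model the latent methylation state of consecutive CpGs
as a two-state Markov chain — U (unmethylated) and M (methylated) — with
binomial emissions: given state $s_t$ and coverage $n_t$, the methylated
count is $\mathrm{Binomial}(n_t, \mu_{s_t})$ with a state-specific latent
fraction $\mu_U < \mu_M$. Optional extensions are beta-binomial emissions
(a per-state dispersion parameter for overdispersed libraries) and a
Gaussian-on-fraction mode kept for parity with fraction-based callers.

Training is Viterbi-EM (segmental k-means): decode the current best path,
re-estimate initial, transition and emission parameters from the hard state
assignments, and repeat. The objective — the joint log-likelihood of the
decoded path — is non-decreasing across iterations, which the test suite
checks directly. Defaults: at most 100 iterations, convergence tolerance
$10^{-6}$, initial self-transition probability 0.95, emission means seeded
from the lower/upper terciles of the observed fractions. Fitting is per
chromosome; ties in the Viterbi recursion resolve toward U so that decoding
is deterministic. After every M-step the states are relabelled if necessary
so that $\mu_U < \mu_M$ always holds.

A signed per-CpG score in $[-1, 1]$ summarises calls for browsing: state M
maps to $+$fraction, state U to fraction $- 1$.

## Partition rules and thresholds

The fixed thresholds are the pipeline's standard values; they are exposed as
arguments everywhere and recorded in every run log.

- **Coverage ≥ 7 reads** per CpG: below this, a binomial call cannot
  separate fractions 0.1 from 0.9 reliably.
- **Segments**: CpGs spaced < 1 kb chain into segments; segments with fewer
  than 10 CpGs are dropped. Runs never cross segment boundaries or ≥ 1 kb
  gaps, so sparse CpG deserts cannot bridge unrelated evidence.
- **Runs ≥ 4 consecutive CpGs**: the smallest unit accepted as a coherent
  unmethylated (or jointly U-then-M) subregion. Run spans extend from the
  first to the last CpG, with the end placed one dinucleotide (2 bp) past
  the last CpG start.
- **PU** is the base-pair intersection of the two conditions' unmethylated
  runs; **DM** requires ≥ 4 consecutive CpGs covered in *both* conditions
  that are U in naive and M in primed, and is trimmed wherever it overlaps
  PU (precedence PU > DM, so a base is never labelled twice); **INT** is the
  SE complement. This makes the partition of every SE exact: disjoint and
  covering, which is asserted on every synthetic run.
- Methylation level of any region is the pooled read-level ratio
  $\sum \text{meth} / \sum \text{total}$, not the mean of per-CpG fractions,
  so deeply covered CpGs carry proportionally more weight.

One deliberate consequence of defining PU by base-pair intersection: a thin
intersection sliver can contain fewer than 4 CpGs of its own even though
both parents had ≥ 4. The `strict_pu` flag re-imposes the CpG minimum on the
intersection for users who prefer symmetrical rules; the default keeps the
intersection because both parent runs independently satisfied the evidence
threshold.

## Downstream modules

**Expression link.** The predicted expression change of the gene linked to a
subregion is $\Delta X = \log_2(\text{normalised contact reads}) \times
(\%\text{CpG}_{naive} - \%\text{CpG}_{primed})$. Genes are "expressed" at
RPKM ≥ 1; each SE is linked to the closest expressed promoter (5-kb windows
centred on the TSS; edge distance, deterministic lexicographic
tie-breaking).

**Capture Hi-C.** Restriction fragments merge into pseudo-fragments of 4
(remainder flagged); interactions need score ≥ 5 and a geometric-mean
replicate coverage ≥ 5, trans contacts are dropped. Normalisation is
median-of-ratios with a per-record geometric-mean reference, estimated
separately in four distance strata ([0, 25 kb), [25, 100 kb),
[100, 300 kb), [300 kb, ∞)) because contact counts decay with distance and
a single factor would confound depth with distance composition. Note that
with an internal geometric-mean reference, size factors are identified only
up to a common scalar per stratum; the scale-free invariances (factor
ratios, normalised-count ratios) are what the tests pin down, and the
estimator itself is verified against an independent median-of-ratios
implementation. Subregion interaction frequency sums normalised reads of
overlapping fragments at native fragment resolution, assigning a fragment to
the subregion with the largest overlap; subregions narrower than 500 bp are
excluded. The class contrast is OLS of $\log_2(\text{frequency}+1)$ on class
with bait count and $\log_2$ distance as covariates (a constant covariate is
dropped with a warning). 4C-style tracks use 5-kb bins within ±1 Mb of the
viewpoint and a 7-bin running mean with partial windows at the edges; bins
under 1000 RPKM are flagged as low coverage.

**Single cells.** Per cell, DM methylation is the pooled call ratio over all
DM subregions. Cells cluster by complete-linkage hierarchical clustering on
squared differences of these averages, cut at $k = 2$; the lower-methylation
cluster is labelled naive-like. By default only serum-grown cells are
clustered (2i-grown cells keep their condition label); a joint mode labels
the 2i-containing cluster naive-like. Expression is normalised per gene by
median centring and scaling to unit standard deviation ($n-1$ denominator;
zero-variance genes are flagged and left centred); a signature score is the
per-cell mean over the signature genes. ROC curves group tied scores, so the
trapezoidal AUC equals the Mann–Whitney statistic $U/(n_1 n_0)$ exactly; the
permutation p-value uses the add-one estimator
$(1 + \#\{AUC_{perm} \ge AUC\})/(1 + n_{perm})$.

**Region features.** Coverage profiles interpolate cumulative sums into
1000 windows (fractional windows supported; minus-strand regions are
reversed). ChIP enrichment is the median over 10-bp bins of
$\log_2((\text{chip}+1)/(\text{input}+1))$. ATAC accessibility is
input-subtracted RPKM with negative values retained but flagged. CpG density
is CG dinucleotide count per bp. DM-vs-PU contrasts use univariate logistic
regressions (non-convergence or quasi-separation is an error, not a silent
estimate).

**Motifs.** Regions tile into 291-bp windows, $n = \max(1,
\mathrm{round}(len/291))$ equally spaced starts (shorter regions give one
clipped tile). PWM scanning is log-odds with pseudocount 0.01 on both
strands; ambiguous bases never match. The presence threshold is the 99%
quantile of best scores over 50,000 seeded background windows — an empirical
1% false-positive rate that is only approximate for short motifs whose score
distribution is coarse. Enrichment per class is the upper-tail
hypergeometric against the union of classes, Benjamini–Hochberg adjusted
across motifs within each class.

## The synthetic-data generator

`simulation_config()` defaults define the reference simulation: 50 SEs on
one synthetic chromosome, planted PU/DM children of 0.9–2 kb with dense CpG
spacing (20–90 bp, ≥ 10 CpGs per child by construction, infeasible draws
resampled), INT spacers, sparse background CpGs with occasional unmethylated
islands so both HMM states occur genome-wide, emission means 0.1/0.9,
negative-binomial coverage (mean 10, size 5), 16 2i + 64 serum cells whose
DM methylation follows a naive-like/primed-like Beta mixture (means
0.15/0.6, sd 0.1), class-II genes upregulated $2^2$-fold in naive-like
cells, and capture Hi-C counts with power-law distance decay ($\gamma = 1$)
and a 3× contact boost at PU/DM fragments over INT in two replicate
libraries of unequal depth.

The generator emulates the *statistical structure* the analysis assumes —
latent two-state methylation, coverage noise, mixture heterogeneity,
distance decay — not any real genome: there is no sequence composition
model (the motif driver plants sequence separately), no replicate structure
in the bulk methylomes, no batch effects, and CpG positions are independent
of the simulated sequence. Every generator is a pure function of
(config, seed) and restores the global RNG state.

## Numerical choices

- Viterbi runs in log space with an unrolled two-state recursion; emission
  means are clamped to $[10^{-6}, 1-10^{-6}]$ so log-likelihoods stay
  finite.
- Interval algebra (intersection, difference, reduction) uses sorted
  two-pointer sweeps over half-open 0-based intervals; results are checked
  against GenomicRanges in the tests. GenomicRanges is still used where its
  semantics are the point (overlap search, edge distances).
- Median-of-ratios excludes records with a zero in any library from factor
  estimation (the log-ratio is undefined there) but normalises all records.
- The hypergeometric test uses `phyper` upper tails rather than summed
  `dhyper` terms for numerical stability; tests verify exact-enumeration
  agreement for populations up to 20.

## Open questions resolved by decision

Where the methodology is underdetermined, the package picks one documented
behaviour: which normalisation feeds $\Delta X$ (the distance-binned
median-of-ratios counts; configurable by passing any column), the standard
deviation denominator in expression normalisation ($n-1$), edge handling of
the 4C running mean (partial windows), the PU sliver question above
(`strict_pu`), and chromosome naming (exact string match, no "chr"
coercion).

## Limitations

Viterbi-EM converges to a local optimum of the hard-assignment objective and
can be sensitive to initialisation in low-coverage data; the tercile seeding
assumes both states are present on each chromosome. The partition inherits
any HMM miscalls at subregion boundaries, so base-pair agreement with
planted truth is high but not exact. The clustering step assumes exactly two
serum populations; more structure requires a different cut. The motif
threshold is calibrated on the supplied genome and should be re-estimated
for any other sequence background. None of the synthetic defaults were tuned
to data from a specific organism.
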