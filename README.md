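# semethdyn

Dissecting super-enhancer methylation dynamics between naive and primed
pluripotent states.

## Scientific problem

Super-enhancers (SEs) mapped in naive embryonic stem cells are largely
unmethylated, but during the transition to the primed (epiblast-like) state
parts of them gain CpG methylation while other parts stay protected. This
package partitions each SE into three kinds of subregion from bulk bisulfite
sequencing of the two states:

- **PU** (persistently unmethylated): unmethylated in both states;
- **DM** (differentially methylated): unmethylated in the naive state,
  methylated in the primed state;
- **INT** (interstitial): methylated in both states.

SEs with at least one PU subregion are **class I**; SEs whose only
unmethylated naive subregions are DM are **class II**. Downstream modules
link the partition to gene expression through promoter capture Hi-C
contacts, quantify cell-to-cell methylation heterogeneity in single-cell
bisulfite data, evaluate gene-expression signatures by ROC/AUC, quantify
ChIP/ATAC features over subregions, and test transcription-factor motif
enrichment per subregion class. A synthetic-data generator with planted
ground truth supports end-to-end recovery testing of every stage.

## Core model

Per-CpG methylated/total read counts are modelled by a two-state hidden
Markov model with binomial emissions (states U and M with distinct latent
methylation fractions), trained per chromosome by Viterbi-EM (segmental
k-means: decode the best path, re-estimate parameters from the hard
assignments, repeat until the path log-likelihood stabilises). The partition
then proceeds on CpGs with coverage ≥ 7 reads, grouped into segments of ≥ 10
CpGs spaced < 1 kb:

- unmethylated **runs** are ≥ 4 consecutive U-state CpGs within a segment;
- **PU** = base-pair intersection of the two conditions' runs;
- **DM** = runs of ≥ 4 CpGs jointly U in naive and M in primed (on CpGs
  covered in both), minus any PU overlap;
- **INT** = the SE minus (PU ∪ DM).

The predicted expression change of a gene linked to a subregion is
`∆X = log2(normalised contact reads) × (%CpG naive − %CpG primed)`, so a
methylation gain at a strongly contacted subregion predicts downregulation.

## Worked example

```r
library(semethdyn)

truth <- simulate_architecture(simulation_config(), seed = 1)  # 50 SEs
rec_a <- simulate_bulk_bsseq(truth, "A", seed = 1)  # naive
rec_b <- simulate_bulk_bsseq(truth, "B", seed = 1)  # primed
res <- partition_superenhancers(rec_a, rec_b, truth$ses)

table(res$subregions$class)
#>  PU  DM INT
#>  53  67 170
table(res$se_classes$class)
#>   I  II
#>  32  18
```

Against the planted architecture this run recovers 53/53 PU and 67/68 DM
subregions with 92.8% base-pair label agreement, and the pooled methylation
levels behave as the classes require (PU: 0.100 naive / 0.095 primed;
DM: 0.104 naive / 0.896 primed).

The ∆X arithmetic on the worked numbers:

```r
predicted_expression_change(8, 10, 80)   # 3 * (10 - 80)
#> [1] -210
```

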