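---
title: "Methods: GA/KNN gene signatures, co-expression ranking and seed-site scanning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GA/KNN gene signatures, co-expression ranking and seed-site scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

`metasig` implements a three-part analysis for finding gene-expression
signatures that separate primary melanoma from regional cutaneous/subcutaneous
metastases, and for following up one candidate gene:

1. **GA/KNN feature-set selection** with resampled train/test evaluation and
   gene selection-frequency ranking;
2. **anchor-gene co-expression**: Spearman correlation tables per sample
   group, threshold selection, and rank-product aggregation across datasets;
3. **a combinatorial miRNA seed-site scanner** with a single allowed G:U
   wobble pair.

All three stages run on synthetic data generated by the package itself, so
every statistical property claimed below is checked by the test suite on
data whose ground truth is known.

```{r setup}
library(metasig)
```

## Input scale and transform

Expression input is a genes × samples matrix of normalised read counts (per
million mapped), as distributed in TCGA level-3 tables. Values below 1 are
floored at 1 and the matrix is log2-transformed once — so zeros map to 0 and
the transformed scale is non-negative — with no further normalisation. The
`expr_matrix` container records the transformed state and refuses a second
transformation; duplicate gene or sample identifiers and missing values are
hard errors rather than guesses, because level-3 matrices are complete and
symbol disambiguation is out of scope.

## The GA/KNN model

A *chromosome* is a set of exactly `L` distinct genes (sets, not ordered
lists: k-nearest-neighbour classification is order-blind, so crossover and
mutation repair duplicates by substituting random unused genes). Its
*fitness* is the leave-one-out cross-validated (LOOCV) accuracy of a
k-nearest-neighbour classifier restricted to those genes on the training
fold:

- distances are Euclidean on per-gene standardised values; the gene mean and
  SD are estimated on training samples only, and during LOOCV they are
  recomputed excluding the held-out sample. Standardisation makes distances
  scale-invariant across genes; `standardize = FALSE` is available because
  the convention is not universal in the GA/KNN literature. Zero-variance
  genes get zero weight at that fold rather than dividing by zero.
- the `k = 5` nearest training samples vote; the majority label wins. With
  two classes and odd `k` a tie is impossible, but the tie-break (label of
  the single nearest neighbour) is defined anyway. Distance ties break by
  ascending sample index, which makes results independent of sort
  implementation details.

The genetic algorithm uses rank-proportional parent selection, uniform gene
exchange, per-slot mutation, and elitism. These operator choices are not part
of the published parameterisation of the method (which fixes `L = 20`,
population 300, up to 1000 generations, `k = 5`, 5000 collected sets); they
are declared in `ga_config()` and logged with every run so results are
reproducible. A run terminates at the first chromosome whose LOOCV fitness
reaches `fitness_threshold` — the *near-optimal* criterion, default 0.95 at
full scale — or at the generation cap, returning the best chromosome found
and recording which criterion fired. "Near-optimal" is our auditable
interpretation of a stopping rule the original description leaves open.

The two shipped configurations are:

| parameter | `paper.yaml` | `desk.yaml` |
|---|---|---|
| chromosome length L | 20 | 5 |
| population P | 300 | 50 |
| generation cap | 1000 | 20 |
| k | 5 | 5 |
| collected sets | 5000 | 200 |
| fitness threshold | 0.95 | 0.90 |

The desk scale is what the test suite and the acceptance script run: signal
recovery there converges in a handful of generations, and a cap of 20 keeps
label-permuted (null) runs bounded. The LOOCV/KNN kernels are implemented in
C++ (the method's original implementations are C programs) because the GA
evaluates tens of thousands of candidate sets per analysis.

## Resampled evaluation

Samples are split 100 times (at full scale) into 75% training / 25% testing.
Splits are stratified by class with per-class round-half-up — for a 74 + 66
cohort this gives 56 + 50 = 106 training and 34 testing samples — because
stratification keeps per-class summary rows meaningful in every fold;
`stratify = FALSE` gives the literal unstratified reading. Each sample
therefore appears about 75 times in training and 25 times in testing.

For one partition, every collected feature set classifies every sample:
training samples via LOOCV inside the training fold, testing samples against
the full training fold. A sample's score in a partition is the *fraction* of
feature sets that classified it correctly (5000 sets = 5000 classifications);
its overall training and testing accuracies are the arithmetic means of
those fractions over its training and testing appearances. We average
fractions rather than binarising each partition's majority call — the
fraction reading follows from counting each set as one classification, and
is the finer-grained statistic. Summaries report min, quartiles (linear
interpolation, `quantile` type 7 — the convention is not fixed by the
source), median, mean and max per class and overall. Genes are then ranked
by how often they appear across all sets and partitions, ties broken
lexicographically.

A worked desk-scale example:

```{r pipeline}
sim <- simulate_expression(c(60, 60), n_genes = 300, n_informative = 5,
                           delta = 2, sigma = 1, seed = 11)
ev <- run_gaknn_evaluation(sim$matrix, desk_config(), n_partitions = 4,
                           seed = 101)
glance(ev)
head(ev$gene_frequency, 8)
sim$truth$informative_genes
```

All five planted genes top the frequency table. Note the gap between mean
training and testing accuracy: sets are *selected* for training-fold LOOCV
performance, so their training scores are optimistically biased while the
held-out scores are not. At these settings (threshold 0.9, `delta = 2σ`)
collected sets typically carry two of the five planted genes plus noise
genes, which caps held-out accuracy near 0.87–0.89; pushing the threshold up
pushes both the number of planted genes per set and the test accuracy up.
This selection-optimism gap mirrors the training-vs-testing gap the method
reports at full scale.

## What the simulator does and does not emulate

`simulate_expression()` draws background genes as Normal(mu_g, sigma²) on
the log2 scale with baselines mu_g uniform in [2, 10]; informative genes add
a shift `delta` to one class; a correlated block is built as
`rho · z_anchor + sqrt(1 − rho²) · noise` against an anchor gene. This
exercises exactly the statistics the pipeline consumes (class separation on
a log scale, rank correlation structure) and nothing else: no count-level
noise, no batch effects, no tumour purity gradients, no gene-gene
correlation beyond the planted block. Passing tests therefore demonstrate
the machinery is correct and calibrated on its own assumptions, not that
real cohorts will reach any particular accuracy. `simulate_utr()` plants
perfect and one-wobble seed complements in uniform random RNA; real 3'UTRs
have composition bias the background-rate test deliberately ignores.

Default condition choices (60 + 60 samples, 300 genes, 5 informative at
`delta = 2σ`, block of 20 at `rho = 0.8`) are the simulation study's fixed
design: large enough that recovery is expected, small enough to run on one
CPU in minutes.

## Co-expression and rank aggregation

`correlate_anchor()` reports the Spearman correlation (Pearson on midranks)
of every gene with a designated anchor, pooled and per sample group, plus
the unweighted mean of the per-group coefficients — the reading of a
per-site "Average" column that matches its printed rows. Genes at pooled
`|r| ≥ 0.5` are the conventional strong-correlate lists. The group
comparison test is Welch's two-sided t test (the safer default when the
variance-equality assumption is undeclared; the pooled-variance test is a
flag away).

For cross-dataset aggregation the per-dataset descending-correlation ranks
are combined by their geometric mean (the rank product, normalised by the
D-th root), a parameter-free robust aggregation; a median-rank alternative
is exposed. The published analysis names only "a robust ranking method", so
the rank product is declared here as our interpretation. Genes absent from
any dataset are dropped (rank products are undefined on missing ranks), with
the dropped count reported.

## Seed-site scanning

The seed is the first 8 nucleotides of the mature miRNA 5'→3' (a
position-2 offset is a flag, since both seed conventions exist). An 8-nt
target window starting at 0-based position `s` pairs antiparallel: target
position `s + 7 − j` against seed position `j`. Each pair is Watson-Crick
(A:U, U:A, G:C, C:G), wobble (G:U, U:G) or mismatch. A putative site needs
at least 7 of 8 positions complementary, where at most one G:U pair may
count as complementary; further wobbles count as mismatches — the literal
reading of "one G:U pairing allowed". Overlapping windows are all reported,
each window at most once; only the given strand is scanned; DNA input is
normalised T→U; IUPAC ambiguity codes are rejected.

```{r scan}
sp <- seed_spec("UGAUUGGUACGUCUGUGGGUAG", mirna_id = "miR-509-3p")
scan_seed_sites(paste0("CCC", "ACCAAUCA", "GGG", "ACCAAUCG", "CCC"), sp)
```

The first hit is the perfect antiparallel complement of the seed; the
second carries one G:U wobble (7 WC + 1 GU). The test suite checks the
scanner against a brute-force enumerator on random sequences and against
the exact 4^8 window-enumeration background rate.

## Numerical and degenerate-input choices

- Rounding for the 75% split: per-class round-half-up, remainder to testing.
- Quartiles: `stats::quantile` type 7 (linear interpolation).
- Constant vectors make Spearman undefined: flagged `NA`, never 0.
- Zero-variance genes in a fold contribute zero distance.
- One master seed drives everything; GA runs and partitions use
  pre-drawn substream seeds so results are reproducible and independent of
  evaluation order.
- `n_sets = 0` returns an empty, correctly-typed table; a gene universe of
  exactly L genes returns the only possible chromosome without search.

## Known limitations

- Two classes only; the four-way classification of all melanoma tissue
  sites is explicitly out of scope (the source analysis abandoned it).
- No GO-term enrichment, no thermodynamic or conservation scoring of seed
  sites, no miRNA expression matrices.
- The GA operator suite and the near-optimal threshold are declared
  defaults, not recovered constants of the original C implementation.
- Desk-scale runs use 4 partitions × 50 sets; full-scale settings
  (100 × 5000) are configuration, not code, but take CPU-days.
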