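---
title: "Modeling sort-seq fitness landscapes with sortscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling sort-seq fitness landscapes with sortscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sortscape)
library(dplyr)
```

## The measurement problem

Deep mutational scans of fluorescent proteins couple three layers of
machinery: a barcoded mutant library built by error-prone PCR, FACS
sorting of expressing cells into eight gates by green intensity, and
sequencing of the sorted pools so that each barcode's distribution of
reads across gates reveals its fluorescence. `sortscape` implements the
complete computational side of such an experiment — and, because the
real datasets are large and noisy in ways that are hard to audit, it
also implements a generative model of the entire experiment, so every
stage can be tested against a known ground truth.

## The ground-truth landscape

A `landscape` maps a protein genotype to a log10 fluorescence:

* every mutant state at every site carries an **additive effect**, drawn
  from a neutral-or-deleterious mixture: with probability `p_neutral`
  the effect is Normal(0, 0.02); otherwise it is minus an Exponential
  with mean `deleterious_scale`. This two-knob mixture reproduces the
  empirical single-mutant picture: most mutations are neutral or
  mildly deleterious, a tail is severe.
* a fraction `epistasis_density` of residue *pairs* carries an
  **epistatic term** (magnitude Exponential(`epistasis_scale`), sign
  negative with probability `epistasis_negative_bias`) that is added
  whenever both sites are mutated, whatever the states. Terms are kept
  at site-pair granularity rather than state-pair granularity: with
  only ~4 substitutions per genotype, state-pair-keyed terms would
  essentially never be encountered twice, making epistatic density
  uncontrollable, and the cross-landscape sharing analyses operate at
  the site-pair level anyway.
* the summed **fitness potential** passes through a normalized sigmoid,

  `F = F_dark + (F_wt - F_dark) * plogis(s (p - m)) / plogis(-s m)`,

  so the wildtype (potential 0) maps exactly to `F_wt`. Genotypes
  mutating one of the three chromophore residues, or carrying a
  premature stop, are forced to `F_dark` outright.

Defaults are `F_dark = 1.8`, `F_wt = 4.2` with gate boundaries at
2.0–4.4 in steps of 0.4: a distinct dark mode, a wildtype mode inside
gate 7, and seven boundaries spanning the observed wildtype range of
real GFP scans. The per-cell log10 noise SD is 0.2, which spreads one
genotype's cells over two to three gates — enough for the gate fit to
identify both location and spread — while keeping the two fluorescence
modes more than six noise SDs apart.

### Flat and sharp presets

Two presets encode the contrast between mutationally robust ("flat")
and fragile ("sharp") fitness peaks:

* `sharp`: strong additive effects (`deleterious_scale = 0.9`), dense
  negative epistasis (25% of site pairs), and a steep threshold
  (`steepness = 6`, `midpoint = -2`). Function collapses after few
  mutations (loss-of-function LD50 ≈ 3.4 at the default scale), and the
  wildtype plateau hides moderate deleterious effects from
  fluorescence-scale measurements — the source of conditionally neutral
  mutations.
* `flat`: the same moderate effect mixture with sparse epistasis and a
  *gentle* transform (`steepness = 2`, `midpoint = -1.2`). The decline
  is near-linear, so mutation costs stay visible in fluorescence, the
  additive expectation holds (few |epistasis| > 0.3 genotypes), and the
  peak tolerates ≈ 6 random mutations before half the genotypes go
  dark. A robust peak is not one whose mutations are huge but invisible;
  it is one where fluorescence tracks the additive cost over a wide
  margin — which is what this transform produces.

The generator is a pure function of `(length, config, seed)`. The
default protein length is 235 residues; module-level examples and tests
use 40–120 residues so that mutation recurrence per site matches the
real experiments' coverage at tractable library sizes.

## Simulating the experiment

`generate_library()` mutates the wildtype CDS at a per-base rate
calibrated analytically so genotypes carry ~4 amino-acid substitutions
on average; synonymous-only genotypes, nonsense mutants and chromophore
mutants arise naturally. Twenty known-barcode spike-in standards with
brightness levels stepped below the wildtype emulate the ortholog
wildtype controls of the real libraries; they anchor the cross-machine
calibration (a regression over anchors at a single brightness would
have no leverage on the slope).

`simulate_sort()` gives each genotype a Poisson number of
secondary-barcode replicates (mean 8), each sorted on one of two
machines (~35 cells, Poisson). Cells draw their log10 fluorescence from
Normal(truth, 0.2), are binned by the gate boundaries — machine B on an
affine-distorted scale — mis-sorted one gate over with probability
0.005, and emit Poisson-distributed reads. Count-control barcodes are
spiked at exactly 5000 cells per gate and sorter.
`simulate_coding_reads()` produces forward/reverse read pairs of two
overlapping amplicon halves with i.i.d. substitution errors across the
whole read. Quality strings are constant and indels are not simulated.

## Read processing

`call_genotypes()` applies the published consensus rules verbatim:
reads lacking the constant region next to the barcode are dropped;
per-direction, per-half consensus requires at least 5 reads per half
and at least 80% per-position agreement (an exact 50/50 tie fails);
forward and reverse consensi must agree exactly — disagreement rejects
the barcode rather than guessing; the two halves must match 100% over
their expected overlap; and calls at a different length than the
wildtype (indels) are rejected because the downstream genotype model is
substitution-only. `merge_secondary_barcodes()` absorbs secondaries
with fewer than 6 reads lying within Hamming distance 2 of a more
abundant secondary of the same primary, iterating to stability in
ascending read order with lexicographic tie-breaks for determinism.
`normalize_by_count_controls()` converts reads to cells per gate and
sorter via the mean count-control read count.

## Fluorescence inference

`fit_gate_distribution()` fits the 8-vector of cell counts to
`N * (Phi((b-mu)/sigma) - Phi((a-mu)/sigma))` over the gate bounds, the
darkest and brightest gates open-ended. The amplitude `N` is profiled
out of an unweighted least-squares objective (read counts are large
enough that Poisson weighting makes little difference, and the
published method names the fitting routine but no loss), leaving a
2-parameter bounded L-BFGS-B problem in `(mu, log sigma)` with
`mu` within 2 log-units of the boundary span and `sigma` in
[0.005, 2]. The initial guess sits in the gate with the highest count,
with `sigma` equal to that gate's width. Fits whose `sigma` collapses
onto a bound are flagged not-OK and excluded from replicate merging.

A genotype below the darkest boundary leaves almost no gradient for
`mu`: such genotypes are *classified* dark rather than *measured*, just
as real darkest-gate genotypes are treated as non-functional. The
recovery guarantee (95% of estimates within 0.05 log10 units at ≥100
cells) therefore applies to genotypes inside the instrument's
measurable range.

`calibrate_machines()` regresses machine-A fluorescence on machine-B
fluorescence over the spike-in anchors and maps all B-side estimates
onto the A frame (A is the fixed reference).

## Quality control

Replicates merge as cell-count-weighted means; the index of dispersion
(variance/mean of replicate fluorescence) is computed on the linear
scale `10^mu`, because cutoffs in the hundreds are only meaningful in
raw FACS units. The three named presets reproduce the published
per-landscape thresholds (2/3/3 replicates; >26/14/23 cells;
dispersion <525/575/1000). Control error rates use the two built-in
control populations: chromophore mutants (expected dark; bright calls
are false positives) and synonymous-only wildtype genotypes (expected
bright; dim calls are false negatives), split by a threshold midway
between the dark mode and the wildtype mean unless specified.
Synonymous nucleotide genotypes then collapse to protein genotypes by
cell-weighted mean, and the synonymous wildtype population provides the
wildtype mean and SD used by the statistics layer.

## Landscape statistics

Single-mutant effects are `F_i - F_wt` for mutations observed in
isolation. The epistasis of a multi-mutant is its observed fluorescence
minus the additive expectation `F_wt + sum(F_i - F_wt)`, with the
expectation capped to the dataset's observed range so that impossible
expectations cannot manufacture epistasis; genotypes containing any
unmeasured single are flagged non-computable and excluded. Cutoffs of
0.3 and 1.0 log10 units (two-fold and ten-fold changes) classify
moderate and strong epistasis. The additive-fraction curve divides
observed functional genotypes by additively-expected functional
genotypes per distance (the capped expectation is used, consistent with
the epistasis definition); mutational LD50s come from bounded
least-squares logistic fits `L / (1 + exp(-k(x - x0)))` to
per-distance failure fractions, solved at `f(x) = 0.5`, with at least
15 genotypes per distance bin and 4 bins required. Pair-level epistasis
for cross-landscape comparisons is computed from double mutants only,
summarizing each site pair by its largest-magnitude value; whether
higher-order genotypes should contribute is ambiguous, and the
double-mutant reading is the conservative one. Structural annotations
(burial categories, stability predictions, residue distances) enter
only as external tables and are compared with rank-based tests.

## Fitness models

Genotypes are one-hot encoded with indicator columns only for states
observed at each position (the wildtype state included), so each row
has exactly one active state per position; `--full-alphabet`-style
encoding is available via `full_alphabet = TRUE`. Rows are split
60/20/20 into train/validation/test; training genotypes containing
mutations seen in fewer than 10 distinct training genotypes are removed
iteratively to a fixed point, and validation genotypes with mutations
absent from the final training set are pruned.

No deep-learning framework is available to R in this package's
dependency set, so the networks are implemented directly in matrix
code: dense layers, inverted dropout, Adam (learning rate 1e-3 default,
batch 64 — unstated in the original description, so set to common
practice and recorded here), MSE loss, early stopping with patience 10
restoring the best-validation weights. The response is standardized
internally; losses are reported on the original scale. The architecture
ladder is: a single linear node (the *fitness potential*); the linear
node plus one sigmoid node and a linear output (the threshold); one
linear node into 10 sigmoid nodes (the transform-visualization network,
exported as a 1-D curve by `transform_curve()`); and the two-layer
network — linear hidden layer, sigmoid hidden layer, each followed by
Monte Carlo dropout at rate 0.1 that stays active at prediction time,
never after the output node. `grid_search()` samples width pairs from
{1..10, 20, 50, 100, 200}, trains each 10 epochs, and retrains the best
by validation MSE up to 30 epochs. `predict_mc()` summarizes 20
stochastic passes by median and SD. The validation loss used for early
stopping is computed with dropout off: a stochastic stopping criterion
makes small-data runs unstable, while prediction-time behavior is
unchanged. An independent a-posteriori filter network (10, 100 and 1
leaky-ReLU nodes, 90/10 split, up to 500 epochs, no dropout) is trained
by `train_posterior()`.

## Genetic-algorithm design

`build_pool()` admits mutations seen in at least 10 distinct training
genotypes, with at least 5 background pairs (dataset genotypes
identical except for the focal mutation) whose median fluorescence
difference is at least −0.1; wildtype states of pooled sites are always
included so dead-ends can be reverted, and sampling weights place 0.6
of the mass on moves not found in the natural-state panel. Note a
deliberate property inherited from the published filter: background
pairs are found mostly among low-mutation genotypes, where a steep
transform's plateau can hide part of a mutation's cost — on sharp
landscapes the pool therefore contains conditionally neutral moves,
which is exactly why naive combinations of pool moves fail there.

`evolve()` starts 50 wildtype copies. Each generation: shuffle; set
half aside untouched; pair the rest and recombine with probability 0.7
at 0–5 uniformly placed breakpoints (strict reciprocal exchange);
mutate each residue with probability 0.012 (midpoint of the published
0.01–0.015 range) using pool draws; genotypes over the target count
lose one randomly chosen added mutation per generation, bouncing back
gradually. Offspring are added to the population (parents retained) and
the merged pool is re-evaluated — every genotype gets fresh Monte Carlo
noise, so no lucky score is frozen — then truncated to 50 by predicted
fluorescence. The run stops three generations after the population
median prediction changes by less than 0.005 over a 5-generation
window, with the plateau test gated on the population's median mutation
count having reached the target (stopping earlier would select
near-wildtype genotypes). Replicates continue until all pool moves have
been sampled, with at least 10 runs.

Candidates are unique on-target genotypes whose prediction minus its MC
SD exceeds the wildtype prediction under both the optimized and the
a-posteriori model. `select_diverse()` emulates iterative
identity-threshold clustering in-package: thresholds descend from 0.999
to 0.80 in steps of 0.002, candidates greedily join the first seed
within threshold (seeds ordered by predicted fluorescence), and the
first threshold producing at most the requested number of clusters
yields one representative per cluster.

## What the synthetic benchmark does and does not show

The generator reproduces the *structure* of the real experiments —
bimodal fluorescence, gate binning with mis-sorting, count controls,
barcode replicates, sequencing errors, conditionally neutral pool
moves — but not their full texture: no nucleotide bias in mutagenesis
(a bias matrix is accepted but defaults to uniform), no PCR chimeras or
indels, constant read quality, and epistasis that is random at the
site-pair level rather than structured by protein contacts. Passing the
synthetic benchmark shows the machinery is correct and the inferential
chain is calibrated; it does not certify performance on any particular
real landscape.

Problem sizes in the tests and the acceptance script are chosen to keep
each stage's per-mutation and per-site-pair coverage comparable to the
real data at desk scale: proteins of 40–120 residues, libraries of
1 200–8 000 genotypes with 3–4 states accessible per site, 250-cell
recovery panels, 200 designed genotypes per arm of the design contrast.
The end-to-end demonstration in the acceptance script uses the flat
preset at 1 200 genotypes and a 120-residue protein.

## Known limitations

* The two-layer network learns pairwise interactions only when the
  epistatic signal carries substantial residual variance after the
  threshold is absorbed; on heavily saturated landscapes it matches but
  does not beat the sigmoid model.
* Per-barcode gate fits assume a monoclonal (unimodal) cell population;
  mixture fits are out of scope.
* Genotypes below the darkest gate boundary are classified, not
  quantified; downstream statistics treat them through the functional
  threshold only.
* The index-of-dispersion filter uses calibrated values; whether the
  original pipeline filtered before or after calibration is unstated.
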