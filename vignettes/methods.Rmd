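---
title: "Methods: information-gain potentials and their benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: information-gain potentials and their benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette records the statistical model behind `igscore`, every default
parameter and why it has the value it has, and the design of the synthetic
data the package is validated on. It is the place to look when a number in
the code seems arbitrary — none of them are.

## 1. The model

A knowledge-based, distance-dependent scoring function assigns each pair of
atoms a score that depends on (a) the *pair type* — the residue and atom
names of the two partners, order-independent, e.g. `LEU:CA|VAL:CB` — and
(b) the distance between them, discretized into bins. A whole model's score
is the sum over all *qualifying* pairs (far enough apart in sequence, close
enough in space). Lower is better.

Training estimates, for each pair type, the distribution of distances
observed in a corpus of native structures, `f_OBS(bin)`, and compares it
with a *reference state* `f_REF(bin)` describing how distances distribute
when pair-type identity carries no information. Four per-bin formalisms
turn the two frequencies into a score:

* **PMF** (potential of mean force): `-ln(f_OBS / f_REF)`, with kT = 1.
* **TIG** (total information gain): `-(f_OBS - f_REF) / f_REF`.
* **MCK1**: `-(f_OBS - f_REF) / ((f_OBS + f_REF)/2)` (mean denominator).
* **MCK2**: `-(f_OBS - f_REF) / max(f_OBS, f_REF)` (max denominator).

MCK1 and MCK2 are deliberate controls: plausible-looking relative
differences whose denominators mix observed and reference mass.

Two identities connect PMF and TIG and are enforced by tests
(`test-scoring.R`, `test-acceptance.R`):

* `-ln(x/y) = -(x - y)/L(x, y)` where `L` is the logarithmic mean — so PMF
  is the same relative difference as TIG, only measured against the
  logarithmic mean of the two frequencies instead of the reference alone;
* `ln t <= t - 1` implies the PMF term dominates the TIG term everywhere,
  with equality iff `f_OBS = f_REF`.

TIG is bounded where PMF is not: at `f_OBS = 0`, TIG plateaus at exactly
+1 while PMF diverges. Where a formalism is genuinely undefined (zero
reference mass; 0/0 for the mock scores; the log of zero for PMF) the
stored score is a fixed default of **+10** — large enough to repel but
finite, and applied *only* where the formula itself fails, never as a
smoothing device.

## 2. Training parameters

All defaults are fixed by the study design and are not tuning knobs:

| parameter | default | role |
|---|---|---|
| `bin_width` | 0.5 Å | distance resolution |
| `cutoff` | 15.0 Å | strict upper bound; pairs at `d >= 15` are discarded |
| `min_separation` | 4 | exclude pairs with residue-index difference < 4 |
| `selection` | `all_heavy` or `ca_only` | atom subset used throughout |
| `min_count` | 2 | pair types with fewer raw observations are *insufficient* |
| bandwidth | Scott rule | `h = 1.06 * min(sd, IQR/1.349) * n^(-1/5)` |

Bins are half-open `[k*0.5, (k+1)*0.5)`, 30 of them. Sequence separation is
computed on gap-free sequential renumbering of the parsed chain, so author
numbering gaps and insertion codes cannot smuggle short-range pairs past the
filter. The separation default of 4 (excluding i+1..i+3) is one reading of
the source material, which elsewhere says "at least three positions"; the
implementation keeps `min_separation` a parameter rather than resolving the
ambiguity, and the default is 4.

**Frequency estimation.** Raw distances per pair type are smoothed by a
Gaussian kernel with the Scott bandwidth above, and the kernel mass is
integrated *exactly* over each bin (differences of the Gaussian CDF at the
bin breaks), then renormalized to sum to 1 over `[0, 15)`. Bin-mass
integration, rather than evaluating the density at bin centers and
multiplying by the bin width, is what makes the estimator converge to the
plain histogram as `h -> 0` and reproduce analytic bin masses for known
distributions — both properties are tested (`test-training.R`). Degenerate
samples with zero spread put mass 1 in their single bin. No pseudo-counts
are ever added: zeros are information (they produce the TIG +1 plateau and
the +10 defaults), and padding them away would destroy exactly the signal
the TIG formalism is designed to read.

**Reference state.** `f_REF` is the count-weighted arithmetic mean of the
per-pair-type observed distributions, weights being the raw observation
counts. Insufficient pair types are excluded from the reference and are
never scored (their pairs are skipped, contributing 0 — an honest "don't
know", not a penalty). `total_count` is the sum of *all* observation counts,
including insufficient types, so that doubling the corpus exactly doubles
it.

One documented tension: a doubled corpus should intuitively leave frequency
vectors unchanged, but the Scott bandwidth shrinks as `n^(-1/5)`, so the
smoothed vectors move slightly. The implementation follows the bandwidth
rule; the invariance is tested exactly at fixed bandwidth and approximately
under the Scott rule.

## 3. Scoring

`build_potential()` materializes a pair-type × bin matrix of per-bin scores
for one formalism; `score_structure()` enumerates the model's qualifying
pairs under the training selection and separation (warning on mismatch),
bins each distance, and sums the matrix entries. Pair types absent from the
potential are counted as skipped. A model with zero qualifying pairs scores
0. Scores are deterministic, additive over any partition of the pair set,
and rigid-motion invariant (away from bin boundaries).

## 4. Benchmark design

Models are graded by a true quality in `[0, 1]` (higher is better) and
stratified into categories: near-native `[0.8, 1.0]`, good `[0.6, 0.8)`,
medium `[0.4, 0.6)`, poor `[0.0, 0.4)`.

**Pairwise ranking accuracy.** Within each target, every unordered model
pair whose quality difference is at least 0.1 qualifies. A pair is credited
when the lower-scored model is the higher-quality one; ties in score count
as incorrect. A pair belongs to a category through its *higher*-quality
member by default (`pair_category = "higher"`): the question a user asks of
the near-native category is "can the score defend the best models against
worse ones", which is a property of the better member. `"lower"` and
`"both"` are available for sensitivity analysis.

**Average predicted rank.** Within each target's category members, models
are ranked by score ascending (best rank 1), ties averaged; per-target
ranks are then pooled. A random scorer's expected rank is `(n+1)/2`.

**Correlation.** Per-target Pearson correlation between score and quality
(skipping targets with fewer than 3 models or zero variance, with a
warning), averaged over targets. Good scores correlate *negatively* with
quality.

**Method comparison.** Two methods are compared by a Wilcoxon signed-rank
test on their paired *per-target accuracies* (zero differences dropped),
at α = 0.05. Per-target accuracies — not pooled pairs — are the exchangeable
unit: pairs within a target share models and are strongly dependent, and
targets are the natural replicates of the experiment.

## 5. Synthetic data

Everything is validated on synthetic Cα traces so the pipeline needs no
downloads, and the generator's defaults are frozen study conditions.

**Natives.** `generate_native()` grows a self-avoiding chain with 3.8 Å
virtual bonds and a 3.5 Å non-bonded exclusion. The default `mixed` fold is
a persistent (momentum 0.6), compact (center pull 0.35) self-avoiding walk
with backtracking; `helix` and `random_walk` are alternatives. Chain
lengths default to 80–250 residues.

**Residue assignment by burial.** Residue identities are assigned *after*
geometry: residues are ranked by distance from the chain centroid, and
identities are drawn with probability proportional to
`composition * exp(beta * hydropathy/4.5 * centrality)` with Kyte–Doolittle
hydropathies and `beta = 5`. This step is what makes the generator
non-trivial. With identities drawn independently of geometry, every pair
type has the *same* distance distribution, `f_OBS == f_REF` identically,
and zero information exists for any potential to learn — the end-to-end
recovery experiment would be unsatisfiable by construction, a generator
defect rather than a scorer failure. Burial-coupled assignment gives
hydrophobic–hydrophobic pairs genuinely shorter distances, the minimal
physics a distance potential can detect. `beta = 5` was chosen once at
design time as "strong but not deterministic core/surface partitioning"
(the observed hydropathy–radius correlation is well below −0.3) and is
frozen; it was not adjusted against any benchmark outcome.

**Decoys and quality.** `generate_decoy()` adds i.i.d. Gaussian noise of a
given σ to every coordinate; self-avoidance is *not* re-imposed, so decoys
contain the clashes real bad models have. True quality is a toy TM-style
score after optimal superposition (Kabsch/SVD):
`q = (1/L) * sum 1/(1 + (d_i/d0)^2)` with the standard length-dependent
`d0`, floored at 0.5 Å. The default σ ladder 0.5/1/2/3/5/8/12 Å spans
near-native to essentially unfolded.

**What the data does and does not emulate.** It reproduces chain
connectivity, excluded volume, compactness, burial-driven composition, and
a graded quality ladder — enough to make every module's contract testable.
It does not emulate secondary-structure hydrogen bonding, side-chain
packing, or realistic decoy correlations (noise is i.i.d.), so absolute
accuracies here say nothing about performance on real structures; only the
*relative* and *statistical* claims (TIG/PMF relations, chance levels,
type-I error rates) transfer.

## 6. Problem sizes and runtimes

The shipped experiments use: training corpora of 10–50 chains of 30–250
residues (seconds); benchmark sets up to 100 targets × 60 models
(~150,000 qualifying scored pairs, tens of seconds); the full test suite
runs in about half a minute and the acceptance script in under a minute on
one CPU.

## 7. Limitations

* Cα-only synthetic validation: `all_heavy` parsing and selection are
  tested on constructed PDB fixtures, but the statistical experiments run
  on Cα traces (with optional pseudo-CB atoms).
* The +10 default is a convention, not a calibrated penalty; comparisons
  between formalisms are only meaningful because all four share it.
* The Wilcoxon comparison assumes targets are independent; synthetic
  targets are, real benchmark sets may not be (homology).
* Scott bandwidths are per pair type, so sparsely observed types are
  smoothed more aggressively than abundant ones — intended, but it couples
  smoothing strength to corpus composition.
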