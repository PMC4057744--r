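---
title: "Methods: a compression-adjusted Grantham metric for variant triage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a compression-adjusted Grantham metric for variant triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmetric)
```

## The model and its assumptions

`gmetric` scores a missense substitution `W → V` in one gene by combining
two signals read from a protein multiple-species alignment:

1. **Severity.** The Grantham score `GS` is the Euclidean distance between
   the two residues in a three-dimensional biochemical property space —
   composition, polarity, molecular volume — with axis coefficients
   `α = 1.833`, `β = 0.1018`, `γ = 0.000399` that normalise the axes by
   mean pairwise distance. The historical ×50.723 rescaling (making the
   mean pairwise distance 100) is linear and therefore irrelevant to
   clustering; the package omits it but exposes `grantham_scale` so
   results can be compared against the published integer distance table.

2. **Constraint.** The Grantham variance `GV` of the alignment column is
   the longest diagonal of the bounding prism of the column's residues in
   the same space. Raw `GV` overestimates diversity in deep alignments:
   the prism can only grow with depth, so a position that admits, say,
   three biochemically scattered residues across 200 species looks as
   free as one that admits anything (and the related deviation measure
   `GD` collapses to zero once the prism covers the candidate — the
   depth-sensitivity failure that motivates this package). The correction
   treats the column as a string: sorted and concatenated, a redundant
   column compresses well under DEFLATE, and the compression ratio
   `|S_c|/|S|` gauges how much of the apparent diversity is real. The
   adjusted variance is `GV′ = GV · ratio^r`.

The two signals fuse into the metric `GM = GS · k^(−GV′)`. The functional
form encodes three requirements: `GM` increases with severity; complete
constraint (`GV′ = 0`) leaves severity untouched; and `GM → 0` as
diversity grows without bound. The base `k ≥ 1` is *gene-specific*: genes
differ in how sharply tolerated diversity should discount a substitution,
and `k` is the single knob the training data must set.

Assumptions worth stating: the method is purely positional (no
inter-column epistasis); the alignment is taken at face value (no
weighting by phylogenetic distance — the compression ratio is the proxy
for redundancy among related species); and classification is only
meaningful for genes whose known deleterious variants genuinely score
above the neutral ones (the orientation flag below).

## Training

For a gene with labelled variants, the metrics of the deleterious set `D`
and neutral set `N` should form separated clusters. The objective is the
one-dimensional cluster-distinction index

    R = |mean(GM_D) − mean(GM_N)| / (sd(GM_D) + sd(GM_N))

with sample (n−1) standard deviations: it rises when the means separate
at fixed dispersion and falls when either dispersion grows at fixed
means. Each class needs at least two members for a meaningful standard
deviation; training refuses anything less. If both dispersions are zero
with distinct means the index is reported as `Inf` — a legitimate
perfect-separation outcome on small panels, which the optimiser treats as
a maximal value.

Maximisation uses a particle swarm with a position-perturbation update
(no velocity or inertia term):

    s_i(t) = s_i(t−1) + U_i(t) + g·[gbest − s_i(t−1)] + l·[nbest_i − s_i(t−1)]

where `U` is uniform on [−1, 1] per element, and `gbest`/`nbest_i` are
the *historically* best positions globally and within particle `i`'s
neighbourhood. The returned model is the historical optimum, not the
final swarm state. Choices the update rule leaves open were fixed as
follows, and all are overridable through `gm_control()`:

| parameter | default | why |
|---|---|---|
| particles `n` | 40 | standard swarm size for 1–5 dimensions |
| attractions `g`, `l` | 0.5, 0.5 | mid-range of the admissible (0, 1) |
| topology | ring of 3 (self + index neighbours) | fixed over time; propagates information swarm-wide over iterations without premature consensus |
| iterations | ≤ 500, early stop after 50 stalled | the 1-D search converges far earlier; the cap bounds worst-case cost |
| initialisation | `k ∈ [1, 64]`, multipliers `∈ [0, 4]`, `r ∈ [0, 8]` | spans the useful attenuation range: `k = 64` at `GV′ = 1` already divides a metric by 64 |
| bound handling | clamp after every update | simplest rule that keeps `k ≥ 1` and multipliers ≥ 0 exactly |

One seeded generator drives each training call (`seed` argument); the
`U` vectors are drawn per particle per iteration in a fixed order, so
runs replay bit-identically.

Two training modes exist. The default `k_only` pins `r = 2.47` — the
empirically optimal constant for this compressor, with no reason to be a
round number and no validity for other compressors — and locks the
property multipliers at 1, leaving `k` free; freeing `r` per gene is
known to cost accuracy, and the multipliers have shown no benefit.
`all_five` frees everything for exploration. Multipliers apply directly
(`α′ = c·α`); no re-normalisation is attempted since the coefficients'
mean-distance rationale has no obvious per-gene analogue.

## Classification

Assigning a new variant to the class that maximises the recomputed index
reduces, in closed form, to a threshold rule with cut-off
`C = |mean_D − mean_N| / 2`. The package implements the printed formula
literally and also ships the index-maximising rule
(`classify_by_index()`) as an independent cross-check, since the two can
disagree in principle when class dispersions differ strongly. Ties
`GM = C` are called deleterious — in triage a false alarm is cheaper than
a miss. If a trained model ends with `mean_D ≤ mean_N` the orientation
flag invalidates it and classification refuses to run, because `GM > C`
then no longer expresses pathogenicity.

Raw `GM` is not comparable across genes (each gene has its own `C`), so
the continuous output is `ln(GM/C)`: zero at the cut-off, positive iff
the binary call is deleterious, order-preserving within a gene. `GM = 0`
cannot arise for a genuine substitution (all pairwise `GS > 0`) but can
appear through rounding; such values are excluded from scoring with an
explicit error.

Posterior probabilities use Bayes' rule over class-conditional densities
of the normalised score. The default densities are maximum-likelihood
normal fits, deliberately flagged `"fitted-normal"`: empirical score
distributions are heavy-tailed and asymmetric, so these posteriors rank
variants correctly (monotone likelihood ratio) but are not calibrated
probabilities. The interface accepts any user-supplied density pair, so
heavier-tailed families can be plugged in without touching the package.
The prior is a required explicit input — the package has no principled
default for disease prevalence among submitted variants. Points where
both densities vanish return `NA` (0/0 is undefined), never a silent 0.

## The DEFLATE convention

Compressed lengths depend on framing. The package pins one convention:
the zlib stream emitted by R's `memCompress()` minus a constant 8 bytes
(the 2-byte header, 4-byte Adler-32 checksum, and a 2-byte constant
stream-overhead correction), fixed once by calibrating against five
reference column strings of known compressed length (20, 10, 8, 4 and 3
bytes for `ACDEFGHIKLMNPQRSTVWY` through `AAAA…A`) and covered by a
regression test. The floor `|S_c| ≥ 1` keeps depth-1 columns legal (their
`GV` is 0 anyway). Columns are canonicalised before compression: gaps and
non-canonical codes dropped, residues upper-cased and sorted, so the
measure is permutation-invariant and the ratio uses the filtered length.
Ambiguity codes (B, Z, X) and non-standard residues are rejected rather
than approximated in all Grantham computations — no property values exist
for them.

## Evaluation protocol

`loo_cv()` performs per-gene leave-one-out cross-validation: every
labelled variant is classified by a model trained on the gene's remaining
variants. Genes need at least 3 variants per class, leaving ≥ 2 per class
in every fold. Fold seeds derive deterministically from the master seed.
Folds whose model comes out orientation-invalid are reported as
unclassified rather than silently dropped or force-called.

Summary statistics are computed on the normalised scores pooled across
genes — pooling is the point of the normalisation. The report contains
the confusion matrix at the theoretical cut-off (score 0), MCC,
sensitivity/specificity, the chi-squared statistic against random
allocation (the 2×2 Pearson independence statistic, which equals
`n·MCC²`; the identity is tested), the ROC curve with tie-averaged
trapezoidal AUC (cross-checked against pROC in the test suite), and an
MCC-vs-cutoff sweep whose peak location can be compared with the
theoretical optimum at 0.

## The synthetic generator

`generate_panel()` builds test panels: a fraction of columns are
conserved (one residue, optionally perturbed at a per-cell noise rate),
the rest draw per-sequence from a small random alphabet. Deleterious
variants are planted at conserved columns with substitutions above the
median pairwise Grantham score; neutral variants at variable columns
below it. Labels can be flipped at a mislabel rate. Defaults — depth 20,
60 columns, half conserved, alphabet size 4, no noise, 6 + 6 variants —
give a panel that is unambiguous by construction: a pipeline that fails
to recover it is broken. The generator plants structure only through the
quantities the metric consumes (severity and conservation), not through
any assumed score distribution, so recovery tests validate mechanics, not
a circular assumption.

What the generator does *not* emulate: phylogenetic correlation between
sequences (columns are i.i.d.; real alignments carry tree structure that
makes compression ratios less uniform), isoform/coordinate noise, and the
long-tailed score distributions of real curated variant sets. Passing the
recovery tests therefore demonstrates correctness of the machinery, not
expected field accuracy, which must be established on real labelled
variants per gene.

```{r example}
panel <- generate_panel(seed = 1)
fit <- gm_train(panel$alignment, panel$variants, seed = 1)
fit
```

## Numerical choices and problem sizes

Degenerate inputs have defined behaviour throughout: empty columns and
unknown residues are validation errors naming the offender; equal class
means give `C = 0` and disable normalised scoring; all-identical training
metrics abort training. The test suite and examples run the swarm at a
reduced budget (20 particles, ≤ 120 iterations, stall 25) and use panels
of depth 20 with 6–12 variants; the 1-D `k` search reaches the grid-search
optimum under this budget on such panels (asserted against a grid oracle),
and the production defaults simply add headroom for harder data.

## Known limitations

- Genes without ≥ 2 (training) or ≥ 3 (cross-validation) known variants
  per class are out of reach; this is a data requirement, not a software
  limit.
- The compression exponent default `r = 2.47` is compressor-specific;
  substituting another compressor would require re-estimating it.
- Default posterior densities are convenience fits, not calibrated
  probability models.
- The cut-off formula is implemented exactly as half the distance between
  class means; `classify_by_index()` exists precisely because the
  reduction from index maximisation to that threshold is not re-derived
  here.
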