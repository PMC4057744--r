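# gmetric

Gene-specific, compression-adjusted Grantham scoring of missense protein
variants.

## The problem

Sequencing turns up far more novel non-synonymous variants (nsSNPs) in
disease genes than laboratories can characterise, so *in-silico* triage is
routine. A classical family of predictors reads evolutionary constraint
off a multiple-species sequence alignment (MSA): a substitution at a
position that tolerates many different residues across species is probably
benign, while a radical change at a conserved position is suspect.
Grantham-geometry tools quantify "radical" as a weighted Euclidean
distance in amino-acid property space and "tolerated diversity" as the
spread of the alignment column in the same space. Their weakness is depth:
as more (and more distant) species enter the alignment, the property-space
prism around a column keeps growing until it swallows every candidate
residue and everything looks neutral.

`gmetric` implements a corrected metric. The apparent diversity of a
column is discounted by how *compressible* the column is: a deep column of
near-identical residues compresses to a few bytes (low Kolmogorov
complexity — tight evolutionary control), while genuine diversity does
not. This keeps constrained positions "hot" no matter how deep the MSA
gets.

## The model

For wild-type `W` and variant `V` with Grantham properties (composition
`c`, polarity `p`, volume `v`) and coefficients `α = 1.833`, `β = 0.1018`,
`γ = 0.000399` (optionally rescaled per gene by multipliers `c, p, v ≥ 0`):

- **Grantham score** `GS = sqrt(α(W_c−V_c)² + β(W_p−V_p)² + γ(W_v−V_v)²)`
  — severity of the substitution.
- **Grantham variance** `GV` — the longest diagonal of the axis-aligned
  property-space prism enclosing the column's residues (equal to `GS` for a
  two-residue column).
- **Compression adjustment** `GV′ = GV · (|S_c|/|S|)^r`, where `S` is the
  column's alphabetically sorted residue string, `S_c` its DEFLATE
  compression, and `r = 2.47` the empirically optimal exponent.
- **Grantham metric** `GM = GS · k^(−GV′)` with a gene-specific constant
  `k ≥ 1`: at a fully constrained position (`GV′ = 0`) the metric is the
  raw severity; with unlimited diversity it decays to zero.

Training maximises the one-dimensional cluster-separation index
`R = |mean_D − mean_N| / (s_D + s_N)` between the metrics of known
deleterious (`D`) and neutral (`N`) variants of the same gene, using a
particle swarm over `k` (optionally also `r` and the property
multipliers). The fitted model classifies a new variant as deleterious
when `GM ≥ C` with cut-off `C = |mean_D − mean_N| / 2`, and scores it
continuously by `ln(GM/C)`, which is comparable across genes and feeds an
optional Bayesian posterior `Pr(D | x) = f_D(x)π / (f_D(x)π + f_N(x)(1−π))`
with pluggable class densities.

## Worked example

Synthetic panels give a fully reproducible demonstration: an alignment of
20 sequences whose conserved columns carry deleterious variants with
severe substitutions, and whose variable columns carry mild neutral ones.

```r
library(gmetric)

panel <- generate_panel(seed = 1)     # 20 x 60 alignment, 6 D + 6 N variants
fit <- gm_train(panel$alignment, panel$variants, seed = 1)
fit
#> Grantham-metric gene model for SYNTH1
#>   parameters: k = 471.2  r = 2.47  multipliers (c,p,v) = 1, 1, 1
#>   clusters: mean_D = 2.309 (sd 0.3885); mean_N = 0.0181 (sd 0.01762)
#>   cluster index R = 5.641  cut-off C = 1.145
```

The swarm found a large attenuation constant `k`: neutral variants at
diverse columns are crushed towards zero while deleterious variants at
conserved columns (where `GV′ = 0`) keep their full Grantham severity —
the clusters separate with index `R = 5.64`, against `R = 1.15` for the
unattenuated (`k = 1`) metric.

```r
head(predict(fit, panel$alignment, panel$variants), 4)
#>   position wt variant label   gs gv_adj   gm score pred
#> 1       33  Q       L     D 2.22      0 2.22 0.660    D
#> 2       56  V       D     D 3.00      0 3.00 0.962    D
#> 3       42  Q       Y     D 1.95      0 1.95 0.531    D
#> 4       47  M       G     D 2.50      0 2.50 0.782    D

loo <- loo_cv(list(SYNTH1 = panel), seed = 11)
evaluation_report(loo)
#> Binary classification over 12 variants
#>          actual
#> predicted D N
#>         D 6 0
#>         N 0 6
#> MCC: 1  sensitivity: 1  specificity: 1
#> chi-squared (1 df) vs random: 12
#> AUC: 1  MCC peak at score cut-off -1.3725
```

Each variant was classified by a model trained without it
(leave-one-out); on this noiseless panel the recovery is perfect, and the
empirical MCC peak sits below the theoretical cut-off `ln(GM/C) = 0`, both
calls agreeing everywhere.

A command-line front end over the same functions ships in
`inst/cli/gmetric.R` with subcommands `train`, `classify`, `evaluate` and
`simulate`.

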