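---
title: "Stress-tolerance indices and genotype classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stress-tolerance indices and genotype classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stresskit)
```

This vignette documents the statistical model behind `stresskit`, the
choices that were genuinely open when it was built, and what the synthetic
validation does and does not demonstrate.

## The trial and its data model

The package targets two-season genotype screening trials with four
environments: two normal winter sowings (`N1`, `N2`, one per season) and
two late sowings in the second season that synchronize the reproductive
phase with temperatures above ~32 °C — irrigated (`SI`, terminal heat
stress) and with irrigation withheld from flowering (`SNI`, combined
heat-drought stress). Data enter as a long table of
(genotype, environment, replicate, trait, value) records; units are
trait-specific (yields in g/plot, heights in cm, protein and harvest index
in %, minerals in mg/kg, grain dimensions in mm/mm²). Validation enforces
key uniqueness, non-negative measurements and percentage bounds, and
reports offending row numbers, because silent coercion is the usual way
trial spreadsheets go wrong.

Yield pairing (`pair_yields()`) averages replicates per genotype within
each environment and joins the normal and stress members of the same
season. Two policies are deliberate and documented rather than universal:
genotypes observed in only one member of the pair are **dropped with a
warning** (every index needs both yields; imputation would manufacture
tolerance scores), and genotypes with non-positive normal yield are
excluded (SSI and YSI divide by `Yp`). Population means `Ȳp`, `Ȳs` are
computed over the retained genotypes only, so the stored means always
recompute exactly from the stored table.

## Indices

With stress intensity `SI = 1 − Ȳs/Ȳp`, the seven indices are computed as
listed in the README. Three parenthesizations deserve a note because the
compact notation in the literature is ambiguous:

* **SSI** is the Fischer–Maurer form `(1 − Ysi/Ypi)/SI`. Under this
  reading SSI is a strictly decreasing affine function of YSI
  (`SSI = (1 − YSI)/SI`), which forces the Pearson correlation between the
  two columns to be exactly −1 and makes `corr(X, SSI) = −corr(X, YSI)`
  for any third column — an analytic property the test suite asserts.
* **HARM** is the standard harmonic mean `2·Ypi·Ysi/(Ypi + Ysi)`; this is
  the only reading satisfying `GMP² = MP·HARM`.
* **STI**'s denominator is the squared *population* mean `Ȳp²`
  (Fernandez's definition). With the per-genotype `Ypi²` the index would
  collapse to a constant multiple of YSI and add no information.

All indices are computed on replicate-mean yields. The identities
`TOL = Yp − Ys`, `GMP² = MP·HARM`, `HARM ≤ GMP ≤ MP` (the AM–GM chain) and
`YSI + SI·SSI = 1` hold to floating-point accuracy and are checked on ten
thousand random pairs.

Degenerate inputs: if `SI = 0` (no stress) SSI is undefined and
`compute_indices()` errors unless explicitly told to return `NA`; a
genotype with total loss (`Ys = 0`) gets `STI = GMP = HARM = YSI = 0`,
`TOL = Yp` and `SSI = 1/SI`, all well defined.

## Classification chain

The nine index columns mix g/plot scales (Ys, Yp, TOL, GMP, MP, HARM) with
dimensionless ratios (STI, SSI, YSI), so both the PCA and the clustering
operate on z-scores (n − 1 denominator). PCA is the eigendecomposition of
the 9×9 correlation matrix: eigenvalues sum to 9, percent variance is
`100·λ/9`, and the contribution of variable *j* to dimension *k* is
`100·e_jk²`, summing to 100 within each dimension. Eigenvector signs are
fixed so the `Ys` loading is non-negative on every dimension; eigenvectors
are sign-ambiguous and an arbitrary LAPACK sign would make biplots and
stored loadings irreproducible across platforms.

Because every index is a smooth function of the two-dimensional
`(Yp, Ys)` input, the correlation matrix has (numerically) rank ≈ 2 and
the first two dimensions carry ≈ 99% of the variance on realistic inputs.
This is a structural property of the index set, not evidence of anything
about the genotypes.

Clustering is Ward's minimum-variance agglomeration on Euclidean distances
of the z-scores (`hclust` method `ward.D2`, Lance–Williams updates); each
merge height equals `√(2·ΔESS)`, the increase in within-cluster sum of
squares it causes. A unit test verifies the whole merge history against an
exhaustive enumeration oracle on a small instance. Merge ties are resolved
by `hclust`'s internal order; on continuous inputs ties have probability
zero, and we did not re-implement the agglomeration just to impose a
lexicographic tie-break. The tree is cut at `k = 4` by default — four
tolerance classes is the convention in this literature — but `k` is a
parameter, not a constant.

Labelling the four clusters is a fixed, documented rule rather than a
judgment call: highest mean GMP → *tolerant*; among the rest, highest mean
SSI → *susceptible*; of the remaining two, higher mean YSI → *moderately
tolerant*, the other *moderately susceptible*. The rule mirrors how
tolerance clusters are described in the selection-index literature (the
tolerant cluster leads in Ys/STI/GMP/MP/HARM, the susceptible one in SSI),
but the rule itself is this package's formalization. Exact ties in a
ranking statistic raise an error demanding manual labels instead of being
broken silently.

Cluster profiling averages replicates within genotype, genotypes within
cluster, and separates cluster means per trait with Duncan's multiple
range test at α = 0.05 (error mean square from the one-way cluster ANOVA
on genotype means; harmonic-mean cluster size when clusters are unequal).

## Trial statistics

**Two-way ANOVA** (`genotype * environment`) supports balanced designs
only; unbalanced input is a hard error rather than a silent Type-I/III
choice, because the simulated trials are balanced and a wrong default
would be worse than no answer. Sums of squares below `1e-12 · Σy²` are
zapped to exact zeros so constant data report `SS = 0` and `F = NA`
instead of floating-point dust.

**Broad-sense heritability** uses the entry-mean variance-components
formula within one environment: `σ̂²_e = MS_error`,
`σ̂²_g = max(0, (MS_genotype − MS_error)/r)` and
`H² = σ̂²_g / (σ̂²_g + σ̂²_e/r)`. Negative component estimates are
truncated at zero, keeping `H² ∈ [0, 1]`. This is the standard definition
reported by multi-environment trial software; a lattice-aware mixed model
is out of scope because block-level data are not part of the data model.
The balanced sums of squares are computed directly from cell means and are
verified against `stats::aov` in a test.

**Correlation panels** use the product-moment formula with two-sided
p-values from `t = r√((n−2)/(1−r²))` and the usual `*`/`**` stars at 0.05
and 0.01. Correlations of magnitude 1 (within 1e-12) are reported as
significant with p = 0 — the t statistic degenerates there, but the
printed convention for exact linear dependencies (like SSI–YSI) is
`−1.00 **`, and we follow it. Both LSD and Duncan mean separation are
provided because the field uses both; the caller chooses. For adjacent
means in the ranked sequence the two criteria coincide
(`q(0.95; 2, df) = √2 · t(0.975, df)`); Duncan's ranges widen for larger
spans.

## The synthetic-data generator

`simulate_trial()` draws `y = μ_te + G_g + (GE)_ge + ε` with independent
normal effects, a fixed draw order and R's default Mersenne-Twister
generator, so a seed fully determines the table across platforms.
Incomplete-block (alpha-lattice) structure is not simulated: no downstream
stage consumes block information, and no block layout is part of the data
model. Out-of-range draws are truncated (negative values to 0, percentage
traits to 100) rather than resampled, so the draw count — and hence
everything downstream of the seed — is independent of the values.

`simulate_yield_pairs()` plants a known group structure: per group,
`Yp ~ N(μ_Yp, 12²)` g/plot and `YSI ~ N(μ_YSI, 0.03²)` (truncated to
(0.01, 1.2)), with `Ys = Yp·YSI`. The presets encode the study conditions
the package is validated under:

* `paper_heat_clusters`: group sizes (11, 5, 12, 15), mean YSI
  (0.55, 0.65, 0.35, 0.22), mean Yp (280, 190, 310, 215). The 11-member
  group leads in Ys/STI/GMP/MP/HARM (hence *tolerant* under the label
  rule), the 12-member group has the highest Yp and TOL, the 15-member
  group the highest SSI.
* `paper_sni_clusters`: group sizes (22, 2, 12, 7), mean YSI
  (0.50, 0.70, 0.28, 0.15), mean Yp (250, 170, 320, 260).
* `paper_protein`: a 43-genotype, 2-replicate protein trial with
  treatment means 20.26 / 20.26 / 22.19 / 21.94 % for N1/N2/SI/SNI and
  residual SD 0.5 %. The genotype SD (0.35) and GxE SD (0.2) were chosen
  once so the entry-mean heritability is ≈ 0.5 — "medium", which is where
  quality traits typically sit — and not revisited.

Group sizes aside, the cluster-preset dispersions and means are fixtures
chosen so that the planted partition is recoverable (separations of
several within-group SDs); no per-genotype field data exist to calibrate
them against. Consequently the recovery results say the chain is
*correct* — it finds structure that is present at this
separation-to-noise ratio — not that real trials are this clean: field
data carry spatial trends, shared error between the paired environments,
non-normal tails and genuine boundary genotypes, all of which the
generator omits.

## Problem sizes and numerical choices

The validation suite runs at the trial's own scale (43 genotypes, 2
replicates, 4 planted groups) for the classification checks, 20–25 seeds
for the stochastic recovery and PCA summaries, and 200 replicates of a
500-genotype single-environment trial for the heritability estimator
(planted `σ²_g = 4`, `σ²_e = 2`, `r = 2`, closed-form `H² = 0.8`); the
whole suite completes in a few seconds. Key tolerances: index identities
to 1e-10 relative; PCA eigenvalues against an independent
characteristic-polynomial solve to 1e-9; ANOVA sums of squares against the
textbook cell-means decomposition to 1e-9; exact-correlation detection at
1e-12.

## Known limitations

* Balanced designs only; no mixed-model/REML path, no spatial adjustment.
* The seven indices above only; other literature indices (DSI, MRP, REI,
  ...) are out of scope.
* Heritability ignores block structure by design (see above).
* The labelling rule presumes the four-cluster convention; for `k ≠ 4`
  clusters are left unlabelled.
* No figure rendering; the dendrogram is exported as newick text and the
  PCA as tables, for plotting elsewhere.
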