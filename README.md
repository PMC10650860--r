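# stresskit

Stress-tolerance analysis of multi-environment crop trials.

Breeding programmes screen genotype collections under paired growing
conditions — a normal sowing and a stress regime such as terminal heat
(late sowing with irrigation) or combined heat-drought (late sowing without
irrigation) — and ask which genotypes keep yielding under stress.
`stresskit` implements the standard selection-index workflow for such
trials: per-genotype tolerance indices from the paired yields, correlation
and principal-component summaries of those indices, Ward clustering of the
genotypes into four tolerance classes, cluster trait profiling with Duncan
letter groups, and the supporting trial statistics (two-way ANOVA,
broad-sense heritability, treatment percent changes). A synthetic-data
module generates trials and cluster-structured yield pairs with known
ground truth so the whole chain is testable end to end.

## The indices

With `Ypi` and `Ysi` the replicate-mean yield of genotype *i* under the
normal and stress environment, and `Ȳp`, `Ȳs` the across-genotype means,
the stress intensity is `SI = 1 − Ȳs/Ȳp` and the per-genotype indices are

| index | formula | reads as |
|---|---|---|
| STI  | `Ypi·Ysi / Ȳp²` | joint performance under both regimes |
| TOL  | `Ypi − Ysi` | absolute yield loss (g/plot) |
| GMP  | `√(Ypi·Ysi)` | geometric mean productivity |
| MP   | `(Ypi + Ysi)/2` | mean productivity |
| HARM | `2·Ypi·Ysi/(Ypi + Ysi)` | harmonic mean productivity |
| SSI  | `(1 − Ysi/Ypi)/SI` | susceptibility (Fischer–Maurer) |
| YSI  | `Ysi/Ypi` | yield stability |

These satisfy exact identities (`GMP² = MP·HARM`, `HARM ≤ GMP ≤ MP`,
`YSI + SI·SSI = 1`), which the test suite checks; in particular SSI is a
decreasing affine map of YSI, so their Pearson correlation is exactly
−1.00 on any data set.

Classification standardizes the nine index columns, runs a
correlation-matrix PCA (eigenvalues sum to 9; per-variable contributions
`100·loading²` sum to 100 within each dimension) and Ward
minimum-variance clustering (`ward.D2` on Euclidean distances of the
z-scores), cuts four clusters and labels them by a fixed rule: highest
mean GMP → *tolerant*; of the rest, highest mean SSI → *susceptible*;
of the remaining two, higher mean YSI → *moderately tolerant*.

## Worked example

```r
library(stresskit)

pairs <- simulate_yield_pairs(sim_preset("paper_heat_clusters", seed = 1))
idx   <- compute_indices(pairs)
head(idx, 4)
#> # A tibble: 4 × 10
#>   genotype    Ys    Yp   STI   TOL   GMP    MP  HARM   SSI   YSI
#>   <chr>    <dbl> <dbl> <dbl> <dbl> <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1 G01       154.  272. 0.640  118.  205.  213.  197. 0.719 0.567
#> 2 G02       149.  282. 0.642  133.  205.  216.  195. 0.781 0.529
#> 3 G03       143.  270. 0.587  127.  196.  206.  187. 0.782 0.529
#> 4 G04       168.  299. 0.764  131.  224.  233.  215. 0.729 0.561
round(attr(idx, "si"), 3)
#> [1] 0.602
```

The simulated heat episode removes about 60% of the population-mean yield
(`SI = 0.602`). The index correlations and the classification chain:

```r
m <- pearson_matrix(idx)
m$r["SSI", "YSI"]          # exactly -1: SSI is an affine map of YSI
#> [1] -1

z  <- standardize_indices(idx)
p  <- pca_indices(z)
round(p$variance_explained[1:3], 2)
#> Dim.1 Dim.2 Dim.3
#> 73.79 25.79  0.40

cl <- label_clusters(ward_cluster(z, k = 4), idx)
table(cluster_assignments(cl)$label)
#> moderately_susceptible    moderately_tolerant   susceptible   tolerant
#>                     12                      5            15         11
```

Two dimensions carry 99.6% of the variance — the indices are all functions
of the two-dimensional (Yp, Ys) input, so a correlation PCA concentrates
almost everything on the first two axes. The four recovered clusters match
the planted group sizes (11 tolerant, 5 moderately tolerant, 12 moderately
susceptible, 15 susceptible genotypes).

`run_pipeline()` wires the same chain end to end from a YAML config or a
trial CSV and writes a reproducible report bundle (all outputs carry the
seed and config hash; reruns are byte-identical). A thin command-line
front end with subcommands `simulate | indices | corr | classify | anova |
report` lives at `inst/cli/stresskit.R`.

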