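# clamcor — cluster-based association measures

Whole-sample correlation coefficients mislead when the data hide separated
subpopulations: two variables independent inside every cluster can look
almost perfectly associated overall, because the estimate picks up the
geometry of the cluster centroids instead of any real within-group
relationship (the continuous analogue of Simpson's paradox). `clamcor` is
for analysts of heterogeneous biomedical data — gene expression with
regimes, microbiome profiles with subject subgroups, imaging features with
classes — who want association estimates that account for hidden clusters
without being told what they are.

The package combines three ingredients:

1. **Nonlinear association estimators** with a shared interface:
   Chatterjee's rank coefficient ξ (tie-aware), distance correlation
   (V-statistic form), maximal correlation via the alternating conditional
   expectations (ACE) iteration with a Gaussian-kernel smoother, the
   maximal information coefficient (MINE-style dynamic-programming search,
   C++ backed), a checkerboard-copula Markov-kernel coefficient, and the
   Pearson/Spearman baselines.
2. **Data-driven clustering with consistency guarantees**: neighborhood-
   graph clustering with core-point denoising (parameters `r`, `s`), and
   spectral clustering over density-sensitive distances — the longest-leg
   (minimax) path distance or the interpolating g-distance
   `g⁻¹(min_path Σ g(edge))` — with the number of clusters chosen by the
   Laplacian eigengap.
3. **The combination.** For clusters I₁, …, I_K and a measure ρ_M,

       ρ̂_CLAM = Σᵢ α̂ᵢ · ρ̂_M(X, Y | Iᵢ),   α̂ᵢ = |Iᵢ| / Σⱼ|Iⱼ|,

   reported with the per-cluster triples (weight, within-cluster
   association, centroid). Noise points and sub-minimum clusters are
   excluded from both numerator and denominator.

Seeded simulators (`gen_gaussian_mixture`, `gen_rotated_squares`,
`gen_two_blocks`, `gen_circle`, `gen_noisy_function`) generate the
separated-mixture benchmark designs the estimators are validated on, and
`run_table_study()` reruns the replicated benchmark grids.

## Worked example

Two uniform blocks on [0,1]² and [2,3]²: within each block the coordinates
are independent, yet the whole-sample maximal correlation is ≈ 1.

```r
library(clamcor)
b <- gen_two_blocks(2000, seed = 42)
ace_maximal(b$x[, 1], b$y[, 1])$rho        # plain whole-sample estimate
#> [1] 0.9914

clam_pipeline(b, "maximal", "ng", r = 0.5)
#> <clam_result> maximal via NG: overall = 0.0647  (2 clusters, 2000/2000 points used)
#>   cluster alpha    rho size    x1    y1
#> 1       1 0.511 0.0739 1023 0.508 0.513
#> 2       2 0.488 0.0552  977 2.510 2.500
```

The plain estimate (0.99) reflects only block membership; the cluster-based
estimate finds the two blocks (weights ≈ ½, centroids ≈ (0.5, 0.5) and
(2.5, 2.5)), measures association inside each (≈ 0.06–0.07, pure
estimation noise around the true 0), and reports their weighted average —
essentially zero, which is the correct description of the within-group
relationship.

The same machinery exposes the rotation-invariance property on the
two-component Gaussian mixture design: the plain maximal correlation climbs
from ≈ 0.20 to ≈ 0.91 as the minority component rotates and grows, while
the cluster-based value stays flat near 0.28 (`run_table_study("table1")`).

## Command-line use

A thin CLI over the same functions lives at `inst/cli/clam.R`:

```sh
Rscript inst/cli/clam.R simulate --model blocks --n 2000 --seed 42 --out blocks.csv
Rscript inst/cli/clam.R clam --measure maximal --algo ng --r 0.5 --out result.json blocks.csv
Rscript inst/cli/clam.R study --which table1 --reps 1000 --seed 1 --out table1.csv
```

JSON outputs embed every parameter of the run; identical seeds give
byte-identical files.

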