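---
title: "Methods: jaw lever biomechanics, morphospace and disparity in jawspace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: jaw lever biomechanics, morphospace and disparity in jawspace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jawspace)
```

## The scientific problem

Sympatric marine predators are expected to partition food resources, and
in fossil assemblages that partitioning must be read from functional
anatomy. `jawspace` implements a complete workflow for asking whether
clades and tooth-based feeding guilds of aquatic amniotes occupy
distinct regions of a *morphofunctional* space built from their lower
jaws: from raw mandibular measurements, through lever-theory
biomechanics, to ordination, permutation-based hypothesis tests,
disparity estimation and discriminant classification.

## The jaw as a lever

The mandible is modelled as a third-class lever with the fulcrum at the
articular glenoid, placed `RPL` (the retroarticular process length)
from the posterior end of the ramus. All arms are straight-line
distances along the long axis of the jaw:

* anterior out-lever `ML - RPL` (fulcrum to tip);
* posterior out-lever `(ML - RPL) - TRL`, the tooth row being taken to
  start at the anterior tip — consistent with `TRL` being measured from
  the tip, and revisable through the explicit override columns if a
  dataset defines its landmarks differently;
* largest-tooth out-lever `(ML - RPL) - DLT`, where `DLT` locates the
  largest tooth from the tip; the bite point used for force-transmission
  comparisons is the largest tooth;
* closing in-lever: the anteroposterior length of the adductor
  insertion, `maL`, which is the measurable fossil proxy for the
  adductor moment arm (muscle cross-sections and pennation do not
  preserve); a dataset that records an explicit closing in-lever can
  supply it in the `ILc` column, which takes precedence;
* opening in-lever: `RPL` itself.

Mechanical advantage is in-lever over out-lever: `aMA` at the tip,
`pMA` at the back of the tooth row, `ltMA` at the largest tooth, and
the opening ratio `oMA = RPL / (ML - RPL)`. We orient `oMA` so that
*low* values mean a fast-opening jaw (a short depressor in-lever
relative to the jaw in front of the fulcrum); this matches the
ecological reading in which smash- and pierce-feeders trade bite force
for opening speed. Whenever the largest tooth lies inside the tooth
row, `pMA >= ltMA >= aMA`, which the test suite asserts over 10,000
random valid jaws.

The eleven morphospace characters are the seven length ratios
(`ASD/ML`, `MSL/ML`, `MSD/ML`, `TRL/ML`, `CPD/ML`, `RPL/ML`,
`maL/ML`), the tooth index `TI = LCH/ML` (largest crown height against
jaw length — crown height is used because it is the tooth dimension
most often measurable in crushed material), and `aMA`, `pMA`, `oMA`.
`ltMA` is computed as an auxiliary but kept out of the ordination set,
and `ML` is kept out as well (all ordination characters are
dimensionless) and carried separately as the size metric. Because jaw
lengths in a mixed assemblage span roughly an order of magnitude, `ML`
enters univariate comparisons on the natural-log scale by default.

## Standardization and ordination

Characters are z-scored per column with the sample (n − 1) standard
deviation — the convention shared with every downstream variance
computation in the package — and constant columns are an error, never
silently zeroed. Ordination is classical principal-coordinate analysis
on Euclidean distances: double-centre the squared distance matrix,
eigendecompose, scale eigenvectors by the square roots of positive
eigenvalues. On Euclidean input this is exactly principal-component
analysis of the standardized matrix, which the test suite checks
against an independent covariance-eigendecomposition route on 50
random matrices. Numerical policy: eigenvalues within `1e-8` (relative
to the largest) of zero are clamped to zero; genuinely negative
eigenvalues abort with a diagnostic, since Euclidean distances
guarantee positive semidefiniteness up to round-off; equal eigenvalues
keep their original order; each axis is oriented so that its
largest-magnitude score is positive, making outputs reproducible and
diffable. Variance-explained fractions are taken over positive
eigenvalues only, and all positive axes are retained for statistical
testing (a constant rescaling of the axes would leave every downstream
test invariant, which is asserted by test).

## Group separation, disparity, classification

**PERMANOVA.** The pseudo-F uses sums of squared inter-point distances
(Gower's identity), so the test on all PCo axes is identical to the
test on the z-scored characters. Labels are permuted; when the number
of distinct label arrangements is at most 100,000 the test is exact by
full enumeration (the observed arrangement counts itself, so p is
never zero); otherwise Monte-Carlo permutation with the add-one
correction `p = (b + 1)/(B + 1)` and a default `B = 9999`. Specimens
are canonically sorted by id before permuting, so results do not
depend on input row order. Pairwise tests report both Bonferroni and
Benjamini–Hochberg adjustments — Bonferroni for the conventional
significance matrix, the false-discovery rate as the less conservative
companion. Groups below a configurable minimum size (default 3) are
carried through the ordination but skipped in tests, with a warning.

**Disparity.** Morphofunctional variety is the sum of per-axis sample
variances — the trace of the group covariance, basis-invariant when
computed over all retained axes (the `--axes`-restricted alternative is
available through the `members`/matrix interface). Uncertainty comes
from a 1000-replicate bootstrap with 2.5/97.5 percentile intervals;
between-group differences are tested by pooling and re-splitting at the
original sizes (two-tailed, exact by enumeration for small groups), and
a rank-sum matrix over the bootstrap distributions is also provided
because that comparison is common practice — its pseudo-replication
makes it anti-conservative, and the permutation test is the one we
recommend reading.

**Classification.** Jackknifed (leave-one-out) linear discriminant
analysis with pooled within-class covariance and equal priors
quantifies how predictable clade or guild membership is from the
characters (or, optionally, from PCo scores — equivalent information,
offered for convenience). Near-singular pooled covariances get an
automatic ridge of `1e-6` times the mean diagonal (escalated tenfold
until invertible), reported by message, never silently. Grouping
variants — family-rank clades via `coarsen_clade()`, merged Pierce
guilds via `collapse_pierce()` — are exposed as options because
recovery rates legitimately depend on the grouping chosen.

## The synthetic assemblage generator

No specimen data ship with the package; instead the generator encodes
one archetype per feeding guild and simulates assemblages with the
structure the analysis assumes. Archetypes are parameterized by the
*free* quantities — the eight measurement ratios, `aMA`, the position
of the largest tooth along the tooth row, and log jaw length — because
`oMA` and `pMA` are anatomically determined once `RPL/ML`, `TRL/ML`
and the in-lever are fixed. Raw measurements are back-solved from the
draws (`ML = exp(logML)`, each ratio times `ML`, `ILc = aMA (ML -
RPL)`, `DLT` from the tooth-position fraction), so recomputing
characters from the simulated table recovers the drawn values exactly;
ratio draws are truncated to (0.005, 0.995) by rejection, with the
additional constraint `TRL/ML + RPL/ML <= 0.95` keeping the posterior
out-lever positive.

Only ordinal relations and ranges among the guild archetypes are
scientifically constrained; within those constraints the default means
were fixed once at values a comparative morphologist would call
realistic and are ordinary configuration data, not magic constants.
The encoded relations: smash-feeders open fastest and durophages
slowest (`oMA` Smash < Pierce II < Crunch); macrophagous guilds (Cut,
Generalist, Crunch) transmit more force and have shorter symphyses
than Pierce II and Smash; the plesiosauroid-style Pierce I archetype
has the highest tooth index, the shortest symphysis and the smallest
jaws; Generalist the largest jaws; Smash the lowest tooth index.
Symphysis-length means sit inside the tabulated per-guild ranges
(e.g. Pierce II 42–55% of `ML`, Crunch 42–50%, Generalist 20–30%).
Noise is independent normal per character (sd ≈ 0.012–0.025 on ratio
characters, 0.15 on log size) with an optional correlation matrix; an
`effect_scale` dial shrinks all archetype means toward their common
centroid, with 0 an exact null used for type-I calibration. The
default study design mirrors a realistic two-formation assemblage: 47
specimens in the composition 14/4/4/12/8/5 across the six clades,
split 25/22 across the two time bins, with clade-to-guild assignments
reflecting the described ecologies.

What the generator does *not* emulate: phylogenetic autocorrelation
(specimens are exchangeable within guilds; clade labels enter only
through the clade-to-guild map, so clade-level classification rates on
synthetic data reflect that map, not real phylogenetic signal),
measurement error and missing-data patterns of real fossils, and
within-guild allometry. Passing tests therefore demonstrate the
correctness and calibration of the statistical machinery, not the
empirical values any particular fossil dataset would yield.

## Calibration and problem sizes

The test suite calibrates the pipeline at sizes chosen to balance
Monte-Carlo resolution against runtime: type-I error of PERMANOVA and
the disparity permutation test is estimated from 1000 null
(`effect_scale = 0`) 47-specimen replicates at 199 permutations each
(with 199 draws and the add-one rule, the 5% level is exactly
attainable); power and guild recovery use 100 replicates of a balanced
8-per-guild design, where pairwise two-group tests are exact by
enumeration (12,870 splits); bootstrap-interval coverage uses 400
simulated 20-point groups with known covariance trace. The
`scripts/acceptance.R` report recomputes the same quantities at 500
null replicates.

## Known limitations

* Lever arms are straight-line proxies along the jaw axis; curvature
  of the ramus (marked in some durophagous taxa) is not modelled.
* The closing in-lever proxy `maL` conflates insertion length with
  moment arm; datasets with better landmark data should use `ILc`.
* The Wilcoxon matrix on bootstrap distributions is reported for
  comparability but is anti-conservative by construction.
* Sum of variances is the only disparity metric implemented; sums of
  ranges or hull volumes respond differently to sample size.
* No phylogenetic comparative correction is applied anywhere; all
  tests treat specimens as exchangeable within groups.

## A worked run

```{r, eval = FALSE}
cfg <- pipeline_config(simulation_config(seed = 7),
                       n_permutations = 999, n_bootstrap = 500,
                       seed = 7, out_dir = "jawspace_results")
res <- run_full_pipeline(cfg)
print(res)
plot_morphospace(res$ordination, res$table$records$guild)
```
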