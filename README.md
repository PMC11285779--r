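# jawspace

Quantitative functional morphology of vertebrate lower jaws, aimed at
the question palaeoecologists ask of sympatric marine predators: do
clades and tooth-based feeding guilds occupy distinct regions of a
biomechanical trait space, and how does their morphofunctional variety
compare?

The mandible is treated as a third-class lever with the fulcrum at the
articular glenoid. From thirteen raw measurements (mm) the package
computes eleven dimensionless characters — seven proportions rescaled
to mandibular length `ML` (gullet size `ASD/ML`, symphysis length and
depth `MSL/ML`, `MSD/ML`, tooth-row length `TRL/ML`, coronoid depth
`CPD/ML`, retroarticular length `RPL/ML`, adductor insertion
`maL/ML`), the tooth index `TI = LCH/ML`, and three mechanical
advantages

    aMA = ILc / (ML − RPL)            anterior bite point
    pMA = ILc / (ML − RPL − TRL)      rear of the tooth row
    oMA = RPL / (ML − RPL)            opening (low = fast-opening jaw)

plus `ltMA` at the largest-tooth bite point as an auxiliary (`ILc`
defaults to the adductor insertion length `maL` when no explicit
in-lever is recorded). The characters are z-scored and ordinated by
principal coordinates on Euclidean distances; group structure is then
tested with one-way and pairwise PERMANOVA (exact by enumeration for
small samples, seeded Monte-Carlo otherwise; Bonferroni and
Benjamini–Hochberg corrected), disparity is measured as the sum of
variances with bootstrap intervals and permutation tests, guild and
clade predictability is estimated by jackknifed linear discriminant
analysis, and individual metrics are compared pairwise with Welch t
and Wilcoxon tests. A seeded synthetic-assemblage generator encodes
one morphofunctional archetype per feeding guild (Cut, Generalist,
Pierce I, Pierce II, Smash, Crunch) so the whole pipeline is testable
and calibratable without specimen data.

## Worked example

```r
library(jawspace)

tab <- simulate_assemblage(simulation_config(seed = 7))
std <- zscore_matrix(character_matrix(tab))
ord <- pcoa(euclidean_distances(std))
print(ord)
#> Principal coordinate ordination: 47 specimens, 11 axes retained
#>   variance explained (first 3 axes): 56.3%, 16.8%, 9.3%

permanova_oneway(ord, tab$records$clade, n_permutations = 9999, seed = 7)
#> PERMANOVA (monte-carlo, 9999 permutations): pseudo-F(5, 41) = 6.8579, p = 0.0001
#>   groups: Geosaurinae, Metriorhynchinae, Ophthalmosauridae, Plesiosauroidea, ...

lda_jackknife(std, tab$records$guild)
#> Jackknifed LDA (characters, n = 47): 95.7% correctly classified
```

The ordination print shows how much of the total character variance
the leading axes carry; the PERMANOVA p-value is the permutation
probability of a pseudo-F at least as large as observed under random
label assignment (clades separate decisively here because the
simulated guild archetypes differ and clades map onto guilds); the LDA
rate is the leave-one-out fraction of specimens assigned to their true
guild. The biomechanics of a single jaw are equally direct:

```r
round(compute_characters(list(ML = 1000, ASD = 150, MSL = 300, MSD = 80,
                              TRL = 550, CPD = 120, RPL = 100, maL = 200,
                              LCH = 40, DLT = 450, ILc = 150)), 4)
#>  ASD.ML  MSL.ML  MSD.ML  TRL.ML  CPD.ML  RPL.ML      TI  maL.ML
#>  0.1500  0.3000  0.0800  0.5500  0.1200  0.1000  0.0400  0.2000
#>     aMA     pMA     oMA    ltMA      ML
#>  0.1667  0.4286  0.1111  0.3333  1000.0000
```

`run_full_pipeline(pipeline_config(...))` chains every stage and, with
`out_dir` set, writes a CSV results bundle plus a JSON manifest of
parameters, seeds and file hashes; `inst/scripts/jawspace-cli.R` is a
thin shell wrapper with `simulate` and `run-all` subcommands. To check
the pipeline against an external measurement table in the canonical
CSV schema, see `replicate_reference_analysis()`.

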