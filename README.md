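# hmoglyco

Label-free glycoprofiling of human milk oligosaccharide (HMO) consumption
from LC-MS feature tables.

## The problem

Human milk oligosaccharides are free glycans built from Glc, Gal, GlcNAc,
Fuc and Neu5Ac. Infant-gut bifidobacteria consume them selectively — some
*Bifidobacterium longum* strains preferentially deplete fucosylated
structures — and the evidence for such phenotypes is structure-resolved
quantification of an HMO pool before and after fermentation or enzymatic
digestion. `hmoglyco` implements that analysis for anyone working downstream
of LC-MS feature extraction: microbiologists profiling strain phenotypes,
glycobiologists characterizing enzyme specificity, and method developers who
need a transparent, testable replacement for vendor "in-house" scripts.

## What it computes

Each LC-MS feature (m/z or neutral mass, retention time, absolute peak
intensity *API* in ion counts) is annotated by exhaustive monosaccharide
composition decomposition within a ±20 ppm window of the theoretical mass

M(c) = n_Hex·162.052824 + n_HexNAc·203.079373 + n_Fuc·146.057909 +
n_Neu5Ac·291.095417 + 18.010565 [+ 2.015650 for alditols] Da,

assigned a structure name by retention-time matching against a library,
grouped with co-eluting isomers of identical composition (abundances
summed), and aligned across runs into a structure × sample matrix. Percent
consumption of sample *s* against the uninoculated external-standard pool
*c* is, over the *n* identified structures,

consumption = (1 − Σᵢ API_s,i / Σᵢ API_c,i) × 100%,

reported in total, per glycan class (neutral / fucosylated / sialylated /
fucosylated-sialylated) and per structure, with mean ± sd across replicates
at each fermentation time point. The same normalization against an
undigested pool yields per-structure enzyme digestion percentages. Also
included: microplate growth-curve summaries with the four-level maximum-OD
classification (−/+/++/+++ at 0.2/0.5/0.8), glycan-array six-replicate
trimmed means, and shared-motif extraction over IUPAC-condensed glycan
strings. Seeded simulators generate every input format with programmed
ground truth.

## Worked example

Simulate a triplicate fermentation sampled at four exponential-phase time
points (the default program depletes fucosylated structures first), run the
full pipeline, and profile a glycan class over time:

```r
library(hmoglyco)
sim <- simulate_fermentation(simulation_spec(seed = 42))
res <- run_pipeline(sim$features, sim$manifest)
print(res)
#> <hmo_pipeline>
#> <abundance_matrix> 157 structures x 13 samples | reference: control
#>   assigned rows: 27 | other rows: 130
#>   total consumption by sample:
#>     od0.2_r1        34.9%
#>     od0.2_r2        35.4%
#>     od0.2_r3        34.7%
#>     od0.4_r1        57.3%
#>     ...
#>     od0.75_r3       79.2%

temporal_profile(res$matrix, sim$manifest, level = "class") |>
  dplyr::filter(label == "fucosylated")
#> # A tibble: 4 × 8
#>   time_point level label       mean_pct sd_pct n_replicates clamped mean_raw
#>   <fct>      <chr> <chr>          <dbl>  <dbl>        <int> <lgl>      <dbl>
#> 1 od0.2      class fucosylated     54.9 0.760             3 FALSE       54.9
#> 2 od0.4      class fucosylated     85.2 0.384             3 FALSE       85.2
#> 3 od0.6      class fucosylated     94.9 0.176             3 FALSE       94.9
#> 4 od0.75     class fucosylated     97.0 0.0633            3 FALSE       97.0
```

All 27 library structures are recovered as assigned matrix rows (the 130
"other" rows are the per-run decoy features, which are never
structure-assigned and are excluded from consumption sums). Total
consumption climbs from ~35% at OD 0.2 to ~79% at OD 0.75, while the
fucosylated class is already 55% depleted at the first time point and ~97%
at the last — the preferential-fucosylation pattern programmed into the
generator, with sub-percent replicate scatter.

See `vignettes/hmo-glycoprofiling.Rmd` for the model, parameter and noise
assumptions, and design decisions.

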