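---
title: "Label-free glycoprofiling of HMO consumption: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-free glycoprofiling of HMO consumption: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(hmoglyco)
library(dplyr)
```

## The analysis problem

Human milk oligosaccharides (HMO) are free glycans built from five
monosaccharides — glucose, galactose, N-acetylglucosamine, fucose and
N-acetylneuraminic acid — spanning degrees of polymerization from roughly 3
to 32. Infant-gut bifidobacteria differ sharply in which HMO structures they
can import and degrade; some *Bifidobacterium longum* strains preferentially
consume fucosylated species. The measurement behind such claims is
**label-free glycoprofiling**: an HMO pool is fermented (or digested by a
purified enzyme), the remaining oligosaccharides are reduced to alditols,
separated on porous graphitized carbon and measured by accurate-mass LC-MS
in positive mode, and the depletion of every annotated structure is
quantified against an uninoculated aliquot of the same pool run as an
external standard.

This package implements that quantification pipeline downstream of feature
extraction: it takes one feature table per run (m/z or neutral mass,
retention time, absolute peak intensity "API" in ion counts) and produces
structure-, class- and pool-level percent consumption with replicate
statistics, plus the surrounding growth-curve classification and
glycan-array summaries that complete the phenotype.

## Annotation model

**Composition from accurate mass.** Every admissible composition
$c = (n_{Hex}, n_{HexNAc}, n_{Fuc}, n_{Neu5Ac})$ has theoretical neutral mass

$$M(c) = n_{Hex} M_{Hex} + n_{HexNAc} M_{HexNAc} + n_{Fuc} M_{Fuc} +
n_{Neu5Ac} M_{Neu5Ac} + M_{H_2O} + \delta_{red}\, M_{2H}$$

with residue monoisotopic masses fixed from atomic masses (Hex 162.052824,
HexNAc 203.079373, Fuc 146.057909, Neu5Ac 291.095417, water 18.010565,
alditol increment 2.015650 Da; the test suite re-derives each from elemental
formulas). `decompose_mass()` enumerates *all* compositions with DP between
the configured bounds (default 2–32) whose mass lies within the ppm window
(default ±20 ppm) of the observed neutral mass; the window is applied to the
neutral mass after charge/proton removal so that it behaves identically
across charge states. Glucose/galactose and the two HexNAcs are
mass-degenerate and are never distinguished at this stage.

**Structure from retention time.** A composition only becomes a named
structure when a library entry of that composition has a reference RT within
`rt_tol` (default 0.5 min) of the observed peak. Competing entries are
resolved by nearest RT, then smallest |ppm|; an exact RT tie is reported as
the shared isomer-group label rather than an arbitrary name. Features with a
composition but no RT match stay "composition-only" and are excluded from
consumption sums (their abundance share is logged), because the
normalization is defined over *identified* HMO.

**Isomer grouping.** Same-composition peaks closer than `coelution_tol`
(default 0.25 min, transitively chained) cannot be integrated separately;
their abundances are summed into one entry at the abundance-weighted mean
RT, labelled by the structure name or, when two assigned isomers merge, by
their isomer group. Total abundance is conserved exactly.

The packaged structure library (`hmo_library()`) carries literature
compositions for 27 commonly annotated structures. Its reference retention
times are **synthetic placeholders**: no public machine-readable RT library
exists for this separation, so the fixture lays structures out on a
plausible elution axis with ≥1.7 min separation inside each isomer group.
It supports simulation and testing, not annotation of real chromatograms.

## Alignment across runs

The upstream vendor workflow used an unpublished in-house aligner; this
package replaces it with an explicit deterministic rule set
(`align_runs()`): structure-assigned entries align by name;
composition-only entries cluster greedily by nearest RT within each
composition, seeding clusters from the external-standard run (the natural
anchor, since all quantities are normalized to it); entries with no
composition cluster by mass (ppm gate) and RT. No RT warping is attempted —
a documented limitation acceptable for the small jitter the generator
produces, and checked against an exact bipartite-matching oracle on small
instances in the tests.

## The consumption statistic

For a sample $s$ and the uninoculated control $c$, over the $n$ identified
structures with positive control abundance,

$$\text{consumption} = \left(1 - \frac{\sum_{i=1}^{n} API_{s,i}}
{\sum_{i=1}^{n} API_{c,i}}\right) \times 100\%$$

applied in total, per glycan class (neutral / fucosylated / sialylated /
fucosylated-sialylated, a partition driven purely by composition) and per
structure (where it reduces to $1 - API_{s}/API_{c}$). Enzyme digestion
percentages use the identical form with the undigested pool as reference.
Three conventions are deliberate choices where the source method is silent:

* **$n$ is fixed by the control pool** (structures detected there), not
  recomputed per sample, so a fully consumed structure counts as 100%
  rather than dropping out of the sum.
* **Negative raw values are clamped to 0 and flagged.** Sample-above-control
  is possible under multiplicative noise; only 0–100% is reported, with the
  raw value retained alongside.
* **Replicates are summarized as mean ± sd of per-replicate *raw*
  percentages**, and the mean is clamped afterwards. Clamping before
  averaging would bias unconsumed structures upward by roughly
  $0.4\,\sigma$; averaging raw values keeps the estimator unbiased.

An exact algebraic identity — total raw consumption equals the
control-abundance-weighted mean of per-structure raw consumptions — and
scale invariance under joint rescaling of both columns are asserted to
1e-9/1e-12 in the tests.

## Growth classification

Growth curves are blank-corrected (the un-inoculated substrate medium,
interpolated onto the sample time grid), summarized by maximum OD600 and by
ΔOD against the no-sugar control, and classified on maximum OD600 as
`-` (< 0.2), `+` (0.2–0.5), `++` (0.5–0.8), `+++` (> 0.8). The printed
thresholds share endpoints, so the boundary convention is explicit and
configurable: the default half-open `[lo, hi)` rule puts OD 0.5 in `++`.
Classification follows maximum OD (the convention the thresholds name);
ΔOD is reported alongside.

## Glycan arrays

Array screens report six replicate RFU values per glycan; the single highest
and lowest are removed and the remaining four averaged
(`trimmed_mean_rfu()`), which absorbs one outlier of either sign per set.
`parse_glycan()` losslessly parses the IUPAC-condensed dialect used on
mammalian arrays (anomers as `a`/`b` or α/β, parenthesized branches and
sulfation modifiers, trailing `-SpN` spacers), and `shared_motif()` walks
main chains from the non-reducing terminus: units must match fully
(residue, anomer, linkage, branches) to extend the motif, and a final
unit sharing only its residue contributes the bare residue name. Branches
therefore participate only when the branch point itself is shared — a
deliberately conservative rule that reproduces the published motif calls
for the two fucose-binding and the two weak galactose-binding examples
without inventing a general subtree-mining algorithm. Binder status uses a
trimmed-mean threshold of 100 RFU by default; screens publish no canonical
cutoff, so this is an explicit, exposed analysis choice.

```{r motifs}
shared_motif(list("Fuca1-2Galβ-Sp8", "Fuca1-2Galβ1-4Glcβ-Sp0"))
```

## The synthetic-data generator

All pipeline stages are exercised on seeded simulations
(`simulate_fermentation()`, `simulate_digestion()`, `simulate_growth()`,
`simulate_array()`) whose defaults mirror the experimental design they
emulate: an uninoculated control pool, four exponential-phase time points
(labelled by OD600 0.2 / 0.4 / 0.6 / 0.75) in triplicate, ±20 ppm
annotation window.

The noise model is an explicit set of assumptions, since no noise model is
published for this measurement:

* **Control abundances** are log-normal across structures
  (median 10^6 ion counts, CV 2), reflecting the orders-of-magnitude
  dynamic range of ion-count data.
* **Intensity noise** is multiplicative log-normal, default CV 5%, mean 1.
* **Mass error** is Gaussian in ppm (default sd 5) truncated at the
  ±20 ppm window; **RT jitter** is Gaussian (default sd 0.1 min, small
  against the 0.5 min assignment window and the ≥1.7 min isomer spacing).
* **Decoy features** (default 10 per run) are drawn ≥25 ppm away from every
  library mass, so they can never be structure-assigned and annotator
  precision is exactly scorable.
* The default consumption program ramps fucosylated structures to ~97%
  depletion early, neutral structures late, sialylated structures to ~40%
  — the preferential-fucosylation phenotype the pipeline is designed to
  resolve.

What the generator does **not** emulate: chromatographic drift and warping
between runs, isotope envelopes and charge-state mixtures, in-source
fragmentation, detector saturation, and missing peaks other than true
depletion. Passing tests therefore demonstrate correctness of the
quantification logic under the stated noise model, not robustness to every
pathology of real chromatograms.

A note on statistical power: with 5% multiplicative noise and triplicates,
a per-structure replicate-mean estimate has standard error
$\approx 5(1-f)/\sqrt{3}$ percentage points, so unconsumed structures carry
~2.9-point errors. A hard ±3-point band on every one of 25 structures is
then satisfied only about half the time — the test suite documents one such
fixed-seed check that sits on this boundary by construction; the mean
absolute recovery error (typically ≈1 point) is the informative summary.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run entirely on synthetic data
at modest sizes chosen to keep the whole suite under half a minute: 27
(or 25) library structures, 1–4 time points, 1–3 replicates, ≤25 decoys per
run, 200-mass decomposition sweeps, and brute-force oracles (full
composition enumeration; permutation-complete matching and trimmed-mean
checks) on instances small enough to enumerate exactly. Degenerate inputs
are defined, not accidental: an all-zero control column is an error; a
structure absent from the control is excluded with a warning; an empty
glycan class reports `NA`; zero-abundance features are legal and count as
full depletion; assignment ties fall back to the isomer-group label;
cluster founding order (control first, then manifest order, features by RT)
makes alignment deterministic under permutation of inputs.

## Known limitations

* Composition, not structure, is what mass determines; all structural
  identity rests on the RT library, and the packaged library's RTs are
  synthetic.
* Only [M+nH]^n+ ions are modelled; sodium/potassium adducts are out of
  scope.
* No RT warping: alignment assumes jitter well inside `rt_tol`.
* Consumption is relative to one external standard; no absolute (molar)
  quantification is attempted.
* The motif rule is a main-chain prefix; binding determinants internal to a
  chain or on unshared branches are not mined.
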