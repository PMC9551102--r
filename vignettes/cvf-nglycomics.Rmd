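---
title: "Methods: permethylated N-glycan profiling, annotation and cohort statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: permethylated N-glycan profiling, annotation and cohort statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvfglycomics)
```

## Scope and model

`cvfglycomics` implements the analysis side of a MALDI-TOF N-glycomics
workflow for mucosal fluids such as cervicovaginal fluid (CVF): N-glycans are
enzymatically released (PNGase F), permethylated, and profiled as sodiated
molecular ions; selected ions are fragmented to read out terminal epitopes
(glycotopes) from diagnostic B-type oxonium ions; per-sample fucosylation and
sialylation metrics are then related to phenotype labels (pregnancy status,
vaginal community state type, delivery outcome) and cytokine concentrations.
Wet-lab processing, instrument control, isotope-envelope deconvolution,
MS3-level isomer separation and 16S-based CST inference are out of scope; CST
enters only as a metadata label.

## The mass calculus

Permethylation replaces every free hydroxyl and amide hydrogen with a methyl
group, so each glycosyl residue contributes a fixed monoisotopic increment:

| residue class | formula (permethylated residue) | mass (Da) |
|---|---|---|
| Hex (Gal/Man/Glc) | C9H16O5 | 204.099774 |
| HexNAc (GlcNAc/GalNAc) | C11H19NO5 | 245.126323 |
| dHex (Fuc) | C8H14O4 | 174.089209 |
| NeuAc | C16H27NO8 | 361.173667 |

An intact permethylated free-reducing glycan adds the two end groups
(C2H6O, +46.041865 Da) and ionises as `[M+Na]+` (+22.989221 Da). B-type
oxonium fragments carry a terminal methyl cation (+15.022927 Da); a glycotope
cleaved from a chain interior has one fewer methylation site (−CH2,
14.015650 Da). Numerical choices made here:

* **Monoisotopic only.** MALDI labels of permethylated glycans match the
  monoisotopic peak; no average-mass mode is provided.
* **Truncation, not rounding.** Printed integer labels are the floor of the
  monoisotopic m/z (`mz_label()`): Man5GlcNAc2 computes to 1579.78 and is
  labelled 1579; Man9GlcNAc2 computes to 2396.18 and is labelled 2396.
* **Single adduct, single charge.** Only `[M+Na]+` for MS1; oxonium ions are
  non-sodiated. This reproduces every conventional MS1 and MS2 label without
  further adduct hypotheses.
* **End-group convention.** The +46.041865 Da constant is the free-reducing
  permethylated convention; reduced or tagged glycans would need a different
  constant, which is why the full mass table is exposed via
  `residue_masses()`.

## Composition annotation

`decompose_mass()` enumerates all residue-count tuples within bounds
(defaults: Hex ≤ 15, HexNAc ≤ 12, dHex ≤ 10, NeuAc ≤ 4, enough to cover
glycans beyond m/z 6000) whose theoretical m/z falls within the tolerance
(default ±0.5 Da, a MALDI-TOF reflector scale) and that pass the
biosynthetic-plausibility filter:

* chitobiose core: HexNAc ≥ 2, Hex ≥ 2;
* HexNAc = 2 is the paucimannose/high-mannose family: Hex ≤ 9, no NeuAc,
  dHex ≤ 1;
* antennary glycans (HexNAc ≥ 3) keep the trimannosyl core (Hex ≥ 3);
* NeuAc ≤ antennae (HexNAc − 2); dHex ≤ 1 + 2 per antenna (core fucose plus
  Lewis-Y-type difucosylation).

Candidates are ranked by absolute mass error, then fewer residues, then
lexicographically — fully deterministic. `annotate_peaklist()` assigns each
peak its top-ranked candidate (the "dominant" assignment for overlapped
clusters), flags peaks that only match the permethylated hexose-polymer
ladder as contaminants, and drops (and counts) everything else.

Interpretation choices, isolated so they are easy to revise:

* **LacNAc counting** assumes no bisecting GlcNAc: `lacnac_units =
  HexNAc − 2`. Truncated antennae (fewer galactoses than LacNAc units) keep
  their LacNAc count.
* **Hybrid rule.** HexNAc = 3 with Hex ≥ 5 is classified hybrid; HexNAc = 3
  with Hex < 5 is a truncated complex glycan. The boundary is one line in
  `classify_glycan()`.
* **Gal/Man split.** For hybrid/complex glycans `gal_count = Hex − 3`
  attributes three hexoses to the core.
* Sulfated/phosphorylated species are not searched.

Above roughly m/z 4100 some biosynthetically plausible compositions differ
by as little as 0.011 Da (a 3 Hex + 4 HexNAc for 5 dHex + 2 NeuAc exchange),
so composition assignment there is inherently tolerance-limited; the
round-trip guarantee ("the generating composition ranks first") is asserted
below 3000 Da only.

## Quantitation

All per-sample metrics are ratios of summed intensities and therefore
scale-invariant; `normalize_to_base_peak()` (most abundant non-contaminant
component = 100%) is provided for display. Quantitative analysis defaults to
complex glycans with 2 or 3 LacNAc units — the strata least affected by
overlapped isotopic clusters — with other strata available via the `lacnac`
argument. Fucosylation degrees are binned 0, 1, 2, 3 and 4+ (the 4+ bin
absorbs the Fuc5–9 species seen in heavily fucosylated samples).
Poly-fucosylated means ≥ 2 Fuc; highly fucosylated means ≥ 3 Fuc in the
2-LacNAc stratum and ≥ 4 in the 3-LacNAc stratum, expressed relative to the
poly-fucosylated intensity. Sialylation % is computed both against the
poly-fucosylated intensity and within each fucosylation bin. Empty strata
propagate as `NA`, never as zeros, so cohort statistics are not biased by
absent denominators.

## Glycotope index

The nine diagnostic oxonium ions (truncated labels 260, 505, 624, 638, 679,
812, 999, 1261, 1435) are matched at 5 ppm (high-resolution Orbitrap
accuracy), summed across all MS2 spectra of a run, and normalised to their
grand total. Two documented decisions: normalisation is over **all nine**
definitions, zeros included (the alternative — detected ions only — changes
the denominator sample by sample and makes indices incomparable); and a peak
within tolerance of two custom definitions is assigned to the nearer m/z
(with the default table the closest pair is > 10 ppm apart at the largest
member, so this cannot trigger). Note that 5 ppm at m/z 505 is ±0.0025 Da:
peak lists rounded to two decimals may fall outside the window, so inputs
should carry at least three decimals (or widen `ppm_tolerance`).

## Cohort statistics

`correlate_feature()` is the Pearson product-moment correlation with the
two-sided p from the t distribution (n − 2 df) and the OLS regression of
cytokine on feature, after pairwise deletion of missing values (n ≥ 3
required; zero variance yields an explicit undefined marker).
`compare_groups()` is the classical pooled-variance Student's t test
(two-sided), with Welch behind a flag; singleton groups report means with an
undefined p rather than failing. No multiple-testing correction is applied
by default; `correlate_features(p_adjust = "BH")` provides
Benjamini–Hochberg. Cytokines are used on the raw pg/mL scale by default
with an optional `log(x + 1)` transform.

## The synthetic-cohort generator

Because raw clinical spectra are not redistributable, the generator is the
package's test bed: it emits exactly what the pipeline consumes (MS1 peak
lists, MS2 diagnostic-ion spectra, metadata with cytokines) with known
ground truth.

**What it emulates.** Each phenotype profile fixes a glycan-class mixture, a
mean fucosylation-degree distribution per LacNAc stratum, a per-glycan
sialylation probability, an antenna-truncation rate and a glycotope mixture.
Per sample, the fucosylation vectors are Dirichlet-perturbed (concentration
25, i.e. a between-donor sd of ≈ 0.09 on a 0.3 proportion — donor-to-donor
spread in mucosal glycomes is wide), glycan abundances get log-normal
dispersion (sd 0.3 beyond the composition-driven mixture), rendered peaks
get 0.05 Da m/z jitter, multiplicative measurement noise (log-sd 0.1) and
polyhexose ladder contaminants (rate 0.25 per ladder position Hex5–Hex12).
Cytokine concentrations couple linearly to the true non-fucosylated
proportion of the 2-LacNAc stratum, floored at 0; the noise sd can be given
directly or derived from a prescribed Pearson correlation against the
realised feature spread. The shipped profiles encode the qualitative
phenotype orderings the analysis is meant to detect: CST IV-like samples
shift towards non-/mono-fucosylated, weakly sialylated (probability 0.2 vs
0.6), antenna-truncated glycans; non-pregnant samples are
high-mannose-dominant with heavy poly-fucosylation.

**Allocation, not multinomial draws.** Panel counts are assigned by
largest-remainder proportional allocation of `n_glycans` over the
composition pool. A real spectrum integrates the ensemble abundances of
~10^9 molecules, so per-molecule multinomial noise at a panel size of a few
hundred would be an artifact of the discretisation, not a property of the
measurement; allocation keeps the panel's composition faithful to the
generating distribution at any panel size while all modelled variability
(Dirichlet, log-normal, measurement noise, jitter) remains.

**Determinism.** Every sample uses a substream seed derived arithmetically
from the cohort seed and the sample index, so identical configurations are
byte-identical and adding samples never reshuffles earlier ones.

**What it does not emulate.** Isotopic envelopes, profile-mode peak shapes,
chromatography, adduct heterogeneity, true biological covariance between
classes and strata, or real cytokine distributions. Passing the synthetic
recovery and calibration checks therefore demonstrates that the pipeline's
arithmetic and statistics are faithful under the stated noise model — not
that any biological claim about real cohorts is reproduced.

## Validation experiments and problem sizes

The shipped test suite runs, among unit and property tests:

* **Mass golden values**: every conventional printed MS1/MS2 label above,
  exactly.
* **Oracle equivalence**: the residue-table path against an independent
  elemental-formula calculator (< 1e-4 Da on 100 random compositions); the
  decomposition against a quadruple-nested-loop reference on 50 random
  masses.
* **Round trip**: 200 random plausible compositions recovered at ±0.3 Da.
* **Partition identities**: proportions sum to 1, poly = 1 − non − mono, and
  by-bin sialylation aggregates to the poly-fucosylated definition, on 100
  random annotation sets.
* **Parameter recovery**: with a complex-glycan-only profile whose 500
  glycans are allocated to the stratum under test, and the measurement stage
  noise-free (no m/z jitter, no per-peak intensity noise; the within-sample
  biological dispersion stays on), the mean L1 distance between
  pipeline-estimated and generating fucosylation vectors stays below 0.05 in
  both strata (6 samples). The measurement stage must be noise-free here
  because per-peak noise does not shrink with panel size — the number of
  distinct peaks is fixed by the composition pool — so recovery with it in
  the loop would measure the noise floor, not estimator convergence.
* **Correlation calibration**: 200 replicate cohorts of n = 50 samples with
  a prescribed feature–cytokine correlation of 0.6; the pipeline-estimated r
  falls inside the 95% Fisher-z sampling interval of 0.6 in ≥ 90% of
  replicates, and the coupling sign is recovered at p < 0.05.
* **Phenotype contrast**: with generating sialylation probabilities 0.6
  (CST I-like) vs 0.2 (CST IV-like), cohort-pooled sialylation % is lower in
  the CST IV-like arm in every fucosylation bin of both strata (10 + 10
  samples; pooling keeps sparse high-Fuc bins populated in every run).

These problem sizes (500 glycans/sample, cohorts of 6–50, 200 replicates)
were chosen as the smallest at which the corresponding sampling intervals
are decisive; they complete in a few minutes on one core.

## Known limitations

* Composition-level annotation cannot resolve linkage or isomerism (core vs
  antenna fucose, Lewis X vs A vs H, branching vs poly-LacNAc extension);
  MS2/MS3 evidence is needed and only enters here through the composite
  glycotope index.
* The dominant-assignment rule keeps exactly one composition per peak; true
  overlapped clusters contribute their full intensity to that one
  composition.
* Near-isobars above ~m/z 4100 limit assignment confidence at MALDI-TOF
  tolerances regardless of implementation.
* The pooled t test and Pearson correlation inherit their usual small-n
  caveats; with cohorts the size of typical pilot studies (n ≈ 10) they
  describe trends, not confirmatory inference.
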