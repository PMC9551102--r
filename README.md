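# cvfglycomics

Analysis pipeline for MALDI-TOF N-glycomics of mucosal fluids such as
cervicovaginal fluid (CVF). N-glycans released by PNGase F and permethylated
are profiled as sodiated molecular ions; this package turns the resulting
centroided peak lists into annotated glycan compositions, per-sample
fucosylation/sialylation metrics and a glycotope index, and relates those
features to phenotype labels (pregnancy status, vaginal community state
type, delivery outcome) and cytokine concentrations. A fully seeded
synthetic-cohort generator makes every stage testable end to end without
clinical spectra.

It is written for glycomics and reproductive-health researchers who have
peak lists (TSV/CSV, `mz` + `intensity`) and sample metadata, and want the
derivation from m/z to cohort statistics to be explicit, deterministic and
tested.

## The core calculus

A fully permethylated glycosyl residue contributes a fixed monoisotopic
increment: Hex 204.0998, HexNAc 245.1263, dHex (Fuc) 174.0892, NeuAc
361.1737 Da. An intact free-reducing permethylated glycan with composition
(n1 Hex, n2 HexNAc, n3 dHex, n4 NeuAc) has

    [M+Na]+  =  Σ nᵢ·mᵢ  +  46.0419 (end groups, C2H6O)  +  22.9892 (Na⁺)

and B-type oxonium fragments (cleavage at HexNAc) have

    B  =  Σ nᵢ·mᵢ  +  15.0229 (CH3⁺);   internal glycotopes: − 14.0157 (CH2)

Printed spectrum labels are the floor of these values: Man3GlcNAc2 computes
to 1171.5831 and is labelled 1171. Composition annotation inverts this map
by bounded enumeration under N-glycan biosynthetic constraints (chitobiose
core, trimannosyl core for antennary glycans, ≤ 1 NeuAc per antenna,
≤ 1 + 2·antennae Fuc), ranked deterministically by mass error.

Quantitation follows the standard fucosylation-stratified conventions:
intensity proportions by Fuc count (0, 1, 2, 3, 4+) within the 2- and
3-LacNAc strata, poly-fucosylated (≥ 2 Fuc) and highly-fucosylated
(≥ 3 or ≥ 4 Fuc by stratum) fractions, sialylation % against poly-fucosylated
intensity or within each Fuc bin, and Pearson/Student statistics against
metadata. The methods vignette (`vignettes/cvf-nglycomics.Rmd`) documents
every rule, default and limitation.

## Worked example

```r
library(cvfglycomics)

# mass calculus: a tri-fucosylated biantennary glycan
sodiated_mz("Gal2Man3GlcNAc4Fuc3")        # 2592.3029
mz_label(sodiated_mz("Gal2Man3GlcNAc4Fuc3"))  # 2592, the printed label

# composition annotation of an observed peak
decompose_mass(2592.30, tolerance = 0.5)
#>   hex hexnac dhex neuac mz_theoretical  mass_error
#> 1   5      4    3     0       2592.303 -0.00287119

# synthetic cohort: 4 CST I-like + 4 CST IV-like samples
cfg   <- cohort_config(n_samples = c(cst_i = 4L, cst_iv = 4L), seed = 42)
coh   <- generate_cohort(cfg)
feats <- cohort_features(coh$peaks, ms2 = coh$ms2)

correlate_feature(feats, coh$metadata, "fuc0_lacnac2", "IL1B")
#> Pearson correlation: IL1B ~ fuc0_lacnac2
#>   n = 8, r = 0.6264, two-sided p = 0.09654
#>   OLS: IL1B = 1.624 + 2973 * fuc0_lacnac2

compare_groups(feats, coh$metadata, "sial_polyfuc_lacnac2", "cst")
#> Student (pooled) t test: sial_polyfuc_lacnac2 by cst
#>   I-A: n = 4, mean = 57.95
#>   IV-B: n = 4, mean = 20.99
#>   t = 20.6217, two-sided p = 8.46e-07
```

The correlation is positive (the generator couples IL-1β to the
non-fucosylated proportion with prescribed r = 0.6; at n = 8 the estimate is
noisy and not yet significant), and the sialylation contrast between
community state types is large and highly significant, matching the
generating sialylation probabilities of 0.6 vs 0.2. With real data, replace
`generate_cohort()` by `read_peaklist()` on your TSV/CSV files and supply
your own metadata table keyed by `sample_id`.

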