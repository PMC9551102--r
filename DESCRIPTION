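Package: cvfglycomics
Title: Compositional Annotation and Quantitation of Permethylated N-Glycan
    Mass Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for MALDI-TOF profiling of permethylated,
    PNGase-F-released N-glycans from mucosal fluids such as cervicovaginal
    fluid. Provides exact monoisotopic mass arithmetic for sodiated molecular
    ions and B-type oxonium fragments of permethylated glycans, decomposition
    of MS1 peak lists into monosaccharide compositions under N-glycan
    biosynthetic constraints, glycan-class assignment, per-sample fucosylation
    and sialylation metrics, a glycotope relative-abundance index from
    diagnostic MS2 oxonium ions, cohort-level correlation of glycan features
    with cytokine concentrations and phenotype labels, and a fully seeded
    synthetic-cohort generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
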