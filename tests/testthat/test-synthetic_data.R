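test_that("profiles validate their fields and name offenders", {
  expect_s3_class(profile_cst_i(), "phenotype_profile")
  expect_s3_class(profile_cst_iv(), "phenotype_profile")
  expect_s3_class(profile_nonpregnant(), "phenotype_profile")
  expect_error(phenotype_profile(sial_prob = 1.4), "sial_prob")
  expect_error(phenotype_profile(class_weights = c(paucimannose = 1, high_mannose = 1,
                                                   hybrid = 0, complex = 0)),
               "class_weights")
  expect_error(phenotype_profile(fuc_probs = list(`2` = c(1, 0, 0, 0),
                                                  `3` = c(1, 0, 0, 0, 0))),
               "fuc_probs")
  expect_error(phenotype_profile(dirichlet_conc = -1), "dirichlet_conc")
})

test_that("panels respect the profile's compositional constraints", {
  set.seed(60)
  hm_only <- phenotype_profile(class_weights = c(paucimannose = 0, high_mannose = 1,
                                                 hybrid = 0, complex = 0))
  p <- sample_glycan_panel(hm_only, 300)
  expect_true(all(p$hexnac == 2L))
  expect_true(all(p$hex >= 5 & p$hex <= 9))
  expect_true(all(biosynthetically_plausible(p$hex, p$hexnac, p$dhex, p$neuac)))

  nofuc <- phenotype_profile(fuc_probs = list(`2` = c(1, 0, 0, 0, 0),
                                              `3` = c(1, 0, 0, 0, 0)),
                             dirichlet_conc = Inf)
  p2 <- sample_glycan_panel(nofuc, 400)
  expect_true(all(p2$dhex[p2$glycan_class == "complex"] == 0L))
  expect_equal(sum(p2$count), 400)
})

test_that("panels and cohorts are reproducible from the seed", {
  prof <- profile_cst_i()
  set.seed(61); a <- sample_glycan_panel(prof, 200)
  set.seed(61); b <- sample_glycan_panel(prof, 200)
  expect_identical(a, b)
  cfg <- cohort_config(n_samples = c(cst_i = 2L, cst_iv = 2L),
                       n_glycans = 200, seed = 11)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$peaks, c2$peaks)
  expect_identical(c1$ms2, c2$ms2)
  expect_identical(c1$metadata, c2$metadata)
  # per-sample substreams: adding samples must not reshuffle earlier ones
  cfg_big <- cohort_config(n_samples = c(cst_i = 3L, cst_iv = 2L),
                           n_glycans = 200, seed = 11)
  c3 <- generate_cohort(cfg_big)
  expect_identical(c3$peaks[["S01"]], c1$peaks[["S01"]])
  expect_identical(c3$peaks[["S02"]], c1$peaks[["S02"]])
})

test_that("noiseless rendering round-trips every composition through annotation", {
  set.seed(62)
  prof <- phenotype_profile(mz_jitter_sd = 0, contaminant_rate = 0)
  panel <- sample_glycan_panel(prof, 400)
  ann <- annotate_peaklist(render_peaklist(panel, prof), tolerance = 0.5)
  expect_equal(attr(ann, "n_dropped"), 0L)
  key <- function(d) sort(paste(d$hex, d$hexnac, d$dhex, d$neuac))
  expect_identical(key(ann[!ann$contaminant, ]), key(panel))
})

test_that("small m/z jitter keeps recovery near-perfect at the default tolerance", {
  set.seed(63)
  prof <- phenotype_profile(mz_jitter_sd = 0.1, contaminant_rate = 0)
  hits <- 0; total <- 0
  for (i in 1:4) {
    panel <- sample_glycan_panel(prof, 300)
    ann <- annotate_peaklist(render_peaklist(panel, prof), tolerance = 0.5)
    ann <- ann[!ann$contaminant, ]
    akey <- paste(ann$hex, ann$hexnac, ann$dhex, ann$neuac)
    key <- paste(panel$hex, panel$hexnac, panel$dhex, panel$neuac)
    hits <- hits + sum(panel$count[key %in% akey])
    total <- total + sum(panel$count)
  }
  expect_gte(hits / total, 0.99)  # per glycan; losses are rare near-isobars
})

test_that("contaminant ladder injection matches the configured rate", {
  set.seed(64)
  prof <- phenotype_profile(contaminant_rate = 0.2)
  n_inj <- 0L; n_pos <- 0L
  for (i in 1:60) {
    panel <- sample_glycan_panel(prof, 100)
    ann <- annotate_peaklist(render_peaklist(panel, prof))
    n_inj <- n_inj + sum(ann$contaminant)
    n_pos <- n_pos + 8L   # ladder positions Hex5..Hex12 per rendering
  }
  # binomial check: observed rate within 4 sd of 0.2
  se <- sqrt(0.2 * 0.8 / n_pos)
  expect_lt(abs(n_inj / n_pos - 0.2), 4 * se)
})

test_that("cohort metadata couples cytokines to fucosylation as configured", {
  cyt0 <- data.frame(name = "IL1B", alpha = 100, beta = 0, rho = NA_real_,
                     sigma = 25, stringsAsFactors = FALSE)
  cfg0 <- cohort_config(profiles = list(cst_i = profile_cst_i()),
                        n_samples = c(cst_i = 60L), n_glycans = 150,
                        cytokines = cyt0, seed = 9)
  coh0 <- generate_cohort(cfg0)
  r0 <- cor(coh0$truth$samples$true_fuc0_lacnac2, coh0$metadata$IL1B)
  expect_lt(abs(r0), 0.3)   # beta = 0: no coupling
  # positive coupling with prescribed rho
  cfg1 <- cohort_config(profiles = list(cst_i = profile_cst_i()),
                        n_samples = c(cst_i = 40L), n_glycans = 150, seed = 10)
  coh1 <- generate_cohort(cfg1)
  expect_gt(cor(coh1$truth$samples$true_fuc0_lacnac2, coh1$metadata$IL1B), 0.3)
  expect_true(all(coh1$metadata$IL1B >= 0))
  expect_setequal(names(coh1$peaks), coh1$metadata$sample_id)
})

test_that("invalid cohort configuration names the offending fields", {
  expect_error(cohort_config(n_samples = c(wrong = 2L)), "n_samples")
  expect_error(cohort_config(n_glycans = 0), "n_glycans")
  expect_error(cohort_config(profiles = list(a = 1)), "profiles")
  bad_cyt <- data.frame(name = "IL1B", alpha = 0, beta = 0, rho = NA_real_,
                        sigma = NA_real_, stringsAsFactors = FALSE)
  cfg <- cohort_config(profiles = list(cst_i = profile_cst_i()),
                       n_samples = c(cst_i = 3L), n_glycans = 100,
                       cytokines = bad_cyt, seed = 2)
  expect_error(generate_cohort(cfg), "sigma")
})
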