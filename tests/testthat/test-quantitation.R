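test_that("base-peak normalisation designates the top non-contaminant 100%", {
  ann <- make_ann(fuc = c(0, 1), neuac = 0, intensity = c(50, 200))
  out <- normalize_to_base_peak(ann)
  expect_equal(out$rel_intensity, c(25, 100))
  single <- normalize_to_base_peak(make_ann(0, 0, 10))
  expect_equal(single$rel_intensity, 100)
  # contaminants are excluded from the max and get NA
  ann2 <- rbind(make_ann(0, 0, 200, contaminant = TRUE), make_ann(1, 0, 50))
  out2 <- normalize_to_base_peak(ann2)
  expect_equal(out2$rel_intensity, c(NA, 100))
  expect_error(normalize_to_base_peak(make_ann(0, 0, 10, contaminant = TRUE)),
               "contaminant")
})

test_that("fucosylation profile computes intensity proportions by degree", {
  ann <- make_ann(fuc = c(0, 1, 2), neuac = 0, intensity = c(30, 50, 20))
  expect_equal(fucosylation_profile(ann, 2),
               c(fuc0 = 0.3, fuc1 = 0.5, fuc2 = 0.2, fuc3 = 0, fuc4p = 0))
  expect_equal(unname(fucosylation_profile(make_ann(0, 0, 10), 2)),
               c(1, 0, 0, 0, 0))
  # the 4+ bin absorbs higher degrees
  ann5 <- make_ann(fuc = c(4, 5), neuac = 0, intensity = c(10, 30))
  expect_equal(fucosylation_profile(ann5, 2)[["fuc4p"]], 1)
  # six-glycan toy set against hand-computed proportions
  toy <- make_ann(fuc = c(0, 0, 1, 2, 3, 4), neuac = 0,
                  intensity = c(10, 20, 30, 40, 50, 60))
  expect_equal(unname(fucosylation_profile(toy, 2)),
               c(30, 30, 40, 50, 60) / 210)
  expect_error(fucosylation_profile(toy, 3), "3 LacNAc")
  expect_true(all(is.na(fucosylation_profile(toy, 3, strict = FALSE))))
})

test_that("poly- and highly-fucosylated fractions use the stratum-specific cutoffs", {
  ann <- make_ann(fuc = c(0, 2, 3), neuac = 0, intensity = c(50, 30, 20))
  ph <- poly_and_highly_fucosylated(ann, 2)
  expect_equal(ph$poly, 0.5)
  expect_equal(ph$highly, 0.4)
  # no poly-fucosylated glycans: ratio missing, never 0
  ph0 <- poly_and_highly_fucosylated(make_ann(0, 0, 100), 2)
  expect_equal(ph0$poly, 0)
  expect_true(is.na(ph0$highly))
  # cutoff moves to >= 4 Fuc in the 3-LacNAc stratum
  ann3 <- make_ann(fuc = c(2, 4), neuac = 0, intensity = c(10, 10), lacnac = 3)
  ph3 <- poly_and_highly_fucosylated(ann3, 3)
  expect_equal(ph3$poly, 1)
  expect_equal(ph3$highly, 0.5)
  ann2 <- make_ann(fuc = c(2, 4), neuac = 0, intensity = c(10, 10))
  expect_equal(poly_and_highly_fucosylated(ann2, 2)$highly, 0.5)
})

test_that("sialylation percentages match both definitions", {
  ann <- make_ann(fuc = c(2, 2, 0), neuac = c(1, 0, 1),
                  intensity = c(30, 30, 40))
  expect_equal(sialylation_pct(ann, 2, mode = "vs_polyfuc"), 50)
  by <- sialylation_pct(ann, 2, mode = "by_fuc_group")
  expect_equal(by[["fuc0"]], 100)
  expect_equal(by[["fuc2"]], 50)
  expect_true(is.na(by[["fuc1"]]))
  # no sialylation anywhere
  none <- make_ann(fuc = c(0, 2), neuac = 0, intensity = c(10, 10))
  expect_equal(sialylation_pct(none, 2, mode = "vs_polyfuc"), 0)
  expect_equal(unname(sialylation_pct(none, 2, mode = "by_fuc_group")[c(1, 3)]),
               c(0, 0))
  # eight-glycan toy table against hand computation
  toy <- make_ann(fuc = c(0, 0, 1, 1, 2, 2, 3, 3),
                  neuac = c(1, 0, 0, 0, 1, 1, 0, 1),
                  intensity = c(5, 15, 10, 30, 20, 20, 10, 30))
  by8 <- sialylation_pct(toy, 2, mode = "by_fuc_group")
  expect_equal(unname(by8[1:4]), c(100 * 5 / 20, 0, 100, 75))
  expect_equal(sialylation_pct(toy, 2, mode = "vs_polyfuc"),
               100 * (20 + 20 + 30) / 80)
})

test_that("class summary is intensity weighted and sums to one", {
  ann <- rbind(make_ann(0, 0, 10, glycan_class = "paucimannose", lacnac = 0),
               make_ann(0, 0, 10, glycan_class = "high_mannose", lacnac = 0),
               make_ann(0, 0, 10, glycan_class = "hybrid", lacnac = 1),
               make_ann(0, 0, 10, glycan_class = "complex"))
  expect_equal(unname(class_summary(ann)), rep(0.25, 4))
  hm <- make_ann(0, 0, 10, glycan_class = "high_mannose", lacnac = 0)
  expect_equal(unname(class_summary(hm)), c(0, 1, 0, 0))
  wt <- rbind(make_ann(0, 0, 30, glycan_class = "paucimannose", lacnac = 0),
              make_ann(0, 0, 70, glycan_class = "complex"))
  expect_equal(unname(class_summary(wt)), c(0.3, 0, 0, 0.7))
})

test_that("quantitation invariants hold on random annotation sets", {
  set.seed(46)
  for (i in 1:40) {
    n <- sample(5:30, 1)
    ann <- make_ann(fuc = sample(0:6, n, replace = TRUE),
                    neuac = sample(0:2, n, replace = TRUE),
                    intensity = runif(n, 0.1, 100))
    fp <- fucosylation_profile(ann, 2)
    expect_equal(sum(fp), 1, tolerance = 1e-9)
    # scale invariance
    ann_scaled <- ann; ann_scaled$intensity <- ann$intensity * runif(1, 0.01, 50)
    expect_equal(fucosylation_profile(ann_scaled, 2), fp, tolerance = 1e-9)
    # partition identity
    ph <- poly_and_highly_fucosylated(ann, 2)
    expect_equal(ph$poly, 1 - fp[["fuc0"]] - fp[["fuc1"]], tolerance = 1e-9)
    # by-group sialylation aggregates to the vs-polyfuc definition
    by <- sialylation_pct(ann, 2, mode = "by_fuc_group")
    w <- vapply(0:4, function(d) {
      b <- pmin(ann$fuc, 4) == d
      sum(ann$intensity[b])
    }, numeric(1))
    poly_bins <- 3:5
    if (sum(w[poly_bins]) > 0) {
      agg <- sum(by[poly_bins] * w[poly_bins], na.rm = TRUE) / sum(w[poly_bins])
      expect_equal(agg, sialylation_pct(ann, 2, mode = "vs_polyfuc"),
                   tolerance = 1e-9)
    }
  }
})

test_that("feature assembly propagates missing strata as NA", {
  ann <- make_ann(fuc = c(0, 2), neuac = c(0, 1), intensity = c(10, 30))
  f <- glycan_features(ann, sample_id = "A")
  expect_equal(f$sample_id, "A")
  expect_equal(f$fuc0_lacnac2, 0.25)
  expect_true(is.na(f$fuc0_lacnac3))
  expect_true(is.na(f$highfuc_lacnac3))
  expect_equal(f$prop_complex, 1)
})
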