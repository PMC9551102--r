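test_that("biosynthetic plausibility implements the pathway constraints", {
  expect_true(biosynthetically_plausible(composition(hex = 3, hexnac = 2, dhex = 1)))
  expect_true(biosynthetically_plausible(composition(hex = 12, hexnac = 11, dhex = 6)))
  expect_true(biosynthetically_plausible(composition(hex = 9, hexnac = 2)))
  # sialic acid with no antenna
  expect_false(biosynthetically_plausible(composition(hex = 2, hexnac = 2, neuac = 1)))
  # more than one fucose on a hexnac-2 glycan
  expect_false(biosynthetically_plausible(composition(hex = 3, hexnac = 2, dhex = 2)))
  # hexnac-2 glycans cap at Man9
  expect_false(biosynthetically_plausible(composition(hex = 10, hexnac = 2)))
  # antennary glycans keep the trimannosyl core
  expect_false(biosynthetically_plausible(composition(hex = 2, hexnac = 4)))
  # per-antenna caps on NeuAc and Fuc
  expect_false(biosynthetically_plausible(composition(hex = 5, hexnac = 4, neuac = 3)))
  expect_false(biosynthetically_plausible(composition(hex = 5, hexnac = 4, dhex = 6)))
  expect_true(biosynthetically_plausible(composition(hex = 5, hexnac = 4, dhex = 5)))
  # missing chitobiose core
  expect_false(biosynthetically_plausible(composition(hex = 5, hexnac = 1)))
})

test_that("glycan classification follows the hexnac/hex rules", {
  expect_equal(classify_glycan("Man3GlcNAc2"),
               list(glycan_class = "paucimannose", lacnac_units = 0L,
                    gal_count = 0L))
  expect_equal(classify_glycan("Man5GlcNAc2")$glycan_class, "high_mannose")
  hyb <- classify_glycan(composition(hex = 5, hexnac = 3))
  expect_equal(hyb$glycan_class, "hybrid")
  expect_equal(hyb$lacnac_units, 1L)
  expect_equal(hyb$gal_count, 2L)
  cx <- classify_glycan(composition(hex = 5, hexnac = 4, neuac = 2))
  expect_equal(cx, list(glycan_class = "complex", lacnac_units = 2L,
                        gal_count = 2L))
  # truncated antennae keep the LacNAc count
  tr <- classify_glycan(composition(hex = 4, hexnac = 5))
  expect_equal(tr$glycan_class, "complex")
  expect_equal(tr$lacnac_units, 3L)
  expect_equal(tr$gal_count, 1L)
  # hexnac = 3 with hex < 5 is complex, not hybrid
  expect_equal(classify_glycan(composition(hex = 4, hexnac = 3))$glycan_class,
               "complex")
  expect_error(classify_glycan(composition(hex = 2, hexnac = 2, neuac = 1)),
               "plausible")
})

test_that("mass decomposition matches known compositions and edge cases", {
  d <- decompose_mass(1171.6, tolerance = 0.5)
  expect_equal(nrow(d), 1L)  # unique under default bounds
  expect_equal(unlist(d[1, c("hex", "hexnac", "dhex", "neuac")]),
               c(hex = 3, hexnac = 2, dhex = 0, neuac = 0),
               ignore_attr = TRUE)
  d <- decompose_mass(6259.1, tolerance = 0.5)
  hit <- d$hex == 12 & d$hexnac == 11 & d$dhex == 6 & d$neuac == 0
  expect_true(any(hit))
  expect_equal(nrow(decompose_mass(50, tolerance = 0.5)), 0L)
  expect_error(decompose_mass(1171.6, tolerance = 0), "tolerance")
  expect_error(decompose_mass(-5), "positive")
})

test_that("decomposition agrees with the brute-force nested-loop oracle", {
  set.seed(43)
  mzs <- runif(50, 1000, 5200)
  for (mz in mzs) {
    got <- decompose_mass(mz, tolerance = 0.4)
    ref <- oracle_decompose(mz, tolerance = 0.4)
    key <- function(d) sort(paste(d$hex, d$hexnac, d$dhex, d$neuac))
    expect_identical(key(got), key(ref), info = sprintf("mz=%.3f", mz))
  }
})

test_that("round trip recovers random plausible compositions", {
  set.seed(44)
  for (i in 1:60) {
    cc <- random_plausible_composition()
    d <- decompose_mass(sodiated_mz(cc), tolerance = 0.3)
    hit <- d$hex == cc[["hex"]] & d$hexnac == cc[["hexnac"]] &
      d$dhex == cc[["dhex"]] & d$neuac == cc[["neuac"]]
    expect_true(any(hit))
    if (sodiated_mz(cc) < 3000) expect_true(hit[1])  # ranks first
  }
})

test_that("peak lists validate, sort and read from delimited files", {
  pk <- peaklist(c(2000, 1000), c(1, 2))
  expect_equal(pk$mz, c(1000, 2000))
  expect_error(peaklist(c(-1, 2), c(1, 1)), "positive")
  expect_error(peaklist(1000, -3), "non-negative")
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(mz = c(1171.58, 1579.78), intensity = c(10, 20)), f,
            row.names = FALSE)
  rt <- read_peaklist(f)
  expect_equal(rt$mz, c(1171.58, 1579.78))
  f2 <- tempfile(fileext = ".tsv")
  writeLines("foo\tbar\n1\t2", f2)
  expect_error(read_peaklist(f2), "mz")
  unlink(c(f, f2))
})

test_that("annotation assigns the dominant candidate, flags contaminants and drops the rest", {
  pk <- peaklist(c(1171.6, 50), c(100, 5))
  ann <- annotate_peaklist(pk)
  expect_equal(nrow(ann), 1L)
  expect_equal(attr(ann, "n_dropped"), 1L)
  expect_equal(ann$glycan_class, "paucimannose")
  expect_equal(ann$composition, "Hex3HexNAc2")

  # a Hex7 polymer ladder peak is flagged, not annotated as a glycan
  hex7 <- 7 * residue_masses()$residues[["hex"]] +
    residue_masses()$end_group + residue_masses()$sodium
  ann2 <- annotate_peaklist(peaklist(c(1171.6, hex7), c(50, 80)))
  expect_true(ann2$contaminant[ann2$composition == "Hex7"])
  expect_false(ann2$contaminant[ann2$composition == "Hex3HexNAc2"])

  expect_equal(nrow(annotate_peaklist(peaklist(numeric(), numeric()))), 0L)
})

test_that("annotation is deterministic under peak order shuffling", {
  set.seed(45)
  comps <- replicate(40, random_plausible_composition(), simplify = FALSE)
  mz <- vapply(comps, sodiated_mz, numeric(1)) + rnorm(40, 0, 0.05)
  inten <- runif(40, 1, 100)
  a1 <- annotate_peaklist(peaklist(mz, inten))
  sh <- sample(40)
  a2 <- annotate_peaklist(peaklist(mz[sh], inten[sh]))
  expect_equal(as.data.frame(a1), as.data.frame(a2))
})
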