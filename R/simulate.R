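# Synthetic cohort generation ------------------------------------------------
#
# The generator emulates what the analysis consumes: centroided MS1 peak
# lists of permethylated N-glycans, MS2 diagnostic-ion spectra, and a sample
# metadata table with phenotype labels and cytokine concentrations coupled to
# the fucosylation features. Panel composition counts are assigned by
# largest-remainder proportional allocation over the composition pool rather
# than by per-molecule multinomial draws: a real spectrum integrates the
# abundances of ~1e9 molecules, so the sample-to-sample variability that
# matters is the biological one (Dirichlet perturbation of the fucosylation
# distribution, log-normal intensity dispersion), not the discretisation of
# the panel to a few hundred entries.

#' Phenotype profile for the synthetic-cohort generator
#'
#' Bundles the generating parameters for one phenotype: the glycan-class
#' mixture, the mean fucosylation-degree distribution per LacNAc stratum, the
#' per-glycan sialylation probability, sample-to-sample variability, noise
#' scales and the glycotope mixture emitted in MS2 spectra. The shipped
#' presets ([profile_cst_i()], [profile_cst_iv()], [profile_nonpregnant()])
#' follow the qualitative orderings observed between phenotypes in
#' cervicovaginal-fluid N-glycomes: a diverse-anaerobe (CST IV-like)
#' community shifts mass towards non-/mono-fucosylated, weakly sialylated,
#' antenna-truncated glycans; a non-pregnant profile is high-mannose-dominant
#' with heavy poly-fucosylation.
#'
#' @param name Profile name.
#' @param pregnancy,cst,outcome Metadata labels attached to samples drawn
#'   from this profile.
#' @param class_weights Named probability vector over `paucimannose`,
#'   `high_mannose`, `hybrid`, `complex`.
#' @param lacnac_weights Named probability vector over LacNAc-unit counts
#'   `"2"`, `"3"`, `"4"` for complex glycans.
#' @param fuc_probs List with elements `"2"` and `"3"`: mean probability
#'   vectors over fucosylation degrees 0-4 for the 2- and 3-LacNAc strata
#'   (4-LacNAc glycans reuse the `"3"` vector).
#' @param sial_prob Per-glycan probability that a complex/hybrid glycan is
#'   sialylated.
#' @param gal_trunc_prob Probability that a complex glycan misses one antenna
#'   galactose (truncated antenna terminated by GlcNAc).
#' @param dirichlet_conc Dirichlet concentration controlling sample-to-sample
#'   variability of the fucosylation vectors (`Inf` disables it); the default
#'   25 gives a between-donor standard deviation of roughly 0.09 on a 0.3
#'   proportion, matching the wide spread seen between donors.
#' @param intensity_sd Log-scale (natural log) dispersion of glycan
#'   abundances beyond the composition-driven mixture, applied per glycan.
#' @param measure_sd Log-scale multiplicative measurement noise applied to
#'   peak intensities when rendering a spectrum.
#' @param mz_jitter_sd Gaussian m/z jitter in Da applied to rendered peaks.
#' @param contaminant_rate Probability that each polyhexose ladder position
#'   (Hex5-Hex12) is injected into the rendered peak list.
#' @param glycotope_weights Named probability vector over the nine glycotopes
#'   of [default_glycotope_table()] governing simulated MS2 intensities.
#' @return An object of class `phenotype_profile`.
#' @export
phenotype_profile <- function(name = "CST-I-like",
                              pregnancy = "pregnant",
                              cst = "I-A",
                              outcome = "term",
                              class_weights = c(paucimannose = 0.25,
                                                high_mannose = 0.25,
                                                hybrid = 0.05,
                                                complex = 0.45),
                              lacnac_weights = c(`2` = 0.55, `3` = 0.35,
                                                 `4` = 0.10),
                              fuc_probs = list(
                                `2` = c(0.30, 0.30, 0.20, 0.15, 0.05),
                                `3` = c(0.28, 0.25, 0.20, 0.15, 0.12)),
                              sial_prob = 0.6,
                              gal_trunc_prob = 0.15,
                              dirichlet_conc = 25,
                              intensity_sd = 0.3,
                              measure_sd = 0.1,
                              mz_jitter_sd = 0.05,
                              contaminant_rate = 0.25,
                              glycotope_weights = c(
                                terminal_HexNAc = 0.10, LacdiNAc = 0.08,
                                internal_Lewis = 0.10, Lewis = 0.20,
                                LacdiNAc_Fuc = 0.05, Lewis_Fuc2 = 0.12,
                                sialyl_Lewis = 0.15, poly_Lewis_Fuc2 = 0.12,
                                poly_Lewis_Fuc3 = 0.08)) {
  p <- list(name = name, pregnancy = pregnancy, cst = cst, outcome = outcome,
            class_weights = class_weights, lacnac_weights = lacnac_weights,
            fuc_probs = fuc_probs, sial_prob = sial_prob,
            gal_trunc_prob = gal_trunc_prob, dirichlet_conc = dirichlet_conc,
            intensity_sd = intensity_sd, measure_sd = measure_sd,
            mz_jitter_sd = mz_jitter_sd,
            contaminant_rate = contaminant_rate,
            glycotope_weights = glycotope_weights)
  .validate_profile(p)
  structure(p, class = "phenotype_profile")
}

.validate_profile <- function(p) {
  bad <- character()
  chk_prob <- function(v, what, len = NULL) {
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0) ||
        abs(sum(v) - 1) > 1e-8 || (!is.null(len) && length(v) != len))
      bad <<- c(bad, what)
  }
  chk_prob(p$class_weights, "class_weights", 4)
  chk_prob(p$lacnac_weights, "lacnac_weights", 3)
  chk_prob(p$fuc_probs[["2"]], "fuc_probs$`2`", 5)
  chk_prob(p$fuc_probs[["3"]], "fuc_probs$`3`", 5)
  chk_prob(p$glycotope_weights, "glycotope_weights", 9)
  for (f in c("sial_prob", "gal_trunc_prob", "contaminant_rate"))
    if (!is.numeric(p[[f]]) || p[[f]] < 0 || p[[f]] > 1) bad <- c(bad, f)
  for (f in c("intensity_sd", "measure_sd", "mz_jitter_sd"))
    if (!is.numeric(p[[f]]) || p[[f]] < 0) bad <- c(bad, f)
  if (!(is.numeric(p$dirichlet_conc) &&
        (is.infinite(p$dirichlet_conc) || p$dirichlet_conc > 0)))
    bad <- c(bad, "dirichlet_conc")
  if (length(bad))
    stop("invalid phenotype profile field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  invisible(p)
}

#' @rdname phenotype_profile
#' @export
profile_cst_i <- function() phenotype_profile()

#' @rdname phenotype_profile
#' @export
profile_cst_iv <- function() {
  phenotype_profile(
    name = "CST-IV-like", pregnancy = "pregnant", cst = "IV-B",
    outcome = "preterm",
    class_weights = c(paucimannose = 0.30, high_mannose = 0.20,
                      hybrid = 0.05, complex = 0.45),
    fuc_probs = list(`2` = c(0.45, 0.35, 0.10, 0.07, 0.03),
                     `3` = c(0.42, 0.33, 0.12, 0.08, 0.05)),
    sial_prob = 0.2, gal_trunc_prob = 0.35,
    glycotope_weights = c(terminal_HexNAc = 0.30, LacdiNAc = 0.10,
                          internal_Lewis = 0.08, Lewis = 0.20,
                          LacdiNAc_Fuc = 0.05, Lewis_Fuc2 = 0.07,
                          sialyl_Lewis = 0.04, poly_Lewis_Fuc2 = 0.10,
                          poly_Lewis_Fuc3 = 0.06))
}

#' @rdname phenotype_profile
#' @export
profile_nonpregnant <- function() {
  phenotype_profile(
    name = "non-pregnant", pregnancy = "non-pregnant", cst = NA_character_,
    outcome = "n/a",
    class_weights = c(paucimannose = 0.15, high_mannose = 0.45,
                      hybrid = 0.05, complex = 0.35),
    fuc_probs = list(`2` = c(0.13, 0.15, 0.25, 0.35, 0.12),
                     `3` = c(0.10, 0.12, 0.23, 0.25, 0.30)),
    sial_prob = 0.4,
    glycotope_weights = c(terminal_HexNAc = 0.08, LacdiNAc = 0.06,
                          internal_Lewis = 0.12, Lewis = 0.18,
                          LacdiNAc_Fuc = 0.05, Lewis_Fuc2 = 0.18,
                          sialyl_Lewis = 0.08, poly_Lewis_Fuc2 = 0.15,
                          poly_Lewis_Fuc3 = 0.10))
}

# Largest-remainder allocation of n units over probabilities p (sum 1).
# Deterministic: remainder ties broken by index order.
.alloc_largest_remainder <- function(n, p) {
  q <- n * p
  k <- floor(q)
  rem <- n - sum(k)
  if (rem > 0) {
    o <- order(q - k, decreasing = TRUE)
    k[o[seq_len(rem)]] <- k[o[seq_len(rem)]] + 1
  }
  as.integer(k)
}

# Dirichlet perturbation of a probability vector (Inf concentration -> exact)
.dirichlet_draw <- function(base, conc) {
  if (is.infinite(conc)) return(base)
  g <- stats::rgamma(length(base), shape = conc * base)
  if (sum(g) <= 0) return(base)
  g / sum(g)
}

# Skeleton of the cell pool: every distinct composition the profile can
# emit, with the probability factor that does not depend on the per-sample
# fucosylation vectors (`p_base`) and, for complex cells, the stratum whose
# fucosylation vector multiplies in (`stratum` 2 or 3; 0 elsewhere). Cached
# per profile parameterisation since it is rebuilt for every sample.
.pool_skeleton <- function(profile) {
  key <- paste0("pool|", paste(c(profile$class_weights,
                                 profile$lacnac_weights, profile$sial_prob,
                                 profile$gal_trunc_prob), collapse = ","))
  sk <- .glyco_cache[[key]]
  if (!is.null(sk)) return(sk)
  cw <- profile$class_weights
  cells <- list()

  # paucimannose: Man2-4GlcNAc2Fuc0-1
  g <- expand.grid(hex = 2:4, dhex = 0:1, KEEP.OUT.ATTRS = FALSE)
  cells$pauci <- data.frame(hex = g$hex, hexnac = 2L, dhex = g$dhex, neuac = 0L,
                            p_base = cw[["paucimannose"]] * (1 / 3) *
                              ifelse(g$dhex == 0, 0.7, 0.3),
                            stratum = 0L)

  # high mannose: Man5-9GlcNAc2, tapering towards Man9
  hm_w <- c(0.30, 0.25, 0.20, 0.15, 0.10)
  cells$hm <- data.frame(hex = 5:9, hexnac = 2L, dhex = 0L, neuac = 0L,
                         p_base = cw[["high_mannose"]] * hm_w, stratum = 0L)

  # hybrid: one antenna plus uncut mannose arm
  g <- expand.grid(hex = 5:7, dhex = 0:1, neuac = 0:1, KEEP.OUT.ATTRS = FALSE)
  cells$hyb <- data.frame(
    hex = g$hex, hexnac = 3L, dhex = g$dhex, neuac = g$neuac,
    p_base = cw[["hybrid"]] * (1 / 3) * ifelse(g$dhex == 0, 0.7, 0.3) *
      ifelse(g$neuac == 0, 1 - profile$sial_prob, profile$sial_prob),
    stratum = 0L)

  # complex: lacnac strata 2-4, optional antenna truncation, fucosylation
  # from the per-stratum vector, sialylation capped by available galactoses
  cx <- list()
  for (l in 2:4) {
    lw <- profile$lacnac_weights[[as.character(l)]]
    for (trunc in 0:1) {
      gal <- l - trunc
      tw <- if (trunc == 0) 1 - profile$gal_trunc_prob else profile$gal_trunc_prob
      kmax <- min(gal, l)
      sial_w <- 0.6 ^ (seq_len(kmax) - 1)
      sial_w <- profile$sial_prob * sial_w / sum(sial_w)
      neu <- 0:kmax
      neu_w <- c(1 - profile$sial_prob, sial_w)
      g <- expand.grid(fuc = 0:4, neuac = neu, KEEP.OUT.ATTRS = FALSE)
      cx[[length(cx) + 1L]] <- data.frame(
        hex = 3L + gal, hexnac = 2L + l, dhex = g$fuc, neuac = g$neuac,
        p_base = cw[["complex"]] * lw * tw * neu_w[match(g$neuac, neu)],
        stratum = if (l == 2L) 2L else 3L)
    }
  }
  sk <- rbind(cells$pauci, cells$hm, cells$hyb, do.call(rbind, cx))
  stopifnot(all(biosynthetically_plausible(sk$hex, sk$hexnac,
                                           sk$dhex, sk$neuac)))
  rownames(sk) <- NULL
  .glyco_cache[[key]] <- sk
  sk
}

.cell_pool <- function(profile, fuc2, fuc3) {
  sk <- .pool_skeleton(profile)
  fmul <- rep(1, nrow(sk))
  i2 <- sk$stratum == 2L
  i3 <- sk$stratum == 3L
  fmul[i2] <- fuc2[sk$dhex[i2] + 1L]
  fmul[i3] <- fuc3[sk$dhex[i3] + 1L]
  pool <- sk[, c("hex", "hexnac", "dhex", "neuac")]
  pool$p <- sk$p_base * fmul
  pool <- pool[pool$p > 0, , drop = FALSE]
  pool$p <- pool$p / sum(pool$p)
  pool
}

#' Draw a ground-truth glycan panel for one sample
#'
#' Realises the per-sample fucosylation vectors (Dirichlet perturbation of
#' the profile means), allocates `n_glycans` over the composition pool by
#' largest-remainder proportional allocation, and assigns each retained
#' composition a noisy abundance (log-normal dispersion shrinking with the
#' allocated count, as the sum of per-molecule noise would). Every emitted
#' composition is biosynthetically plausible.
#'
#' @param profile A [phenotype_profile()].
#' @param n_glycans Panel size (total allocated glycan count).
#' @return A data frame with columns `hex`, `hexnac`, `dhex`, `neuac`,
#'   `count`, `intensity`, `glycan_class`, `lacnac_units`; the realised
#'   generating fucosylation vectors are attached as attribute
#'   `fuc_vectors` (list with elements `"2"` and `"3"`).
#' @export
sample_glycan_panel <- function(profile, n_glycans = 500) {
  stopifnot(inherits(profile, "phenotype_profile"), n_glycans >= 1)
  fuc2 <- .dirichlet_draw(profile$fuc_probs[["2"]], profile$dirichlet_conc)
  fuc3 <- .dirichlet_draw(profile$fuc_probs[["3"]], profile$dirichlet_conc)
  pool <- .cell_pool(profile, fuc2, fuc3)
  cnt <- .alloc_largest_remainder(n_glycans, pool$p)
  keep <- cnt > 0L
  panel <- pool[keep, c("hex", "hexnac", "dhex", "neuac"), drop = FALSE]
  panel$count <- cnt[keep]
  noise <- stats::rnorm(nrow(panel), 0,
                        profile$intensity_sd / sqrt(panel$count))
  panel$intensity <- panel$count * exp(noise)
  panel$glycan_class <- .classify_vec(panel$hex, panel$hexnac)
  panel$lacnac_units <- pmax(0L, panel$hexnac - 2L)
  rownames(panel) <- NULL
  structure(panel, fuc_vectors = list(`2` = fuc2, `3` = fuc3))
}

# A panel viewed as annotations (ground truth, no measurement step), so the
# quantitation functions can compute true per-sample feature values.
.panel_as_annotation <- function(panel) {
  structure(data.frame(
    mz = sodiated_mz_counts(panel$hex, panel$hexnac, panel$dhex, panel$neuac),
    intensity = panel$intensity,
    hex = panel$hex, hexnac = panel$hexnac, dhex = panel$dhex,
    neuac = panel$neuac,
    composition = NA_character_,
    glycan_class = panel$glycan_class,
    lacnac_units = panel$lacnac_units,
    fuc = panel$dhex, neuac_count = panel$neuac,
    gal_count = ifelse(panel$glycan_class %in% c("hybrid", "complex"),
                       pmax(0L, panel$hex - 3L), 0L),
    mass_error = 0, contaminant = FALSE, stringsAsFactors = FALSE),
    class = c("glycan_annotation", "data.frame"))
}

# vectorised sodiated m/z over count vectors (internal)
sodiated_mz_counts <- function(hex, hexnac, dhex, neuac) {
  .residue_sum(hex, hexnac, dhex, neuac) +
    .GLYCO_MASS$end_group + .GLYCO_MASS$sodium
}

#' Render a panel into a centroided MS1 peak list
#'
#' Theoretical sodiated m/z values receive Gaussian jitter
#' (`profile$mz_jitter_sd`), intensities receive multiplicative log-normal
#' measurement noise (`profile$measure_sd`), and polyhexose contaminant
#' ladder peaks (Hex5-Hex12) are injected independently with probability
#' `profile$contaminant_rate` at an intensity comparable to the panel median.
#'
#' @param panel A [sample_glycan_panel()] result.
#' @param profile The generating [phenotype_profile()].
#' @return A [peaklist()].
#' @export
render_peaklist <- function(panel, profile) {
  stopifnot(inherits(profile, "phenotype_profile"))
  mz <- sodiated_mz_counts(panel$hex, panel$hexnac, panel$dhex, panel$neuac) +
    stats::rnorm(nrow(panel), 0, profile$mz_jitter_sd)
  inten <- panel$intensity *
    exp(stats::rnorm(nrow(panel), 0, profile$measure_sd))
  ladder <- 5:12
  inject <- stats::runif(length(ladder)) < profile$contaminant_rate
  if (any(inject)) {
    cm <- .hexose_ladder_mz(ladder[inject])
    ci <- stats::median(inten) * exp(stats::rnorm(sum(inject), 0, 0.5))
    mz <- c(mz, cm)
    inten <- c(inten, ci)
  }
  peaklist(mz, inten, label = profile$name)
}

#' Render simulated MS2 diagnostic-ion spectra
#'
#' Each spectrum contains the nine diagnostic glycotope oxonium ions with
#' 1 ppm m/z jitter and log-normal intensity noise around the profile's
#' glycotope mixture.
#'
#' @param profile A [phenotype_profile()].
#' @param n_spectra Number of MS2 spectra to emit.
#' @return A data frame with columns `spectrum`, `mz`, `intensity`.
#' @export
render_ms2 <- function(profile, n_spectra = 3) {
  stopifnot(inherits(profile, "phenotype_profile"), n_spectra >= 1)
  tab <- default_glycotope_table()
  w <- profile$glycotope_weights[tab$name]
  rows <- lapply(seq_len(n_spectra), function(s) {
    data.frame(spectrum = s,
               mz = tab$mz * (1 + stats::rnorm(nrow(tab), 0, 1e-6)),
               intensity = 1000 * w * exp(stats::rnorm(nrow(tab), 0, 0.2)))
  })
  do.call(rbind, rows)
}

#' Cohort configuration for the synthetic generator
#'
#' @param profiles Named list of [phenotype_profile()]s.
#' @param n_samples Named integer vector of sample counts per profile (names
#'   must match `profiles`).
#' @param n_glycans Panel size per sample.
#' @param cytokines Data frame defining simulated cytokines with columns
#'   `name`, `alpha` (intercept, pg/mL), `beta` (slope on the true
#'   non-fucosylated proportion of the 2-LacNAc stratum, pg/mL per unit
#'   proportion) and either `rho` (prescribed Pearson correlation with that
#'   feature; the Gaussian noise scale is derived from the realised feature
#'   spread) or `sigma` (explicit noise sd in pg/mL; overrides `rho` when not
#'   `NA`). Concentrations are floored at 0. The default couples IL-1 beta
#'   and IL-18 positively to the non-fucosylated proportion.
#' @param seed Integer seed; all randomness in [generate_cohort()] derives
#'   from it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(profiles = list(cst_i = profile_cst_i(),
                                          cst_iv = profile_cst_iv()),
                          n_samples = c(cst_i = 5L, cst_iv = 5L),
                          n_glycans = 500,
                          cytokines = data.frame(
                            name = c("IL1B", "IL18"),
                            alpha = c(50, 200),
                            beta = c(3000, 8000),
                            rho = c(0.6, 0.5),
                            sigma = NA_real_,
                            stringsAsFactors = FALSE),
                          seed = 1L) {
  bad <- character()
  if (!is.list(profiles) || length(profiles) == 0L ||
      is.null(names(profiles)) ||
      !all(vapply(profiles, inherits, logical(1), "phenotype_profile")))
    bad <- c(bad, "profiles")
  if (!is.numeric(n_samples) || is.null(names(n_samples)) ||
      !setequal(names(n_samples), names(profiles)) || any(n_samples < 0))
    bad <- c(bad, "n_samples")
  if (!is.numeric(n_glycans) || length(n_glycans) != 1L || n_glycans < 1)
    bad <- c(bad, "n_glycans")
  if (!is.data.frame(cytokines) ||
      !all(c("name", "alpha", "beta") %in% names(cytokines)))
    bad <- c(bad, "cytokines")
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    bad <- c(bad, "seed")
  if (length(bad))
    stop("invalid cohort config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!"rho" %in% names(cytokines)) cytokines$rho <- NA_real_
  if (!"sigma" %in% names(cytokines)) cytokines$sigma <- NA_real_
  structure(list(profiles = profiles, n_samples = n_samples,
                 n_glycans = n_glycans, cytokines = cytokines,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Deterministic per-sample substream seed: depends only on the cohort seed
# and the sample index, so changing the sample count never reshuffles the
# panels of earlier samples.
.sample_seed <- function(seed, i) {
  s <- (abs(as.numeric(seed)) %% 1e6) * 1000003 + i * 7919
  as.integer(s %% 2147483647 + 1)
}

#' Generate a synthetic cohort
#'
#' Draws one glycan panel, MS1 peak list and MS2 collection per sample, using
#' a deterministic per-sample random substream, and builds the metadata table
#' with cytokine concentrations coupled to the true non-fucosylated
#' proportion of the 2-LacNAc stratum:
#' `concentration = alpha + beta * feature + N(0, sigma)`, floored at 0. The
#' ground-truth manifest records the generating configuration, each sample's
#' realised fucosylation vectors and its true (noise-free-measurement)
#' feature values.
#'
#' @param config A [cohort_config()].
#' @return A list of class `glycan_cohort` with elements `peaks` (named list
#'   of peak lists), `ms2` (named list of MS2 data frames), `metadata` (data
#'   frame) and `truth` (list with `config` and per-sample data frame
#'   `samples`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  ids <- character(); phen <- character()
  for (nm in names(config$profiles))
    phen <- c(phen, rep(nm, config$n_samples[[nm]]))
  n <- length(phen)
  if (n == 0L) stop("cohort has zero samples", call. = FALSE)
  ids <- sprintf("S%02d", seq_len(n))

  peaks <- stats::setNames(vector("list", n), ids)
  ms2 <- stats::setNames(vector("list", n), ids)
  truth_rows <- vector("list", n)
  for (i in seq_len(n)) {
    prof <- config$profiles[[phen[i]]]
    set.seed(.sample_seed(config$seed, i))
    panel <- sample_glycan_panel(prof, config$n_glycans)
    peaks[[i]] <- render_peaklist(panel, prof)
    ms2[[i]] <- render_ms2(prof)
    tf <- glycan_features(.panel_as_annotation(panel), sample_id = ids[i])
    fv <- attr(panel, "fuc_vectors")
    gen <- as.data.frame(as.list(stats::setNames(
      c(fv[["2"]], fv[["3"]]),
      c(paste0("gen_", .FUC_BINS, "_lacnac2"),
        paste0("gen_", .FUC_BINS, "_lacnac3")))))
    names(tf)[-1] <- paste0("true_", names(tf)[-1])
    truth_rows[[i]] <- cbind(tf, gen)
  }
  truth <- do.call(rbind, truth_rows)

  meta <- data.frame(
    sample_id = ids,
    phenotype = phen,
    pregnancy = vapply(phen, function(p) config$profiles[[p]]$pregnancy, ""),
    cst = vapply(phen, function(p) config$profiles[[p]]$cst, ""),
    outcome = vapply(phen, function(p) config$profiles[[p]]$outcome, ""),
    stringsAsFactors = FALSE, row.names = NULL)

  x <- truth$true_fuc0_lacnac2
  for (k in seq_len(nrow(config$cytokines))) {
    ck <- config$cytokines[k, ]
    sigma <- ck$sigma
    if (is.na(sigma)) {
      if (is.na(ck$rho) || ck$rho <= 0 || ck$rho >= 1 || ck$beta == 0)
        stop("cytokine \"", ck$name,
             "\": supply sigma, or rho in (0,1) with beta != 0",
             call. = FALSE)
      sigma <- abs(ck$beta) * stats::sd(x) * sqrt(1 / ck$rho^2 - 1)
      if (!is.finite(sigma)) sigma <- 0
    }
    set.seed(.sample_seed(config$seed, 1000000 + k))
    meta[[ck$name]] <- pmax(0, ck$alpha + ck$beta * x +
                              stats::rnorm(n, 0, sigma))
  }

  structure(list(peaks = peaks, ms2 = ms2, metadata = meta,
                 truth = list(config = config, samples = truth)),
            class = "glycan_cohort")
}

#' @export
print.glycan_cohort <- function(x, ...) {
  cat(sprintf("<glycan cohort> %d sample(s): %s\n",
              nrow(x$metadata),
              paste(sprintf("%s (n=%d)", names(x$truth$config$n_samples),
                            x$truth$config$n_samples), collapse = ", ")))
  invisible(x)
}
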