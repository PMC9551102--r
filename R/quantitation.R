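# Per-sample glycan quantitation ---------------------------------------------
#
# All metrics are ratios of summed intensities, so they are invariant to the
# overall intensity scale. Quantitative analysis is restricted by default to
# complex glycans with 2 or 3 LacNAc units, the strata least affected by
# overlapped isotopic clusters in MALDI profiling; other strata can be
# computed by passing the corresponding `lacnac` value.

#' Base-peak normalisation of annotated intensities
#'
#' Expresses each annotated glycan intensity relative to the most abundant
#' non-contaminant component, designated 100%. Contaminant peaks are excluded
#' from the maximum and receive `NA` relative intensity.
#'
#' @param annotations An [annotate_peaklist()] result.
#' @return The annotations with an added `rel_intensity` column (percent).
#' @export
normalize_to_base_peak <- function(annotations) {
  ann <- .check_annotations(annotations)
  keep <- !ann$contaminant
  if (!any(keep))
    stop("all peaks are flagged as contaminants; no base peak available",
         call. = FALSE)
  base <- max(ann$intensity[keep])
  if (base <= 0)
    stop("base peak intensity must be positive", call. = FALSE)
  ann$rel_intensity <- ifelse(keep, 100 * ann$intensity / base, NA_real_)
  ann
}

.check_annotations <- function(annotations) {
  need <- c("intensity", "glycan_class", "lacnac_units", "fuc",
            "neuac_count", "contaminant")
  if (!is.data.frame(annotations) || !all(need %in% names(annotations)))
    stop("expected a glycan annotation data frame (see annotate_peaklist)",
         call. = FALSE)
  annotations
}

# complex glycans of one LacNAc stratum, contaminants excluded
.lacnac_group <- function(ann, lacnac) {
  if (!lacnac %in% 2:10 || length(lacnac) != 1L)
    stop("lacnac must be a single LacNAc-unit count >= 2", call. = FALSE)
  ann[!ann$contaminant & ann$glycan_class %in% "complex" &
        ann$lacnac_units == lacnac, , drop = FALSE]
}

.FUC_BINS <- c("fuc0", "fuc1", "fuc2", "fuc3", "fuc4p")

.fuc_bin <- function(fuc) pmin(fuc, 4L) + 1L   # index into .FUC_BINS

#' Fucosylation-degree profile of a LacNAc stratum
#'
#' For complex glycans with the given number of LacNAc units, computes the
#' proportion of summed intensity carried by glycans with 0, 1, 2, 3 and 4+
#' fucoses (the 4+ bin absorbs higher degrees). Proportions sum to 1.
#'
#' @param annotations An [annotate_peaklist()] result.
#' @param lacnac LacNAc-unit stratum, typically 2 or 3.
#' @param strict If `TRUE` (default) an empty stratum is an error naming the
#'   stratum; if `FALSE` it yields a vector of `NA`s, the missing-value
#'   convention used when assembling cohort feature tables.
#' @return Named numeric vector `fuc0`, `fuc1`, `fuc2`, `fuc3`, `fuc4p`.
#' @export
fucosylation_profile <- function(annotations, lacnac, strict = TRUE) {
  ann <- .check_annotations(annotations)
  g <- .lacnac_group(ann, lacnac)
  tot <- sum(g$intensity)
  if (nrow(g) == 0L || tot <= 0) {
    if (isTRUE(strict))
      stop(sprintf("no complex glycans with %d LacNAc units", lacnac),
           call. = FALSE)
    return(stats::setNames(rep(NA_real_, 5L), .FUC_BINS))
  }
  sums <- vapply(seq_along(.FUC_BINS), function(b)
    sum(g$intensity[.fuc_bin(g$fuc) == b]), numeric(1))
  stats::setNames(sums / tot, .FUC_BINS)
}

#' Poly- and highly-fucosylated intensity fractions
#'
#' Poly-fucosylated glycans carry at least 2 fucoses; the poly proportion is
#' their summed intensity over the stratum total. Highly fucosylated glycans
#' carry at least 3 fucoses in the 2-LacNAc stratum and at least 4 in the
#' 3-LacNAc stratum; the highly ratio is their summed intensity over the
#' poly-fucosylated intensity, and is reported as `NA` (never 0) when no
#' poly-fucosylated glycan is present.
#'
#' @inheritParams fucosylation_profile
#' @return A list with elements `poly` and `highly`.
#' @export
poly_and_highly_fucosylated <- function(annotations, lacnac, strict = TRUE) {
  ann <- .check_annotations(annotations)
  g <- .lacnac_group(ann, lacnac)
  tot <- sum(g$intensity)
  if (nrow(g) == 0L || tot <= 0) {
    if (isTRUE(strict))
      stop(sprintf("no complex glycans with %d LacNAc units", lacnac),
           call. = FALSE)
    return(list(poly = NA_real_, highly = NA_real_))
  }
  h <- if (lacnac == 2L) 3L else 4L
  poly_int <- sum(g$intensity[g$fuc >= 2L])
  high_int <- sum(g$intensity[g$fuc >= h])
  list(poly = poly_int / tot,
       highly = if (poly_int > 0) high_int / poly_int else NA_real_)
}

#' Sialylation percentage of a LacNAc stratum
#'
#' Two definitions are used in fucosylation-stratified profiling:
#'
#' * `mode = "vs_polyfuc"`: 100 x intensity of sialylated (`neuac >= 1`)
#'   poly-fucosylated (`fuc >= 2`) glycans over the intensity of all
#'   poly-fucosylated glycans;
#' * `mode = "by_fuc_group"`: within each fucosylation-degree bin (0, 1, 2,
#'   3, 4+), 100 x intensity of sialylated glycans over the bin total.
#'
#' Empty denominators yield `NA`, never 0.
#'
#' @inheritParams fucosylation_profile
#' @param mode `"vs_polyfuc"` or `"by_fuc_group"`.
#' @return A scalar percentage (`vs_polyfuc`) or a named vector over the
#'   fucosylation bins (`by_fuc_group`).
#' @export
sialylation_pct <- function(annotations, lacnac,
                            mode = c("vs_polyfuc", "by_fuc_group"),
                            strict = TRUE) {
  mode <- match.arg(mode)
  ann <- .check_annotations(annotations)
  g <- .lacnac_group(ann, lacnac)
  if (nrow(g) == 0L || sum(g$intensity) <= 0) {
    if (isTRUE(strict))
      stop(sprintf("no complex glycans with %d LacNAc units", lacnac),
           call. = FALSE)
    return(if (mode == "vs_polyfuc") NA_real_
           else stats::setNames(rep(NA_real_, 5L), .FUC_BINS))
  }
  if (mode == "vs_polyfuc") {
    den <- sum(g$intensity[g$fuc >= 2L])
    if (den <= 0) return(NA_real_)
    return(100 * sum(g$intensity[g$fuc >= 2L & g$neuac_count >= 1L]) / den)
  }
  bins <- .fuc_bin(g$fuc)
  out <- vapply(seq_along(.FUC_BINS), function(b) {
    den <- sum(g$intensity[bins == b])
    if (den <= 0) return(NA_real_)
    100 * sum(g$intensity[bins == b & g$neuac_count >= 1L]) / den
  }, numeric(1))
  stats::setNames(out, .FUC_BINS)
}

#' Intensity-weighted glycan-class proportions
#'
#' @param annotations An [annotate_peaklist()] result with at least one
#'   non-contaminant annotation.
#' @return Named numeric vector over `paucimannose`, `high_mannose`,
#'   `hybrid`, `complex`, summing to 1.
#' @export
class_summary <- function(annotations) {
  ann <- .check_annotations(annotations)
  g <- ann[!ann$contaminant, , drop = FALSE]
  tot <- sum(g$intensity)
  if (nrow(g) == 0L || tot <= 0)
    stop("no non-contaminant annotations", call. = FALSE)
  classes <- c("paucimannose", "high_mannose", "hybrid", "complex")
  out <- vapply(classes, function(k)
    sum(g$intensity[g$glycan_class == k]) / tot, numeric(1))
  stats::setNames(out, classes)
}

#' Per-sample glycan feature vector
#'
#' Assembles the derived metrics for one sample into a one-row data frame:
#' fucosylation-degree proportions, poly/highly-fucosylated fractions and
#' sialylation percentages for the 2- and 3-LacNAc strata, glycan-class
#' proportions, and (when MS2 spectra are supplied) the glycotope index.
#' Empty strata propagate as `NA`, never as zeros.
#'
#' @param annotations An [annotate_peaklist()] result for one sample.
#' @param ms2 Optional MS2 peak collection for the sample (see
#'   [glycotope_index()]).
#' @param sample_id Sample identifier stored in the `sample_id` column.
#' @param lacnac_groups LacNAc strata to profile; default `c(2, 3)`.
#' @return A one-row data frame. Column naming is stable:
#'   `fuc<d>_lacnac<g>`, `polyfuc_lacnac<g>`, `highfuc_lacnac<g>`,
#'   `sial_polyfuc_lacnac<g>`, `sial_fuc<d>_lacnac<g>`, `prop_<class>`,
#'   `gt_<glycotope>`.
#' @export
glycan_features <- function(annotations, ms2 = NULL, sample_id = NA_character_,
                            lacnac_groups = c(2L, 3L)) {
  ann <- .check_annotations(annotations)
  out <- list(sample_id = sample_id)
  for (g in lacnac_groups) {
    fp <- fucosylation_profile(ann, g, strict = FALSE)
    names(fp) <- paste0(names(fp), "_lacnac", g)
    ph <- poly_and_highly_fucosylated(ann, g, strict = FALSE)
    sp <- sialylation_pct(ann, g, mode = "vs_polyfuc", strict = FALSE)
    sg <- sialylation_pct(ann, g, mode = "by_fuc_group", strict = FALSE)
    names(sg) <- paste0("sial_", names(sg), "_lacnac", g)
    out <- c(out, as.list(fp),
             stats::setNames(list(ph$poly, ph$highly, sp),
                             paste0(c("polyfuc_lacnac", "highfuc_lacnac",
                                      "sial_polyfuc_lacnac"), g)),
             as.list(sg))
  }
  cs <- tryCatch(class_summary(ann),
                 error = function(e) stats::setNames(
                   rep(NA_real_, 4L),
                   c("paucimannose", "high_mannose", "hybrid", "complex")))
  names(cs) <- paste0("prop_", names(cs))
  out <- c(out, as.list(cs))
  if (!is.null(ms2)) {
    gi <- suppressWarnings(glycotope_index(ms2))
    names(gi) <- paste0("gt_", names(gi))
    out <- c(out, as.list(gi))
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Cohort feature table from raw peak lists
#'
#' Annotates each sample's MS1 peak list and assembles the per-sample feature
#' vectors into one table, one row per sample — the machine-readable contract
#' consumed by [correlate_feature()] and [compare_groups()].
#'
#' @param peaklists Named list of peak lists (names become sample ids).
#' @param ms2 Optional named list of MS2 collections, matched by name.
#' @param tolerance MS1 annotation tolerance in Da.
#' @inheritParams decompose_mass
#' @return A data frame with one row per sample, keyed by `sample_id`.
#' @export
cohort_features <- function(peaklists, ms2 = NULL, tolerance = 0.5,
                            bounds = .default_bounds) {
  if (!is.list(peaklists) || is.null(names(peaklists)) ||
      any(!nzchar(names(peaklists))))
    stop("peaklists must be a named list of peak lists", call. = FALSE)
  rows <- lapply(names(peaklists), function(id) {
    ann <- annotate_peaklist(peaklists[[id]], tolerance = tolerance,
                             bounds = bounds)
    glycan_features(ann, ms2 = if (!is.null(ms2)) ms2[[id]] else NULL,
                    sample_id = id)
  })
  do.call(rbind, rows)
}
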