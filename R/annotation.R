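# Composition annotation of MS1 peak lists -----------------------------------

#' N-glycan biosynthetic plausibility of a composition
#'
#' Encodes the constraints that mammalian N-glycan biosynthesis places on a
#' monosaccharide composition, used to prune the mass-decomposition search:
#'
#' * the chitobiose core requires `hexnac >= 2` and `hex >= 2`;
#' * `hexnac == 2` glycans are the paucimannose / high-mannose family
#'   (Man2-9GlcNAc2): `hex <= 9`, no sialic acid, at most a single (core)
#'   fucose;
#' * `hexnac >= 3` (antennary) glycans keep the trimannosyl core: `hex >= 3`;
#' * each antenna (LacNAc unit, `hexnac - 2`) can carry at most one capping
#'   sialic acid: `neuac <= max(0, hexnac - 2)`;
#' * fucose is bounded by one core fucose plus up to two per antenna
#'   (Lewis-Y-type difucosylation): `dhex <= 1 + 2 * max(0, hexnac - 2)`.
#'
#' @param c A [composition()], composition string, or named vector (see
#'   [sodiated_mz()]). Alternatively supply the four counts as equal-length
#'   vectors via `hexnac`, `dhex`, `neuac` with `c` the `hex` counts, in which
#'   case the result is vectorised.
#' @param hexnac,dhex,neuac Optional count vectors for vectorised use.
#' @return Logical (vector): is the composition reachable by the canonical
#'   N-glycan biosynthetic pathway?
#' @examples
#' biosynthetically_plausible(composition(hex = 3, hexnac = 2, dhex = 1)) # TRUE
#' biosynthetically_plausible(composition(hex = 2, hexnac = 2, neuac = 1)) # FALSE
#' @export
biosynthetically_plausible <- function(c, hexnac = NULL, dhex = NULL,
                                       neuac = NULL) {
  if (is.null(hexnac)) {
    cc <- .as_comp(c)
    hex <- cc[["hex"]]; hexnac <- cc[["hexnac"]]
    dhex <- cc[["dhex"]]; neuac <- cc[["neuac"]]
  } else {
    hex <- c
  }
  antennae <- pmax(0L, hexnac - 2L)
  hexnac >= 2L & hex >= 2L &
    (hexnac != 2L | (hex <= 9L & neuac == 0L & dhex <= 1L)) &
    (hexnac < 3L | hex >= 3L) &
    neuac <= antennae &
    dhex <= 1L + 2L * antennae
}

#' Classify a plausible composition into an N-glycan class
#'
#' Assigns one of the four canonical N-glycan classes from the pooled
#' composition, together with the derived LacNAc and galactose counts:
#'
#' * `hexnac == 2`, `hex` 2–4: paucimannose;
#' * `hexnac == 2`, `hex` 5–9: high-mannose;
#' * `hexnac == 3`, `hex >= 5`: hybrid (one antenna plus uncut mannose arm);
#' * otherwise: complex.
#'
#' `lacnac_units = max(0, hexnac - 2)` assumes no bisecting GlcNAc, and
#' `gal_count = max(0, hex - 3)` for hybrid/complex glycans attributes three
#' hexoses to the trimannosyl core. Truncated antennae
#' (`gal_count < lacnac_units`) are permitted and keep their LacNAc count.
#'
#' @inheritParams sodiated_mz
#' @return A list with elements `glycan_class` (character), `lacnac_units`
#'   and `gal_count` (integers).
#' @examples
#' classify_glycan("Man5GlcNAc2")            # high_mannose
#' classify_glycan("Gal2Man3GlcNAc4NeuAc2")  # complex, 2 LacNAc units
#' @export
classify_glycan <- function(c) {
  cc <- .as_comp(c)
  if (!biosynthetically_plausible(composition(cc[["hex"]], cc[["hexnac"]],
                                              cc[["dhex"]], cc[["neuac"]])))
    stop("composition is not biosynthetically plausible: ",
         format.glycan_composition(structure(cc, class = "glycan_composition")),
         call. = FALSE)
  cls <- .classify_vec(cc[["hex"]], cc[["hexnac"]])
  list(glycan_class = cls,
       lacnac_units = max(0L, cc[["hexnac"]] - 2L),
       gal_count = if (cls %in% c("hybrid", "complex"))
         max(0L, cc[["hex"]] - 3L) else 0L)
}

.classify_vec <- function(hex, hexnac) {
  ifelse(hexnac == 2L & hex <= 4L, "paucimannose",
  ifelse(hexnac == 2L,             "high_mannose",
  ifelse(hexnac == 3L & hex >= 5L, "hybrid", "complex")))
}

# Enumeration table of all biosynthetically plausible compositions within
# bounds, with theoretical sodiated m/z, sorted by m/z. Cached per bounds.
.glyco_cache <- new.env(parent = emptyenv())

.default_bounds <- c(hex = 15L, hexnac = 12L, dhex = 10L, neuac = 4L)

.comp_table <- function(bounds = .default_bounds) {
  key <- paste(bounds, collapse = ",")
  tbl <- .glyco_cache[[key]]
  if (!is.null(tbl)) return(tbl)
  g <- expand.grid(hex = 0:bounds[["hex"]], hexnac = 0:bounds[["hexnac"]],
                   dhex = 0:bounds[["dhex"]], neuac = 0:bounds[["neuac"]],
                   KEEP.OUT.ATTRS = FALSE)
  ok <- biosynthetically_plausible(g$hex, g$hexnac, g$dhex, g$neuac)
  g <- g[ok, , drop = FALSE]
  g$mz <- .residue_sum(g$hex, g$hexnac, g$dhex, g$neuac) +
    .GLYCO_MASS$end_group + .GLYCO_MASS$sodium
  g$total <- g$hex + g$hexnac + g$dhex + g$neuac
  g <- g[order(g$mz), , drop = FALSE]
  rownames(g) <- NULL
  .glyco_cache[[key]] <- g
  g
}

#' Decompose an observed m/z into candidate glycan compositions
#'
#' Exhaustively enumerates monosaccharide compositions within `bounds` whose
#' theoretical sodiated permethylated m/z lies within `tolerance` of the
#' observed value and which are biosynthetically plausible (see
#' [biosynthetically_plausible()]). Candidates are ranked by absolute mass
#' error, ties broken by fewer total residues, then lexicographically on
#' (hex, hexnac, dhex, neuac), making the result fully deterministic.
#'
#' @param mz Observed m/z, Da (positive scalar).
#' @param tolerance Mass tolerance in Da; default 0.5 (MALDI-TOF reflector
#'   scale).
#' @param bounds Named integer vector of per-residue enumeration maxima; the
#'   defaults (`hex` 15, `hexnac` 12, `dhex` 10, `neuac` 4) cover glycans
#'   beyond m/z 6000.
#' @return A data frame with columns `hex`, `hexnac`, `dhex`, `neuac`,
#'   `mz_theoretical` and `mass_error` (observed minus theoretical), best
#'   candidate first; zero rows when nothing matches.
#' @examples
#' decompose_mass(1171.58)   # unique: Hex3HexNAc2
#' @export
decompose_mass <- function(mz, tolerance = 0.5, bounds = .default_bounds) {
  if (!is.numeric(mz) || length(mz) != 1L || !is.finite(mz) || mz <= 0)
    stop("mz must be a positive number", call. = FALSE)
  if (!is.numeric(tolerance) || length(tolerance) != 1L || tolerance <= 0)
    stop("tolerance must be > 0", call. = FALSE)
  bounds <- .check_bounds(bounds)
  tbl <- .comp_table(bounds)
  hit <- tbl[abs(tbl$mz - mz) <= tolerance, , drop = FALSE]
  err <- mz - hit$mz
  ord <- order(abs(err), hit$total, hit$hex, hit$hexnac, hit$dhex, hit$neuac)
  out <- hit[ord, c("hex", "hexnac", "dhex", "neuac", "mz"), drop = FALSE]
  names(out)[5] <- "mz_theoretical"
  out$mass_error <- mz - out$mz_theoretical
  rownames(out) <- NULL
  out
}

.check_bounds <- function(bounds) {
  need <- c("hex", "hexnac", "dhex", "neuac")
  if (!is.numeric(bounds) || !all(need %in% names(bounds)) ||
      any(bounds[need] < 1))
    stop("bounds must be a named positive vector with hex, hexnac, dhex, neuac",
         call. = FALSE)
  b <- as.integer(bounds[need]); names(b) <- need
  b
}

# m/z of a permethylated hexose polymer ladder member (Hex_n), the signature
# of the polyhexose contaminants that ride along in glycan preparations.
.hexose_ladder_mz <- function(n) {
  n * .GLYCO_MASS$residues[["hex"]] + .GLYCO_MASS$end_group + .GLYCO_MASS$sodium
}

.match_hexose_ladder <- function(mz, tolerance) {
  n <- round((mz - .GLYCO_MASS$end_group - .GLYCO_MASS$sodium) /
               .GLYCO_MASS$residues[["hex"]])
  n >= 1 & abs(mz - .hexose_ladder_mz(pmax(n, 1))) <= tolerance
}

#' Construct or validate an MS1 peak list
#'
#' @param mz,intensity Numeric vectors of equal length; `mz > 0`,
#'   `intensity >= 0`. Peaks are sorted by ascending m/z.
#' @param label Optional acquisition label, kept as an attribute.
#' @return A data frame with columns `mz` and `intensity`, class `peaklist`.
#' @export
peaklist <- function(mz, intensity, label = NULL) {
  if (length(mz) != length(intensity))
    stop("mz and intensity must have equal length", call. = FALSE)
  if (any(!is.finite(mz)) || any(mz <= 0))
    stop("mz values must be positive and finite", call. = FALSE)
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop("intensities must be non-negative and finite", call. = FALSE)
  o <- order(mz)
  structure(data.frame(mz = mz[o], intensity = intensity[o]),
            label = label, class = c("peaklist", "data.frame"))
}

#' Read a peak list from a delimited file
#'
#' Reads a TSV/CSV centroided peak list with a mandatory header containing
#' columns `mz` and `intensity` (extra columns are ignored).
#'
#' @param path File path; the delimiter is inferred from the extension
#'   (`.csv` comma, otherwise tab) unless `sep` is given.
#' @param sep Optional field separator override.
#' @return A [peaklist()].
#' @export
read_peaklist <- function(path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = TRUE)
  if (!all(c("mz", "intensity") %in% names(df)))
    stop("peak list file must have header columns 'mz' and 'intensity'",
         call. = FALSE)
  peaklist(df$mz, df$intensity, label = basename(path))
}

#' Annotate an MS1 peak list with glycan compositions
#'
#' Runs [decompose_mass()] on every peak and assigns the top-ranked candidate
#' (the dominant-assignment rule for overlapped clusters). Peaks that match no
#' plausible glycan but fall on the permethylated hexose-polymer ladder within
#' tolerance are flagged `contaminant = TRUE` (they are excluded from all
#' downstream totals); peaks matching neither are dropped and counted.
#'
#' @param peaks A [peaklist()] or a data frame with columns `mz`, `intensity`.
#' @inheritParams decompose_mass
#' @param verbose Emit a message with annotated/contaminant/dropped counts.
#' @return A data frame of class `glycan_annotation` with one row per retained
#'   peak: `mz`, `intensity`, `hex`, `hexnac`, `dhex`, `neuac`, `composition`
#'   (display string), `glycan_class`, `lacnac_units`, `fuc`, `neuac_count`,
#'   `gal_count`, `mass_error`, `contaminant`. The number of dropped peaks is
#'   attached as attribute `n_dropped`.
#' @examples
#' pk <- peaklist(c(1171.58, 1579.78), c(80, 100))
#' annotate_peaklist(pk)
#' @export
annotate_peaklist <- function(peaks, tolerance = 0.5, bounds = .default_bounds,
                              verbose = FALSE) {
  if (!is.data.frame(peaks) || !all(c("mz", "intensity") %in% names(peaks)))
    stop("peaks must be a data frame with columns mz and intensity",
         call. = FALSE)
  if (!is.numeric(tolerance) || length(tolerance) != 1L || tolerance <= 0)
    stop("tolerance must be > 0", call. = FALSE)
  bounds <- .check_bounds(bounds)
  pk <- peaks[order(peaks$mz), c("mz", "intensity"), drop = FALSE]
  n <- nrow(pk)
  empty <- data.frame(mz = numeric(), intensity = numeric(), hex = integer(),
                      hexnac = integer(), dhex = integer(), neuac = integer(),
                      composition = character(), glycan_class = character(),
                      lacnac_units = integer(), fuc = integer(),
                      neuac_count = integer(), gal_count = integer(),
                      mass_error = numeric(), contaminant = logical(),
                      stringsAsFactors = FALSE)
  if (n == 0L)
    return(structure(empty, n_dropped = 0L,
                     class = c("glycan_annotation", "data.frame")))

  tbl <- .comp_table(bounds)
  lo <- findInterval(pk$mz - tolerance, tbl$mz)
  # findInterval gives the last index <= x; shift lower bound when the
  # boundary value itself is inside the window
  lo <- lo - (lo >= 1L & abs(tbl$mz[pmax(lo, 1L)] - pk$mz) <= tolerance)
  hi <- findInterval(pk$mz + tolerance, tbl$mz)
  ncand <- pmax(0L, hi - lo)
  has <- ncand > 0L

  ann <- empty
  if (any(has)) {
    pk_idx <- rep(which(has), ncand[has])
    cand <- sequence(ncand[has], from = lo[has] + 1L)
    err <- pk$mz[pk_idx] - tbl$mz[cand]
    ord <- order(pk_idx, abs(err), tbl$total[cand], tbl$hex[cand],
                 tbl$hexnac[cand], tbl$dhex[cand], tbl$neuac[cand])
    best <- ord[!duplicated(pk_idx[ord])]
    bi <- cand[best]; pi <- pk_idx[best]
    cls <- .classify_vec(tbl$hex[bi], tbl$hexnac[bi])
    lac <- pmax(0L, tbl$hexnac[bi] - 2L)
    gal <- ifelse(cls %in% c("hybrid", "complex"),
                  pmax(0L, tbl$hex[bi] - 3L), 0L)
    ann <- data.frame(
      mz = pk$mz[pi], intensity = pk$intensity[pi],
      hex = tbl$hex[bi], hexnac = tbl$hexnac[bi],
      dhex = tbl$dhex[bi], neuac = tbl$neuac[bi],
      composition = paste0(
        ifelse(tbl$hex[bi] > 0, paste0("Hex", tbl$hex[bi]), ""),
        ifelse(tbl$hexnac[bi] > 0, paste0("HexNAc", tbl$hexnac[bi]), ""),
        ifelse(tbl$dhex[bi] > 0, paste0("dHex", tbl$dhex[bi]), ""),
        ifelse(tbl$neuac[bi] > 0, paste0("NeuAc", tbl$neuac[bi]), "")),
      glycan_class = cls, lacnac_units = lac, fuc = tbl$dhex[bi],
      neuac_count = tbl$neuac[bi], gal_count = as.integer(gal),
      mass_error = pk$mz[pi] - tbl$mz[bi], contaminant = FALSE,
      stringsAsFactors = FALSE)
  }

  # unmatched peaks: polyhexose ladder -> contaminant; otherwise dropped
  un <- which(!has)
  n_drop <- 0L
  if (length(un)) {
    ladder <- .match_hexose_ladder(pk$mz[un], tolerance)
    n_drop <- sum(!ladder)
    if (any(ladder)) {
      li <- un[ladder]
      nhex <- as.integer(round((pk$mz[li] - .GLYCO_MASS$end_group -
                                  .GLYCO_MASS$sodium) /
                                 .GLYCO_MASS$residues[["hex"]]))
      contam <- data.frame(
        mz = pk$mz[li], intensity = pk$intensity[li],
        hex = nhex, hexnac = 0L, dhex = 0L, neuac = 0L,
        composition = paste0("Hex", nhex),
        glycan_class = NA_character_, lacnac_units = 0L, fuc = 0L,
        neuac_count = 0L, gal_count = 0L,
        mass_error = pk$mz[li] - .hexose_ladder_mz(nhex),
        contaminant = TRUE, stringsAsFactors = FALSE)
      ann <- rbind(ann, contam)
    }
  }
  ann <- ann[order(ann$mz), , drop = FALSE]
  rownames(ann) <- NULL
  if (isTRUE(verbose))
    message(sprintf("annotated %d peak(s), %d contaminant(s), %d dropped",
                    sum(!ann$contaminant), sum(ann$contaminant), n_drop))
  structure(ann, n_dropped = n_drop,
            class = c("glycan_annotation", "data.frame"))
}

#' Write annotations to a CSV file
#'
#' @param annotations A [annotate_peaklist()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.csv(as.data.frame(annotations), path, row.names = FALSE)
  invisible(path)
}
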