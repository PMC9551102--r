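# Glycotope-centric MS2 analysis ---------------------------------------------
#
# Terminal glycan epitopes (glycotopes) such as Lewis, Sialyl Lewis and
# LacdiNAc produce characteristic B-type oxonium ions on CID fragmentation of
# permethylated glycans, because cleavage is preferred at HexNAc. Summing each
# diagnostic ion's intensity over all MS2 spectra of a run, and normalising
# the sums to their total, gives a relative-abundance index of the glycotopes
# carried by the sample's glycome.

#' Default table of diagnostic glycotope oxonium ions
#'
#' The nine diagnostic B-ion definitions used for glycotope profiling of
#' permethylated N-glycans, with fragment compositions, position (terminal or
#' internal) and theoretical m/z from [oxonium_mz()]. Their floor-truncated
#' labels are 260 (terminal HexNAc/GalNAc), 505 and 679 (LacdiNAc and its
#' fucosylated form), 624 (internal Lewis), 638 and 812 (terminal mono- and
#' di-fucosylated Lewis), 999 (Sialyl Lewis), 1261 and 1435 (poly-LacNAc
#' Lewis with 2 and 3 fucoses). The isomeric constituents under one label
#' (e.g. Lewis X vs Lewis A vs blood-group H under 638) require MS3 and are
#' reported as the composite glycotope.
#'
#' @return A data frame with columns `name`, `hex`, `hexnac`, `dhex`,
#'   `neuac`, `internal`, `mz` and `label`.
#' @export
default_glycotope_table <- function() {
  d <- data.frame(
    name = c("terminal_HexNAc", "LacdiNAc", "internal_Lewis", "Lewis",
             "LacdiNAc_Fuc", "Lewis_Fuc2", "sialyl_Lewis",
             "poly_Lewis_Fuc2", "poly_Lewis_Fuc3"),
    hex      = c(0L, 0L, 1L, 1L, 0L, 1L, 1L, 2L, 2L),
    hexnac   = c(1L, 2L, 1L, 1L, 2L, 1L, 1L, 2L, 2L),
    dhex     = c(0L, 0L, 1L, 1L, 1L, 2L, 1L, 2L, 3L),
    neuac    = c(0L, 0L, 0L, 0L, 0L, 0L, 1L, 0L, 0L),
    internal = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  d$mz <- vapply(seq_len(nrow(d)), function(i)
    oxonium_mz(composition(d$hex[i], d$hexnac[i], d$dhex[i], d$neuac[i]),
               internal = d$internal[i]), numeric(1))
  d$label <- mz_label(d$mz)
  d
}

#' Glycotope relative-abundance index from MS2 spectra
#'
#' For each glycotope definition, sums the intensities of all MS2 peaks lying
#' within `ppm_tolerance` of its theoretical m/z across every spectrum of the
#' collection, then divides each sum by the grand total over all definitions.
#' Undetected glycotopes score 0 and the index sums to 1; normalisation is
#' over all definitions, zeros included. A peak within tolerance of two
#' definitions (impossible with the default table at the default tolerance)
#' is assigned to the nearer theoretical m/z.
#'
#' @param ms2 MS2 peaks for one sample: a data frame with columns `mz` and
#'   `intensity` (an optional `spectrum` column identifies individual scans),
#'   or a list of such data frames.
#' @param table Glycotope definition table; default [default_glycotope_table()].
#' @param ppm_tolerance Matching window in parts per million; the default
#'   5 ppm reflects high-resolution Orbitrap mass accuracy.
#' @return Named numeric vector over the table's glycotope names, summing to
#'   1 when any diagnostic ion was detected; all `NA` with a warning when
#'   none was.
#' @examples
#' sp <- data.frame(mz = c(505.28, 638.34), intensity = c(10, 30))
#' glycotope_index(sp)
#' @export
glycotope_index <- function(ms2, table = default_glycotope_table(),
                            ppm_tolerance = 5) {
  if (!is.numeric(ppm_tolerance) || length(ppm_tolerance) != 1L ||
      ppm_tolerance <= 0)
    stop("ppm_tolerance must be > 0", call. = FALSE)
  if (is.data.frame(ms2)) ms2 <- list(ms2)
  if (!is.list(ms2) || length(ms2) == 0L)
    stop("ms2 must be a non-empty data frame or list of data frames",
         call. = FALSE)
  need <- c("name", "mz")
  if (!is.data.frame(table) || !all(need %in% names(table)))
    stop("table must contain columns name and mz", call. = FALSE)

  peaks <- do.call(rbind, lapply(ms2, function(s) {
    if (!is.data.frame(s) || !all(c("mz", "intensity") %in% names(s)))
      stop("each MS2 spectrum needs columns mz and intensity", call. = FALSE)
    s[, c("mz", "intensity"), drop = FALSE]
  }))

  sums <- stats::setNames(numeric(nrow(table)), table$name)
  if (nrow(peaks)) {
    # nearest definition per peak, kept when within the ppm window
    d <- abs(outer(peaks$mz, table$mz, "-"))
    nearest <- max.col(-d, ties.method = "first")
    ppm <- 1e6 * d[cbind(seq_len(nrow(peaks)), nearest)] / table$mz[nearest]
    ok <- ppm <= ppm_tolerance
    if (any(ok)) {
      agg <- tapply(peaks$intensity[ok], table$name[nearest[ok]], sum)
      sums[names(agg)] <- agg
    }
  }
  total <- sum(sums)
  if (total <= 0) {
    warning("no diagnostic glycotope ion detected in any spectrum")
    return(stats::setNames(rep(NA_real_, nrow(table)), table$name))
  }
  sums / total
}
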