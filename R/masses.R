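# Permethylated glycan mass calculus -----------------------------------------
#
# Monoisotopic masses of fully permethylated glycosyl residues, i.e. the
# residue as it sits inside a permethylated chain (every free hydroxyl and the
# amide NH methylated, minus the water lost on glycosidic bond formation):
#
#   Hex    C9H16O5   204.099774
#   HexNAc C11H19NO5 245.126323
#   dHex   C8H14O4   174.089209
#   NeuAc  C16H27NO8 361.173667
#
# An intact permethylated free-reducing glycan carries one extra methyl at the
# non-reducing terminus and a methylated reducing-end hydroxyl, which together
# amount to C2H6O (+46.041865 Da) over the residue sum. MALDI ionises these
# analytes as [M+Na]+ (Na+ = 22.989221 Da allowing for the electron).
# B-type oxonium fragments keep the residue sum plus a terminal methyl cation
# (CH3+, 15.022927 Da); a glycotope cleaved out of a chain interior has one
# fewer methylation site, i.e. -CH2 (14.015650 Da).
#
# These constants reproduce, after floor-truncation, every integer m/z label
# conventionally printed on permethylated N-glycan MALDI spectra (e.g. 1171
# for Man3GlcNAc2, 2396 for Man9GlcNAc2) and the standard diagnostic oxonium
# series (260, 505, 624, 638, 679, 812, 999, 1261, 1435).

.GLYCO_MASS <- list(
  residues = c(hex    = 204.09977361,
               hexnac = 245.12632271,
               dhex   = 174.08920893,
               neuac  = 361.17366683),
  end_group    = 46.04186481,   # C2H6O: reducing + non-reducing end methyls
  sodium       = 22.98922070,   # Na+ (electron subtracted)
  oxonium_ch3  = 15.02292652,   # CH3+ charge carrier of B ions
  internal_ch2 = 14.01565006    # methyl site lost at an internal position
)

#' Monoisotopic mass table for permethylated glycans
#'
#' Returns the residue and adjustment masses used throughout the package:
#' permethylated glycosyl residue masses for the four monosaccharide classes,
#' the end-group adjustment for an intact permethylated free-reducing glycan,
#' the sodium-adduct mass, the oxonium (B-ion) charge-carrier adjustment, and
#' the internal-position methyl correction. All values are monoisotopic, in Da.
#'
#' @return A list with elements `residues` (named numeric vector),
#'   `end_group`, `sodium`, `oxonium_ch3` and `internal_ch2`.
#' @examples
#' residue_masses()$residues["hex"]
#' @export
residue_masses <- function() .GLYCO_MASS

# Vectorised residue-mass sum; workhorse shared with the annotation module.
.residue_sum <- function(hex, hexnac, dhex, neuac) {
  r <- .GLYCO_MASS$residues
  hex * r[["hex"]] + hexnac * r[["hexnac"]] +
    dhex * r[["dhex"]] + neuac * r[["neuac"]]
}

#' Theoretical m/z of the sodiated permethylated molecular ion
#'
#' Computes the monoisotopic m/z of the singly charged `[M+Na]+` ion of a
#' fully permethylated, free-reducing glycan — the dominant species in MALDI
#' spectra of permethylated glycans. Printed spectrum labels correspond to the
#' floor-truncated value (see [mz_label()]).
#'
#' @param c A [composition()], a composition string, or a named numeric vector
#'   with any of `hex`, `hexnac`, `dhex`, `neuac`.
#' @return Monoisotopic m/z in Da (numeric scalar).
#' @examples
#' sodiated_mz("Man3GlcNAc2")        # 1171.58 -> printed label 1171
#' sodiated_mz(composition(hex = 12, hexnac = 11, dhex = 6))  # label 6259
#' @export
sodiated_mz <- function(c) {
  cc <- .as_comp(c)
  .residue_sum(cc[["hex"]], cc[["hexnac"]], cc[["dhex"]], cc[["neuac"]]) +
    .GLYCO_MASS$end_group + .GLYCO_MASS$sodium
}

#' Theoretical m/z of a B-type oxonium fragment ion
#'
#' Computes the monoisotopic m/z of the non-sodiated B-type oxonium ion formed
#' by glycosidic cleavage at a HexNAc of a permethylated glycan — the
#' diagnostic fragments used for glycotope profiling in MS2. A terminal
#' glycotope retains the non-reducing-end methyl; set `internal = TRUE` for a
#' glycotope excised from a chain interior, which has one fewer methylation
#' site (one CH2 less).
#'
#' @inheritParams sodiated_mz
#' @param internal Logical; apply the internal-position methyl correction.
#' @return Monoisotopic m/z in Da (numeric scalar).
#' @examples
#' oxonium_mz("HexNAc1")                       # 260.1 terminal HexNAc
#' oxonium_mz("Hex1HexNAc1Fuc1")               # 638.3 Lewis-type glycotope
#' oxonium_mz("Hex1HexNAc1Fuc1", internal = TRUE)  # 624.3 internal Lewis
#' @export
oxonium_mz <- function(c, internal = FALSE) {
  cc <- .as_comp(c)
  if (cc[["hexnac"]] < 1L)
    stop("oxonium (B-type) ions cleave at HexNAc; composition has hexnac = 0",
         call. = FALSE)
  .residue_sum(cc[["hex"]], cc[["hexnac"]], cc[["dhex"]], cc[["neuac"]]) +
    .GLYCO_MASS$oxonium_ch3 -
    (if (isTRUE(internal)) .GLYCO_MASS$internal_ch2 else 0)
}

#' Integer spectrum label of an m/z value
#'
#' Spectrum annotations conventionally print the integer part of the
#' monoisotopic m/z, i.e. the value truncated towards zero (1579.78 is
#' labelled 1579, not 1580).
#'
#' @param mz Numeric m/z value(s), Da.
#' @return Integer label(s).
#' @export
mz_label <- function(mz) as.integer(floor(mz))
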