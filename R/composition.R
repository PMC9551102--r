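# Monosaccharide compositions ------------------------------------------------
#
# Mass spectrometry cannot distinguish isobaric monosaccharides, so a
# composition pools residues into four mass classes: Hex (Gal + Man + Glc),
# HexNAc (GlcNAc + GalNAc), dHex (Fuc) and NeuAc.

#' Construct a glycan monosaccharide composition
#'
#' A composition holds integer counts of the four monosaccharide mass classes
#' of an N-glycan: hexose (`hex`, Gal and Man pooled), N-acetylhexosamine
#' (`hexnac`, GlcNAc and GalNAc pooled), deoxyhexose (`dhex`, fucose) and
#' N-acetylneuraminic acid (`neuac`). Identity below the mass class (e.g. Gal
#' vs Man, Lewis X vs Lewis A) is not mass-resolvable and is never stored here;
#' the Gal/Man split of annotated glycans is derived downstream from the
#' biosynthetic core (see [classify_glycan()]).
#'
#' @param hex,hexnac,dhex,neuac Non-negative integer residue counts. At least
#'   one count must be positive.
#' @return An object of class `glycan_composition`: a named integer vector
#'   with elements `hex`, `hexnac`, `dhex`, `neuac`.
#' @examples
#' composition(hex = 3, hexnac = 2)           # the N-glycan trimannosyl core
#' composition(hex = 5, hexnac = 4, neuac = 2) # disialyl biantennary
#' @seealso [parse_composition()], [sodiated_mz()], [oxonium_mz()]
#' @export
composition <- function(hex = 0, hexnac = 0, dhex = 0, neuac = 0) {
  counts <- c(hex = hex, hexnac = hexnac, dhex = dhex, neuac = neuac)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("composition counts must be non-negative integers", call. = FALSE)
  if (sum(counts) < 1)
    stop("composition must contain at least one residue", call. = FALSE)
  structure(as.integer(round(counts)),
            names = c("hex", "hexnac", "dhex", "neuac"),
            class = "glycan_composition")
}

#' @export
print.glycan_composition <- function(x, ...) {
  cat("<glycan composition> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.glycan_composition <- function(x, ...) {
  lab <- c(hex = "Hex", hexnac = "HexNAc", dhex = "dHex", neuac = "NeuAc")
  nz <- x > 0L
  paste0(lab[names(x)[nz]], unclass(x)[nz], collapse = "")
}

# Residue tokens of the two accepted grammars, longest names first so that
# e.g. "HexNAc" is never split into "Hex" + junk. Case sensitive.
.COMP_TOKENS <- c(
  GlcNAc = "hexnac", GalNAc = "hexnac", HexNAc = "hexnac",
  NeuAc  = "neuac",  dHex   = "dhex",
  Hex    = "hex",    Gal    = "hex",    Man    = "hex",  Glc = "hex",
  Fuc    = "dhex"
)

#' Parse a composition string
#'
#' Accepts both the generic mass-class grammar (`"Hex5HexNAc4Fuc1"`) and the
#' biosynthetic alias grammar used when reporting annotated spectra
#' (`"Gal2Man3GlcNAc4Fuc1"` or the underscored variant
#' `"Gal_2_Man_3_GlcNAc_4_Fuc_1_"`). Aliases are pooled into mass classes:
#' Gal/Man/Glc into `hex`, GlcNAc/GalNAc into `hexnac`, Fuc into `dhex`.
#' Residue names are case sensitive; a residue without an explicit count
#' counts once; residues absent from the string count zero.
#'
#' @param text A single composition string.
#' @return A [composition()] object.
#' @examples
#' parse_composition("Gal9Man3GlcNAc11Fuc6")
#' parse_composition("Hex3HexNAc2")
#' @export
parse_composition <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("expected a single non-empty composition string", call. = FALSE)
  counts <- c(hex = 0L, hexnac = 0L, dhex = 0L, neuac = 0L)
  rest <- text
  token_re <- paste0("^(", paste(names(.COMP_TOKENS), collapse = "|"),
                     ")_?([0-9]+)?_?")
  while (nzchar(rest)) {
    m <- regexpr(token_re, rest, perl = TRUE)
    if (m[1] == -1L) {
      bad <- regmatches(rest, regexpr("^[A-Za-z]+", rest))
      if (length(bad) == 0L) bad <- substr(rest, 1L, 8L)
      stop(sprintf("unknown residue \"%s\" in composition \"%s\"", bad, text),
           call. = FALSE)
    }
    tok <- regmatches(rest, m)
    parts <- regmatches(tok, regexec(token_re, tok, perl = TRUE))[[1]]
    cls <- .COMP_TOKENS[[parts[2]]]
    n <- if (nzchar(parts[3])) as.integer(parts[3]) else 1L
    counts[[cls]] <- counts[[cls]] + n
    rest <- substr(rest, attr(m, "match.length") + 1L, nchar(rest))
  }
  composition(hex = counts[["hex"]], hexnac = counts[["hexnac"]],
              dhex = counts[["dhex"]], neuac = counts[["neuac"]])
}

# Coerce a composition-like argument (glycan_composition, named vector or
# string) to the canonical integer vector.
.as_comp <- function(c) {
  if (inherits(c, "glycan_composition")) return(unclass(c))
  if (is.character(c)) return(unclass(parse_composition(c)))
  if (is.numeric(c) && !is.null(names(c))) {
    out <- c(hex = 0, hexnac = 0, dhex = 0, neuac = 0)
    bad <- setdiff(names(c), names(out))
    if (length(bad))
      stop("unknown residue class: ", paste(bad, collapse = ", "), call. = FALSE)
    out[names(c)] <- c
    return(unclass(composition(out[["hex"]], out[["hexnac"]],
                               out[["dhex"]], out[["neuac"]])))
  }
  stop("cannot interpret argument as a glycan composition", call. = FALSE)
}
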