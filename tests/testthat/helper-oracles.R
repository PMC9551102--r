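# Independent oracles used across the suite. These deliberately avoid the
# package's residue-mass table and decomposition code: masses are rebuilt
# from elemental formulas and atomic masses, and decomposition is a plain
# quadruple nested loop.

# Atomic monoisotopic masses (CODATA/AME values)
.AT <- c(H = 1.00782503207, C = 12, N = 14.0030740048, O = 15.9949146196,
         Na = 22.9897692809, e = 0.00054857991)

# Elemental formulas of permethylated glycosyl residues as atom-count vectors
.RES_ATOMS <- list(
  hex    = c(C = 9,  H = 16, N = 0, O = 5),
  hexnac = c(C = 11, H = 19, N = 1, O = 5),
  dhex   = c(C = 8,  H = 14, N = 0, O = 4),
  neuac  = c(C = 16, H = 27, N = 1, O = 8)
)

.atom_mass <- function(atoms) sum(atoms * .AT[names(atoms)])

# Elemental-formula path to the sodiated molecular ion m/z
oracle_sodiated_mz <- function(hex, hexnac, dhex, neuac) {
  atoms <- c(C = 0, H = 0, N = 0, O = 0)
  counts <- c(hex = hex, hexnac = hexnac, dhex = dhex, neuac = neuac)
  for (r in names(counts))
    atoms <- atoms + counts[[r]] * .RES_ATOMS[[r]][names(atoms)]
  atoms <- atoms + c(C = 2, H = 6, N = 0, O = 1)  # free-reducing end groups
  .atom_mass(atoms) + .AT[["Na"]] - .AT[["e"]]
}

# Elemental-formula path to the B-type oxonium m/z
oracle_oxonium_mz <- function(hex, hexnac, dhex, neuac, internal = FALSE) {
  atoms <- c(C = 0, H = 0, N = 0, O = 0)
  counts <- c(hex = hex, hexnac = hexnac, dhex = dhex, neuac = neuac)
  for (r in names(counts))
    atoms <- atoms + counts[[r]] * .RES_ATOMS[[r]][names(atoms)]
  atoms <- atoms + c(C = 1, H = 3, N = 0, O = 0)  # charge-carrying methyl
  if (internal) atoms <- atoms - c(C = 1, H = 2, N = 0, O = 0)
  .atom_mass(atoms) - .AT[["e"]]
}

# Brute-force quadruple-nested-loop mass decomposition (reference path)
oracle_decompose <- function(mz, tolerance, bounds = c(hex = 15, hexnac = 12,
                                                       dhex = 10, neuac = 4)) {
  out <- list()
  for (h in 0:bounds[["hex"]]) for (hn in 0:bounds[["hexnac"]])
    for (d in 0:bounds[["dhex"]]) for (nu in 0:bounds[["neuac"]]) {
      if (h + hn + d + nu == 0) next
      if (!biosynthetically_plausible(h, hn, d, nu)) next
      m <- oracle_sodiated_mz(h, hn, d, nu)
      if (abs(m - mz) <= tolerance)
        out[[length(out) + 1L]] <- c(hex = h, hexnac = hn, dhex = d,
                                     neuac = nu)
    }
  if (length(out) == 0L)
    return(data.frame(hex = integer(), hexnac = integer(), dhex = integer(),
                      neuac = integer()))
  as.data.frame(do.call(rbind, out))
}

# Textbook Pearson r and two-sided p from the t distribution (n - 2 df)
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2))
}

# Textbook pooled-variance two-sample t statistic and two-sided p
oracle_pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, p = 2 * stats::pt(-abs(t), df = nx + ny - 2))
}

# Draw a random biosynthetically plausible composition within the default
# decomposition search bounds (hex 15, hexnac 12, dhex 10, neuac 4)
random_plausible_composition <- function(max_hex = 12, max_hexnac = 10) {
  repeat {
    hn <- sample(2:max_hexnac, 1)
    h <- sample(2:max_hex, 1)
    ant <- max(0, hn - 2)
    d <- sample(0:min(1 + 2 * ant, 10), 1)
    nu <- sample(0:min(ant, 4), 1)
    if (hn == 2) { nu <- 0; d <- min(d, 1); h <- min(h, 9) }
    if (hn >= 3) h <- max(h, 3)
    if (biosynthetically_plausible(h, hn, d, nu))
      return(composition(hex = h, hexnac = hn, dhex = d, neuac = nu))
  }
}

# Minimal annotation data frame for quantitation tests
make_ann <- function(fuc, neuac, intensity, lacnac = 2L,
                     glycan_class = "complex", contaminant = FALSE) {
  n <- max(length(fuc), length(neuac), length(intensity))
  data.frame(mz = seq_len(n) + 2000, intensity = rep_len(intensity, n),
             hex = 5L, hexnac = rep_len(lacnac, n) + 2L,
             dhex = rep_len(fuc, n), neuac = rep_len(neuac, n),
             composition = "x",
             glycan_class = rep_len(glycan_class, n),
             lacnac_units = rep_len(lacnac, n),
             fuc = rep_len(fuc, n), neuac_count = rep_len(neuac, n),
             gal_count = 2L, mass_error = 0,
             contaminant = rep_len(contaminant, n),
             stringsAsFactors = FALSE)
}
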