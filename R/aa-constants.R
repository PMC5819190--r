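# Amino-acid alphabets, physicochemical classes and reference tables.

#' The twenty standard amino acids
#'
#' One-letter codes in alphabetical order. All compositional statistics in the
#' package are computed over this alphabet; non-standard letters
#' (B, J, O, U, X, Z) are excluded from both numerator and denominator.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' amino_acids()
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# EMBOSS PEPSTATS physicochemical classes. Charged is a subset of polar;
# hydrophobic (non-polar) is the complement of polar; the classes overlap by
# design and are reported independently.
.aa_charged     <- c("D", "E", "H", "K", "R")
.aa_polar       <- c("D", "E", "H", "K", "N", "Q", "R", "S", "T")
.aa_hydrophobic <- c("A", "C", "F", "G", "I", "L", "M", "P", "V", "W", "Y")

# Ambiguity / non-standard letters tolerated in input but never scored.
.aa_nonstandard <- c("B", "J", "O", "U", "X", "Z")

#' Background amino-acid frequencies for simulated proteomes
#'
#' Typical average amino-acid frequencies of well-curated protein databases,
#' used as the default residue law for simulated mesophilic proteomes. The
#' vector is normalized to sum to exactly 1.
#'
#' @return Named numeric vector over [amino_acids()], summing to 1.
#' @export
#' @examples
#' sum(aa_background_freqs())
aa_background_freqs <- function() {
  f <- c(
    A = 8.25, C = 1.38, D = 5.45, E = 6.75, F = 3.86,
    G = 7.07, H = 2.27, I = 5.96, K = 5.84, L = 9.66,
    M = 2.42, N = 4.06, P = 4.70, Q = 3.93, R = 5.53,
    S = 6.56, T = 5.34, V = 6.87, W = 1.08, Y = 2.92
  ) / 100
  f[amino_acids()] / sum(f)
}

#' Default compositional shift of thermophilic proteomes
#'
#' Additive frequency deltas applied to the background law when simulating
#' thermophilic species: Ala, Glu, Gly, Pro, Arg and Val increase; Cys, His,
#' Ile, Lys, Met, Asn, Gln, Ser, Thr and Trp decrease; Asp, Phe, Leu and Tyr
#' are unchanged. Directions follow the compositional contrasts reported for
#' thermophilic versus mesophilic fungal proteomes; the magnitudes (+0.005 /
#' -0.003, balanced so the deltas sum to zero) are generator parameters, not
#' literature estimates.
#'
#' @return Named numeric vector over [amino_acids()], summing to 0.
#' @export
#' @examples
#' sum(thermophilic_shift())
thermophilic_shift <- function() {
  up   <- c("A", "E", "G", "P", "R", "V")
  down <- c("C", "H", "I", "K", "M", "N", "Q", "S", "T", "W")
  s <- setNames(numeric(20), amino_acids())
  s[up] <- 0.005
  s[down] <- -0.003
  s
}

# Average (isotope-averaged) residue masses in Da; water 18.0153 Da is added
# once per chain.
.aa_residue_mass <- c(
  A =  71.0788, C = 103.1388, D = 115.0886, E = 129.1155, F = 147.1766,
  G =  57.0519, H = 137.1411, I = 113.1594, K = 128.1741, L = 113.1594,
  M = 131.1926, N = 114.1038, P =  97.1167, Q = 128.1307, R = 156.1875,
  S =  87.0782, T = 101.1051, V =  99.1326, W = 186.2132, Y = 163.1760
)
.water_mass <- 18.0153

# EMBOSS pKa set for net-charge / pI computation.
.pka <- c(Nterm = 8.6, Cterm = 3.6, C = 8.5, D = 3.9, E = 4.1,
          H = 6.5, K = 10.8, R = 12.5, Y = 10.1)

# Van der Waals radii (Angstrom) by element, default 1.70 for others.
.vdw_radius <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20)
.vdw_default <- 1.70
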