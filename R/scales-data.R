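# Published per-residue scales and dipeptide weights used by the property
# calculators. Residue order is fixed alphabetical (one-letter codes) to match
# the feature encoders.

#' @keywords internal
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' @keywords internal
AA_AROMATIC <- c("F", "W", "Y")

# Kyte-Doolittle (1982) hydropathy scale.
#' @keywords internal
KD_HYDROPATHY <- c(
  A = 1.8,
  C = 2.5,
  D = -3.5,
  E = -3.5,
  F = 2.8,
  G = -0.4,
  H = -3.2,
  I = 4.5,
  K = -3.9,
  L = 3.8,
  M = 1.9,
  N = -3.5,
  P = -1.6,
  Q = -3.5,
  R = -4.5,
  S = -0.8,
  T = -0.7,
  V = 4.2,
  W = -0.9,
  Y = -1.3
)

# Average residue masses (Da), i.e. free amino-acid mass minus one water;
# peptide mass = sum of residue masses + one water (18.01524 Da).
#' @keywords internal
WATER_MASS <- 18.01524

#' @keywords internal
AA_RESIDUE_MASS <- c(
  A = 71.0779,
  C = 103.1429,
  D = 115.0874,
  E = 129.114,
  F = 147.1738,
  G = 57.0513,
  H = 137.1393,
  I = 113.1576,
  K = 128.1723,
  L = 113.1576,
  M = 131.196,
  N = 114.1026,
  P = 97.1152,
  Q = 128.1292,
  R = 156.1857,
  S = 87.0773,
  T = 101.1039,
  V = 99.131,
  W = 186.2099,
  Y = 163.1732
)

# Guruprasad, Reddy & Pandit (1990) dipeptide instability weight values
# (DIWV); rows = first residue, columns = second residue.
#' @keywords internal
DIWV <- matrix(c(
     1.00,   44.94,   -7.49,    1.00,    1.00,    1.00,   -7.49,    1.00,    1.00,    1.00,    1.00,    1.00,   20.26,    1.00,    1.00,    1.00,    1.00,    1.00,    1.00,    1.00,
     1.00,    1.00,   20.26,    1.00,    1.00,    1.00,   33.60,    1.00,    1.00,   20.26,   33.60,    1.00,   20.26,   -6.54,    1.00,    1.00,   33.60,   -6.54,   24.68,    1.00,
     1.00,    1.00,    1.00,    1.00,   -6.54,    1.00,    1.00,    1.00,   -7.49,    1.00,    1.00,    1.00,    1.00,    1.00,   -6.54,   20.26,  -14.03,    1.00,    1.00,    1.00,
     1.00,   44.94,   20.26,   33.60,    1.00,    1.00,   -6.54,   20.26,    1.00,    1.00,    1.00,    1.00,   20.26,   20.26,    1.00,   20.26,    1.00,    1.00,  -14.03,    1.00,
     1.00,    1.00,   13.34,    1.00,    1.00,    1.00,    1.00,    1.00,  -14.03,    1.00,    1.00,    1.00,   20.26,    1.00,    1.00,    1.00,    1.00,    1.00,    1.00,   33.60,
    -7.49,    1.00,    1.00,   -6.54,    1.00,   13.34,    1.00,   -7.49,   -7.49,    1.00,    1.00,   -7.49,    1.00,    1.00,    1.00,    1.00,   -7.49,    1.00,   13.34,   -7.49,
     1.00,    1.00,    1.00,    1.00,   -9.37,   -9.37,    1.00,   44.94,   24.68,    1.00,    1.00,   24.68,   -1.88,    1.00,    1.00,    1.00,   -6.54,    1.00,   -1.88,   44.94,
     1.00,    1.00,    1.00,   44.94,    1.00,    1.00,   13.34,    1.00,   -7.49,   20.26,    1.00,    1.00,   -1.88,    1.00,    1.00,    1.00,    1.00,   -7.49,    1.00,    1.00,
     1.00,    1.00,    1.00,    1.00,    1.00,   -7.49,    1.00,   -7.49,    1.00,   -7.49,   33.60,    1.00,   -6.54,   24.64,   33.60,    1.00,    1.00,   -7.49,    1.00,    1.00,
     1.00,    1.00,    1.00,    1.00,    1.00,    1.00,    1.00,    1.00,   -7.49,    1.00,    1.00,    1.00,   20.26,   33.60,   20.26,    1.00,    1.00,    1.00,   24.68,    1.00,
    13.34,    1.00,    1.00,    1.00,    1.00,    1.00,   58.28,    1.00,    1.00,    1.00,   -1.88,    1.00,   44.94,   -6.54,   -6.54,   44.94,   -1.88,    1.00,    1.00,   24.68,
     1.00,   -1.88,    1.00,    1.00,  -14.03,  -14.03,    1.00,   44.94,   24.68,    1.00,    1.00,    1.00,   -1.88,   -6.54,    1.00,    1.00,   -7.49,    1.00,   -9.37,    1.00,
    20.26,   -6.54,   -6.54,   18.38,   20.26,    1.00,    1.00,    1.00,    1.00,    1.00,   -6.54,    1.00,   20.26,   20.26,   -6.54,   20.26,    1.00,   20.26,   -1.88,    1.00,
     1.00,   -6.54,   20.26,   20.26,   -6.54,    1.00,    1.00,    1.00,    1.00,    1.00,    1.00,    1.00,   20.26,   20.26,    1.00,   44.94,    1.00,   -6.54,    1.00,   -6.54,
     1.00,    1.00,    1.00,    1.00,    1.00,   -7.49,   20.26,    1.00,    1.00,    1.00,    1.00,   13.34,   20.26,   20.26,   58.28,   44.94,    1.00,    1.00,   58.28,   -6.54,
     1.00,   33.60,    1.00,   20.26,    1.00,    1.00,    1.00,    1.00,    1.00,    1.00,    1.00,    1.00,   44.94,   20.26,   20.26,   20.26,    1.00,    1.00,    1.00,    1.00,
     1.00,    1.00,    1.00,   20.26,   13.34,   -7.49,    1.00,    1.00,    1.00,    1.00,    1.00,  -14.03,    1.00,   -6.54,    1.00,    1.00,    1.00,    1.00,  -14.03,    1.00,
     1.00,    1.00,  -14.03,    1.00,    1.00,   -7.49,    1.00,    1.00,   -1.88,    1.00,    1.00,    1.00,   20.26,    1.00,    1.00,    1.00,   -7.49,    1.00,    1.00,   -6.54,
   -14.03,    1.00,    1.00,    1.00,    1.00,   -9.37,   24.68,    1.00,    1.00,   13.34,   24.68,   13.34,    1.00,    1.00,    1.00,    1.00,  -14.03,   -7.49,    1.00,    1.00,
    24.68,    1.00,   24.68,   -6.54,    1.00,   -7.49,   13.34,    1.00,    1.00,    1.00,   44.94,    1.00,   13.34,    1.00,  -15.91,    1.00,   -7.49,    1.00,   -9.37,   13.34
), nrow = 20, byrow = TRUE, dimnames = list(AA_ALPHABET, AA_ALPHABET))

# Bjellqvist pK set as used by ProtParam: side-chain and terminal pK values,
# with residue-specific overrides for the termini.
#' @keywords internal
PK_POSITIVE <- c(Nterm = 7.5, K = 10.0, R = 12.0, H = 5.98)

#' @keywords internal
PK_NEGATIVE <- c(Cterm = 3.55, D = 4.05, E = 4.45, C = 9.0, Y = 10.0)

#' @keywords internal
PK_NTERM_BY_RESIDUE <- c(A = 7.59, M = 7.0, S = 6.93, P = 8.36, T = 6.82, V = 7.44, E = 7.7)

#' @keywords internal
PK_CTERM_BY_RESIDUE <- c(D = 4.55, E = 4.75)

# Overall amino-acid composition (percent) of UniProtKB/Swiss-Prot
# (release 2015_03 statistics), used as the default background for
# fold-change comparisons and as the negative-set sampling composition.
#' @keywords internal
SWISSPROT_COMPOSITION <- c(
  A = 8.25, C = 1.37, D = 5.45, E = 6.75, F = 3.86,
  G = 7.07, H = 2.27, I = 5.96, K = 5.84, L = 9.66,
  M = 2.42, N = 4.06, P = 4.70, Q = 3.93, R = 5.53,
  S = 6.56, T = 5.34, V = 6.87, W = 1.08, Y = 2.92
)
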