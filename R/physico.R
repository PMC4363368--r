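# ProtParam-style physicochemical property calculators and the per-set
# property panel (length, aromaticity, instability index, pI, molecular
# weight, GRAVY).

#' Aromaticity of a peptide
#'
#' Relative frequency of the aromatic residues Phe, Tyr and Trp:
#' `(count(F) + count(Y) + count(W)) / length`.
#'
#' @param seq an amino-acid sequence (character scalar).
#' @return Fraction in `[0, 1]`.
#' @examples
#' aromaticity("FALK")  # 0.25
#' @export
aromaticity <- function(seq) {
  ch <- aa_chars(seq)
  mean(ch %in% AA_AROMATIC)
}

#' Guruprasad instability index
#'
#' `II = (10 / L) * sum over i of DIWV(x_i, x_{i+1})`, summing the dipeptide
#' instability weight values of all `L - 1` overlapping dipeptides; 10 is a
#' scaling factor. A peptide with II below 40 is classed as stable.
#'
#' @inheritParams aromaticity
#' @param diwv optional 20 x 20 replacement weight table (rows = first
#'   residue); defaults to the published Guruprasad values.
#' @return Dimensionless index, with a `"stable"` logical attribute
#'   (`II < 40`).
#' @export
instability_index <- function(seq, diwv = DIWV) {
  ch <- aa_chars(seq)
  L <- length(ch)
  if (L < 2) stop("instability index requires length >= 2", call. = FALSE)
  ii <- 10 / L * sum(diwv[cbind(ch[-L], ch[-1])])
  structure(ii, stable = ii < 40)
}

#' Grand average of hydropathy (GRAVY)
#'
#' Sum of the Kyte-Doolittle hydropathy values of all residues divided by
#' the sequence length.
#'
#' @inheritParams aromaticity
#' @return Dimensionless mean hydropathy.
#' @export
gravy <- function(seq) {
  mean(KD_HYDROPATHY[aa_chars(seq)])
}

#' Peptide molecular weight
#'
#' Sum of average (not monoisotopic) residue masses plus one water mass
#' (18.01524 Da), following ProtParam conventions.
#'
#' @inheritParams aromaticity
#' @return Mass in Daltons.
#' @export
molecular_weight <- function(seq) {
  sum(AA_RESIDUE_MASS[aa_chars(seq)]) + WATER_MASS
}

#' Net charge of a peptide at a given pH
#'
#' Henderson-Hasselbalch sum over the two termini and the ionizable side
#' chains (D, E, C, Y negative; H, K, R positive) with the Bjellqvist pK set
#' used by ProtParam, including the residue-specific terminal pK overrides.
#'
#' @inheritParams aromaticity
#' @param pH the pH at which to evaluate the charge.
#' @return Net charge in elementary units.
#' @export
net_charge <- function(seq, pH) {
  ch <- aa_chars(seq)
  counts <- table(factor(ch, AA_ALPHABET))
  pk_n <- if (ch[1] %in% names(PK_NTERM_BY_RESIDUE)) {
    PK_NTERM_BY_RESIDUE[[ch[1]]]
  } else PK_POSITIVE[["Nterm"]]
  last <- ch[length(ch)]
  pk_c <- if (last %in% names(PK_CTERM_BY_RESIDUE)) {
    PK_CTERM_BY_RESIDUE[[last]]
  } else PK_NEGATIVE[["Cterm"]]
  pos_pk <- c(pk_n, PK_POSITIVE[["K"]], PK_POSITIVE[["R"]], PK_POSITIVE[["H"]])
  pos_n <- c(1, counts[["K"]], counts[["R"]], counts[["H"]])
  neg_pk <- c(pk_c, PK_NEGATIVE[["D"]], PK_NEGATIVE[["E"]],
              PK_NEGATIVE[["C"]], PK_NEGATIVE[["Y"]])
  neg_n <- c(1, counts[["D"]], counts[["E"]], counts[["C"]], counts[["Y"]])
  sum(pos_n / (1 + 10^(pH - pos_pk))) - sum(neg_n / (1 + 10^(neg_pk - pH)))
}

#' Isoelectric point
#'
#' The pH at which [net_charge()] is zero, located by bisection on (0, 14)
#' to a charge tolerance of 1e-4. Net charge is strictly decreasing in pH,
#' so the root is unique.
#'
#' @inheritParams aromaticity
#' @return pI in pH units.
#' @export
isoelectric_point <- function(seq) {
  lo <- 0; hi <- 14
  # charge(0) > 0 (all bases protonated) and charge(14) < 0 always hold
  # because both termini are counted, so bisection is safe.
  repeat {
    mid <- (lo + hi) / 2
    q <- net_charge(seq, mid)
    if (abs(q) < 1e-4 || (hi - lo) < 1e-8) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
}

#' Physicochemical property panel for a peptide set
#'
#' Computes length, aromaticity, instability index, isoelectric point,
#' molecular weight and GRAVY for every peptide. The instability index is
#' `NA` for single-residue peptides (it is defined over dipeptides).
#'
#' @param x a [peptide_set()].
#' @return A data frame of class `physico_profile`, one row per peptide.
#' @export
physico_profile <- function(x) {
  stopifnot(inherits(x, "peptide_set"))
  if (nrow(x) == 0) stop("empty peptide set", call. = FALSE)
  out <- data.frame(
    id = x$id,
    length = nchar(x$seq),
    aromaticity = vapply(x$seq, aromaticity, numeric(1), USE.NAMES = FALSE),
    instability_index = vapply(x$seq, function(s) {
      if (nchar(s) < 2) NA_real_ else as.numeric(instability_index(s))
    }, numeric(1), USE.NAMES = FALSE),
    pI = vapply(x$seq, isoelectric_point, numeric(1), USE.NAMES = FALSE),
    molecular_weight = vapply(x$seq, molecular_weight, numeric(1),
                              USE.NAMES = FALSE),
    gravy = vapply(x$seq, gravy, numeric(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
  class(out) <- c("physico_profile", "data.frame")
  attr(out, "name") <- attr(x, "name")
  out
}

#' Per-set summary of the property panel
#'
#' Mean, minimum, quartiles and maximum of each property over a peptide set,
#' mirroring box-plot style set comparisons between QSPs and non-QSPs.
#'
#' @param x a [peptide_set()] or a [physico_profile()].
#' @return A matrix with one row per property and columns
#'   `mean, min, q1, median, q3, max`.
#' @export
profile_summary <- function(x) {
  if (inherits(x, "peptide_set")) x <- physico_profile(x)
  stopifnot(inherits(x, "physico_profile"))
  props <- c("length", "aromaticity", "instability_index", "pI",
             "molecular_weight", "gravy")
  t(vapply(props, function(p) {
    v <- x[[p]][!is.na(x[[p]])]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    c(mean = mean(v), min = min(v), q1 = q[1], median = q[2], q3 = q[3],
      max = max(v))
  }, numeric(6)))
}
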