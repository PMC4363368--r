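# Descriptive analyses: pooled residue composition, fold change against a
# background composition, and two-sample positional enrichment at the
# peptide termini.

#' Pooled residue composition of a peptide set
#'
#' Residue counts pooled across all peptides, expressed as percentages of
#' the total residue count.
#'
#' @param x a non-empty [peptide_set()].
#' @return A data frame of class `composition_table` with columns `residue`,
#'   `count`, `percent`; attributes `n_peptides` and `total_residues`.
#' @export
composition <- function(x) {
  stopifnot(inherits(x, "peptide_set"))
  if (nrow(x) == 0) stop("empty peptide set", call. = FALSE)
  ch <- unlist(strsplit(x$seq, "", fixed = TRUE))
  counts <- tabulate(factor(ch, AA_ALPHABET), 20)
  out <- data.frame(residue = AA_ALPHABET, count = counts,
                    percent = 100 * counts / length(ch),
                    stringsAsFactors = FALSE)
  class(out) <- c("composition_table", "data.frame")
  attr(out, "n_peptides") <- nrow(x)
  attr(out, "total_residues") <- length(ch)
  attr(out, "name") <- attr(x, "name")
  out
}

#' Swiss-Prot background residue composition
#'
#' Overall amino-acid composition of UniProtKB/Swiss-Prot (release 2015_03
#' statistics), the default background for fold-change comparisons. Users
#' comparing against other proteomes supply their own table via
#' [composition_from_percent()].
#'
#' @return A `composition_table` (counts unavailable, set to `NA`).
#' @export
swissprot_composition <- function() {
  composition_from_percent(SWISSPROT_COMPOSITION, name = "Swiss-Prot 2015_03")
}

#' @rdname swissprot_composition
#' @param percent named numeric vector of per-residue percentages (names are
#'   one-letter residue codes); renormalized to total 100.
#' @param name label for the table.
#' @export
composition_from_percent <- function(percent, name = "") {
  stopifnot(all(names(percent) %in% AA_ALPHABET), all(percent >= 0))
  p <- stats::setNames(numeric(20), AA_ALPHABET)
  p[names(percent)] <- percent
  p <- 100 * p / sum(p)
  out <- data.frame(residue = AA_ALPHABET, count = NA_integer_,
                    percent = as.numeric(p), stringsAsFactors = FALSE)
  class(out) <- c("composition_table", "data.frame")
  attr(out, "name") <- name
  out
}

#' Per-residue fold change of a composition against a background
#'
#' Enriched residues are reported as `query / background` and depleted ones
#' as `background / query`, so every fold is at least 1 and carries a
#' direction (the "depleted by x-fold" convention). Residues absent from the
#' query are flagged as `"absent"`.
#'
#' @param query,background [composition()] tables; background percentages
#'   must be positive for all compared residues.
#' @return Data frame with columns `residue`, `query_percent`,
#'   `background_percent`, `fold`, `direction`.
#' @export
fold_change <- function(query, background) {
  stopifnot(inherits(query, "composition_table"),
            inherits(background, "composition_table"))
  q <- stats::setNames(query$percent, query$residue)[AA_ALPHABET]
  b <- stats::setNames(background$percent, background$residue)[AA_ALPHABET]
  if (any(b <= 0)) {
    stop("background composition must be positive for every residue",
         call. = FALSE)
  }
  direction <- ifelse(q == 0, "absent", ifelse(q >= b, "enriched", "depleted"))
  fold <- ifelse(q == 0, NA_real_, ifelse(q >= b, q / b, b / q))
  data.frame(residue = AA_ALPHABET, query_percent = as.numeric(q),
             background_percent = as.numeric(b), fold = fold,
             direction = direction, stringsAsFactors = FALSE)
}

#' Two-sample positional residue enrichment at the termini
#'
#' For each of the first `n_positions` N-terminal positions (+1..+n) and the
#' last `n_positions` C-terminal positions (-1..-n, -1 being the last
#' residue) and each residue, compares the residue frequency between the two
#' sets with a two-sided two-proportion z-test (with continuity correction).
#' Peptides shorter than `n_positions` are skipped with a warning.
#'
#' @param pos,neg [peptide_set()]s to compare (e.g. QSPs vs non-QSPs).
#' @param n_positions how many terminal positions to test on each side.
#' @param alpha significance threshold (default 0.05).
#' @param bonferroni apply Bonferroni correction over all performed tests.
#' @return Data frame of class `position_enrichment` with columns
#'   `position` (signed), `residue`, `freq_pos`, `freq_neg`, `p_value`,
#'   `direction`, `significant`; sorted by position then p-value. Attribute
#'   `n_skipped` counts length-filtered peptides.
#' @export
positional_enrichment <- function(pos, neg, n_positions = 5L, alpha = 0.05,
                                  bonferroni = FALSE) {
  stopifnot(inherits(pos, "peptide_set"), inherits(neg, "peptide_set"))
  keep_p <- nchar(pos$seq) >= n_positions
  keep_n <- nchar(neg$seq) >= n_positions
  n_skipped <- sum(!keep_p) + sum(!keep_n)
  if (n_skipped > 0) {
    warning(sprintf("skipped %d peptide(s) shorter than %d residues",
                    n_skipped, n_positions), call. = FALSE)
  }
  p_seq <- pos$seq[keep_p]; n_seq <- neg$seq[keep_n]
  if (length(p_seq) == 0 || length(n_seq) == 0) {
    stop("a set is empty after length filtering", call. = FALSE)
  }
  residue_at <- function(seqs, sp) {
    # sp > 0: position from N-terminus; sp < 0: from C-terminus (-1 = last)
    L <- nchar(seqs)
    at <- ifelse(sp > 0, sp, L + sp + 1)
    substring(seqs, at, at)
  }
  positions <- c(seq_len(n_positions), -seq_len(n_positions))
  rows <- list()
  for (sp in positions) {
    rp <- residue_at(p_seq, sp)
    rn <- residue_at(n_seq, sp)
    for (res in AA_ALPHABET) {
      k1 <- sum(rp == res); k2 <- sum(rn == res)
      if (k1 + k2 == 0) next
      pv <- suppressWarnings(stats::prop.test(
        c(k1, k2), c(length(rp), length(rn)), correct = TRUE))$p.value
      if (is.nan(pv)) pv <- 1
      f1 <- k1 / length(rp); f2 <- k2 / length(rn)
      rows[[length(rows) + 1]] <- data.frame(
        position = sp, residue = res, freq_pos = f1, freq_neg = f2,
        p_value = pv,
        direction = if (f1 >= f2) "enriched" else "depleted",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  cutoff <- if (bonferroni) alpha / nrow(out) else alpha
  out$significant <- out$p_value < cutoff
  out <- out[order(out$position, out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("position_enrichment", "data.frame")
  attr(out, "n_skipped") <- n_skipped
  attr(out, "alpha") <- cutoff
  out
}
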