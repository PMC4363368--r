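# Feature encodings: amino-acid composition (AAC), dipeptide composition
# (DPC), terminal one-hot binary profiles (N5Bin/C5Bin/N5C5Bin), AAindex
# physicochemical descriptors (Physico) and hybrid concatenations.

#' Load the AAindex physicochemical index table
#'
#' Returns the 544 per-residue physicochemical indices distributed with the
#' AAindex database (as bundled by the seqinr package) as a matrix with one
#' row per accession and 20 columns in fixed alphabetical residue order.
#' A small number of indices contain missing values; these are retained in
#' the table but excluded from index screening.
#'
#' @return A 544 x 20 numeric matrix, rownames the AAindex accessions, with
#'   a `"description"` attribute carrying the index titles.
#' @export
aaindex_table <- function() {
  env <- new.env()
  utils::data("aaindex", package = "seqinr", envir = env)
  idx <- env$aaindex
  three <- c(A = "Ala", C = "Cys", D = "Asp", E = "Glu", F = "Phe",
             G = "Gly", H = "His", I = "Ile", K = "Lys", L = "Leu",
             M = "Met", N = "Asn", P = "Pro", Q = "Gln", R = "Arg",
             S = "Ser", T = "Thr", V = "Val", W = "Trp", Y = "Tyr")
  m <- t(vapply(idx, function(e) unname(e$I[three]), numeric(20)))
  rownames(m) <- vapply(idx, function(e) e$H, character(1))
  colnames(m) <- AA_ALPHABET
  attr(m, "description") <- stats::setNames(
    vapply(idx, function(e) e$D, character(1)), rownames(m))
  m
}

#' AAindex accessions of secondary-structure-heavy indices reported to
#' discriminate QSPs
#'
#' A named preset of twelve AAindex accessions, dominated by helix/turn/coil
#' propensity scales, that showed clear between-class variance in published
#' QSP screening. [select_top_indices()] re-derives a data-driven top list;
#' this preset is provided for users who want the published starting point.
#'
#' @return Character vector of AAindex accessions.
#' @export
qsp_physico_preset <- function() {
  c("NAGK730101", "KANM800101", "AURR980118", "AURR980103",
    "AURR980101", "CHAM830101", "CHOP780210", "CHOP780101",
    "FASG760105", "LEVM760105", "RICJ880105", "WOEC730101")
}

#' Describe a feature encoding
#'
#' An encoding spec names one of the fixed-length encodings, or a hybrid
#' concatenation of several. Dimensionality: AAC = 20, DPC = 400,
#' N5Bin = 20 * n_term_len, C5Bin = 20 * c_term_len,
#' N5C5Bin = 20 * (n_term_len + c_term_len), Physico = number of accessions,
#' hybrid = sum over components.
#'
#' @param scheme one of `"AAC"`, `"DPC"`, `"N5Bin"`, `"C5Bin"`, `"N5C5Bin"`,
#'   `"Physico"`, `"hybrid"`.
#' @param n_term_len,c_term_len terminal window lengths for the binary
#'   profiles (default 5).
#' @param aaindex_ids ordered AAindex accessions (Physico only).
#' @param components list of `encoding_spec` objects (hybrid only).
#' @return An object of class `encoding_spec`.
#' @examples
#' encoding_spec("AAC")
#' encoding_spec("hybrid", components = list(
#'   encoding_spec("AAC"), encoding_spec("DPC")))
#' @export
encoding_spec <- function(scheme = c("AAC", "DPC", "N5Bin", "C5Bin",
                                     "N5C5Bin", "Physico", "hybrid"),
                          n_term_len = 5L, c_term_len = 5L,
                          aaindex_ids = NULL, components = NULL) {
  scheme <- match.arg(scheme)
  if (scheme == "Physico" && length(aaindex_ids) == 0) {
    stop("Physico encoding requires `aaindex_ids`", call. = FALSE)
  }
  if (scheme == "hybrid") {
    if (length(components) == 0) {
      stop("hybrid encoding requires `components`", call. = FALSE)
    }
    stopifnot(all(vapply(components, inherits, logical(1), "encoding_spec")))
  }
  out <- structure(
    list(scheme = scheme, n_term_len = as.integer(n_term_len),
         c_term_len = as.integer(c_term_len),
         aaindex_ids = aaindex_ids, components = components),
    class = "encoding_spec")
  out$n_features <- n_features(out)
  out
}

n_features <- function(spec) {
  switch(spec$scheme,
    AAC = 20L,
    DPC = 400L,
    N5Bin = 20L * spec$n_term_len,
    C5Bin = 20L * spec$c_term_len,
    N5C5Bin = 20L * (spec$n_term_len + spec$c_term_len),
    Physico = length(spec$aaindex_ids),
    hybrid = sum(vapply(spec$components, n_features, integer(1))))
}

#' @export
print.encoding_spec <- function(x, ...) {
  if (x$scheme == "hybrid") {
    cat(sprintf("encoding_spec: hybrid of %s (%d features)\n",
                paste(vapply(x$components, function(s) s$scheme, character(1)),
                      collapse = "+"),
                x$n_features))
  } else {
    cat(sprintf("encoding_spec: %s (%d features)\n", x$scheme, x$n_features))
  }
  invisible(x)
}

#' Amino-acid composition of one sequence
#'
#' Fraction of each of the 20 residues, in fixed alphabetical order
#' ACDEFGHIKLMNPQRSTVWY. Components sum to 1.
#'
#' @param seq an amino-acid sequence (character scalar).
#' @return Named numeric vector of length 20.
#' @examples
#' encode_aac("ACDE")
#' @export
encode_aac <- function(seq) {
  ch <- aa_chars(seq)
  stats::setNames(tabulate(factor(ch, AA_ALPHABET), 20) / length(ch),
                  AA_ALPHABET)
}

#' Dipeptide composition of one sequence
#'
#' Fraction of each of the 400 overlapping residue pairs, row-major in the
#' fixed alphabetical residue order (AA, AC, ..., YY). Requires length >= 2;
#' components sum to 1.
#'
#' @inheritParams encode_aac
#' @return Named numeric vector of length 400.
#' @export
encode_dpc <- function(seq) {
  ch <- aa_chars(seq)
  L <- length(ch)
  if (L < 2) stop("dipeptide composition requires length >= 2", call. = FALSE)
  dip <- paste0(ch[-L], ch[-1])
  lev <- as.vector(t(outer(AA_ALPHABET, AA_ALPHABET, paste0)))
  stats::setNames(tabulate(factor(dip, lev), 400) / (L - 1), lev)
}

#' Terminal one-hot binary profile of one sequence
#'
#' Maps the first `n_term_len` and last `c_term_len` residues each to a
#' 20-slot one-hot block (alphabetical residue order); all N-terminal blocks
#' precede all C-terminal blocks. For peptides shorter than
#' `n_term_len + c_term_len` the two windows overlap, which is permitted;
#' peptides shorter than either single window are rejected.
#'
#' @inheritParams encode_aac
#' @param n_term_len,c_term_len window lengths (either may be 0).
#' @return Numeric 0/1 vector of length `20 * (n_term_len + c_term_len)`
#'   containing exactly `n_term_len + c_term_len` ones.
#' @export
encode_binary <- function(seq, n_term_len = 5L, c_term_len = 5L) {
  ch <- aa_chars(seq)
  L <- length(ch)
  if (L < max(n_term_len, c_term_len)) {
    stop(sprintf("peptide of length %d is shorter than the %d-residue terminal window",
                 L, max(n_term_len, c_term_len)), call. = FALSE)
  }
  one_hot <- function(residues) {
    idx <- match(residues, AA_ALPHABET)
    v <- numeric(20 * length(residues))
    v[20 * (seq_along(idx) - 1) + idx] <- 1
    v
  }
  n_part <- if (n_term_len > 0) one_hot(ch[seq_len(n_term_len)]) else numeric(0)
  c_part <- if (c_term_len > 0) one_hot(ch[seq.int(L - c_term_len + 1, L)]) else numeric(0)
  v <- c(n_part, c_part)
  names(v) <- c(if (n_term_len > 0) paste0("N", rep(seq_len(n_term_len), each = 20), ".",
                                           rep(AA_ALPHABET, n_term_len)),
                if (c_term_len > 0) paste0("C", rep(seq_len(c_term_len), each = 20), ".",
                                           rep(AA_ALPHABET, c_term_len)))
  v
}

#' AAindex physicochemical descriptor vector of one sequence
#'
#' Each component is the arithmetic mean over the peptide's residues of one
#' AAindex per-residue scale — the simplest length-invariant statistic that
#' turns a 20-value scale into a single fixed-length feature.
#'
#' @inheritParams encode_aac
#' @param table an AAindex matrix from [aaindex_table()].
#' @param ids ordered AAindex accessions to use.
#' @return Named numeric vector of length `length(ids)`.
#' @export
encode_physico <- function(seq, table = aaindex_table(), ids) {
  missing_ids <- setdiff(ids, rownames(table))
  if (length(missing_ids) > 0) {
    stop("unknown AAindex accession(s): ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  ch <- aa_chars(seq)
  idx <- match(ch, AA_ALPHABET)
  vapply(ids, function(a) mean(table[a, idx]), numeric(1))
}

#' Encode a peptide set as a feature matrix
#'
#' Applies the encoding described by `spec` to every peptide; hybrid specs
#' concatenate their component encodings in listed order. Row order follows
#' the set; rownames are peptide ids.
#'
#' @param spec an [encoding_spec()].
#' @param x a [peptide_set()].
#' @param table AAindex matrix (used by Physico components).
#' @return Numeric matrix, `nrow(x)` rows by `spec$n_features` columns.
#' @export
encode <- function(spec, x, table = NULL) {
  stopifnot(inherits(spec, "encoding_spec"), inherits(x, "peptide_set"))
  if (uses_physico(spec) && is.null(table)) table <- aaindex_table()
  enc_one <- function(seq) encode_one(spec, seq, table)
  if (nrow(x) == 0) {
    m <- matrix(numeric(0), nrow = 0, ncol = spec$n_features)
    return(m)
  }
  rows <- lapply(seq_len(nrow(x)), function(i) {
    tryCatch(enc_one(x$seq[[i]]), error = function(e) {
      stop(sprintf("cannot encode peptide '%s': %s",
                   x$id[[i]], conditionMessage(e)), call. = FALSE)
    })
  })
  m <- do.call(rbind, rows)
  rownames(m) <- x$id
  m
}

uses_physico <- function(spec) {
  if (spec$scheme == "Physico") return(TRUE)
  if (spec$scheme == "hybrid") {
    return(any(vapply(spec$components, uses_physico, logical(1))))
  }
  FALSE
}

encode_one <- function(spec, seq, table) {
  switch(spec$scheme,
    AAC = encode_aac(seq),
    DPC = encode_dpc(seq),
    N5Bin = encode_binary(seq, spec$n_term_len, 0L),
    C5Bin = encode_binary(seq, 0L, spec$c_term_len),
    N5C5Bin = encode_binary(seq, spec$n_term_len, spec$c_term_len),
    Physico = encode_physico(seq, table, spec$aaindex_ids),
    hybrid = unlist(lapply(spec$components, encode_one, seq = seq,
                           table = table)))
}

#' Screen AAindex scales by single-feature classification performance
#'
#' Evaluates every complete AAindex scale as a one-dimensional RBF-SVM
#' classifier by stratified k-fold cross-validated accuracy on the labelled
#' training set, and returns the `k` best accessions (descending accuracy,
#' ties broken by accession string). The fold partition is fixed across
#' scales so the ranking is deterministic given `seed`.
#'
#' @param x a labelled [peptide_set()] containing both classes.
#' @param table AAindex matrix from [aaindex_table()] (possibly subsetted).
#' @param k number of accessions to return.
#' @param folds number of cross-validation folds.
#' @param seed integer seed for the fold partition.
#' @return Character vector of `k` accessions, best first, with the
#'   per-accession CV accuracies in attribute `"accuracy"`.
#' @export
select_top_indices <- function(x, table = aaindex_table(), k = 10L,
                               folds = 10L, seed = 1L) {
  stopifnot(inherits(x, "peptide_set"))
  y <- peptide_labels(x)
  if (nlevels(droplevels(y)) < 2) {
    stop("index screening needs both classes in `x`", call. = FALSE)
  }
  complete <- rownames(table)[apply(is.finite(table), 1, all)]
  if (k > length(complete)) {
    stop("`k` exceeds the number of complete indices", call. = FALSE)
  }
  fold_id <- stratified_folds(y, folds, seed)
  idx <- lapply(aa_chars_set(x), match, AA_ALPHABET)
  acc <- vapply(complete, function(a) {
    vals <- vapply(idx, function(i) mean(table[a, i]), numeric(1))
    cv_accuracy_1d(vals, y, fold_id)
  }, numeric(1))
  ord <- order(-acc, complete)
  out <- complete[ord][seq_len(k)]
  attr(out, "accuracy") <- acc[ord][seq_len(k)]
  out
}

# Residue index lists for each peptide in a set (cached split).
aa_chars_set <- function(x) lapply(x$seq, function(s) strsplit(s, "", fixed = TRUE)[[1]])

# CV accuracy of a single-feature RBF SVM at default cost.
cv_accuracy_1d <- function(vals, y, fold_id) {
  pred <- factor(rep(NA_character_, length(y)), levels(y))
  for (f in sort(unique(fold_id))) {
    tr <- fold_id != f
    rng <- range(vals[tr])
    sc <- if (diff(rng) > 0) (vals - rng[1]) / diff(rng) else vals * 0
    fit <- e1071::svm(x = matrix(sc[tr], ncol = 1), y = y[tr],
                      kernel = "radial", cost = 1, gamma = 1, scale = FALSE)
    pred[!tr] <- stats::predict(fit, matrix(sc[!tr], ncol = 1))
  }
  mean(pred == y)
}

# Labels as a factor with fixed level order (positive first).
peptide_labels <- function(x) {
  if (any(x$label == "unknown")) {
    stop("peptide set contains unlabelled peptides", call. = FALSE)
  }
  factor(x$label, levels = c("positive", "negative"))
}

aa_chars <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1)
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  if (length(ch) == 0) stop("empty sequence", call. = FALSE)
  bad <- which(!ch %in% AA_ALPHABET)
  if (length(bad) > 0) {
    stop(sprintf("invalid residue '%s' at offset %d", ch[bad[1]], bad[1]),
         call. = FALSE)
  }
  ch
}

#' Min-max feature scaling learned on training data
#'
#' Computes per-column ranges on a training matrix; [apply_scaling()] maps
#' features into `[0, 1]` using those ranges (constant columns map to 0).
#' Scaling is always learned on training folds only, never on held-out data.
#'
#' @param x numeric matrix of training features.
#' @return A list with elements `min` and `range`.
#' @export
scaling_ranges <- function(x) {
  mn <- apply(x, 2, min)
  rg <- apply(x, 2, max) - mn
  list(min = mn, range = rg)
}

#' @rdname scaling_ranges
#' @param ranges a list from `scaling_ranges()`.
#' @export
apply_scaling <- function(x, ranges) {
  rg <- ifelse(ranges$range > 0, ranges$range, 1)
  out <- sweep(sweep(x, 2, ranges$min), 2, rg, "/")
  out[, ranges$range == 0] <- 0
  out
}
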