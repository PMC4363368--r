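# Peptide sets: construction, FASTA I/O, validation, deduplication,
# train/validation splitting and scramble-negative generation.

#' Construct a peptide set
#'
#' A peptide set is a data frame with columns `id`, `seq` and `label`, one
#' row per peptide. Sequences must use the 20 standard one-letter amino-acid
#' codes (uppercase); ids must be unique within a set.
#'
#' @param id character vector of record identifiers.
#' @param seq character vector of amino-acid sequences.
#' @param label class labels, recycled; one of `"positive"`, `"negative"`,
#'   `"unknown"`.
#' @param name optional name for the set.
#' @return An object of class `peptide_set` (a data frame).
#' @examples
#' peptide_set("p1", "SGSLSTFFRLFNRSFTQA", label = "positive")
#' @export
peptide_set <- function(id, seq, label = "unknown", name = "") {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (length(id) != length(seq)) {
    stop("`id` and `seq` must have the same length", call. = FALSE)
  }
  label <- rep_len(match.arg(label, c("unknown", "positive", "negative"),
                             several.ok = TRUE),
                   length(seq))
  if (any(!nzchar(id))) stop("peptide ids must be non-empty", call. = FALSE)
  dup <- id[duplicated(id)]
  if (length(dup) > 0) {
    stop("duplicate peptide id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad <- validate_residues(seq)
  if (nrow(bad) > 0) {
    stop(sprintf("invalid residue '%s' in record '%s' at offset %d",
                 bad$residue[1], id[bad$record[1]], bad$offset[1]),
         call. = FALSE)
  }
  if (any(!nzchar(seq))) stop("peptide sequences must be non-empty", call. = FALSE)
  out <- data.frame(id = id, seq = seq, label = label,
                    stringsAsFactors = FALSE)
  class(out) <- c("peptide_set", "data.frame")
  attr(out, "name") <- name
  out
}

# Locate characters outside the 20-letter alphabet. Returns a data frame
# with one row per offending character: record index, 1-based offset, residue.
validate_residues <- function(seq) {
  rec <- integer(0); off <- integer(0); res <- character(0)
  for (i in seq_along(seq)) {
    ch <- strsplit(seq[[i]], "", fixed = TRUE)[[1]]
    bad <- which(!ch %in% AA_ALPHABET)
    if (length(bad) > 0) {
      rec <- c(rec, rep(i, length(bad)))
      off <- c(off, bad)
      res <- c(res, ch[bad])
    }
  }
  data.frame(record = rec, offset = off, residue = res,
             stringsAsFactors = FALSE)
}

#' Read peptides from a FASTA file
#'
#' Sequences are uppercased on input. Records containing characters outside
#' the 20 standard amino-acid codes are rejected (`mode = "strict"`) or
#' dropped with a warning (`mode = "lenient"`); there is no silent
#' substitution, because every downstream encoding indexes the 20-letter
#' alphabet. An optional header convention `"|label=positive"` overrides
#' the `label` argument for that record.
#'
#' @param path path to a FASTA file (wrapped or unwrapped lines).
#' @param label class label assigned to all records lacking a header label.
#' @param mode `"strict"` (default) or `"lenient"`.
#' @return A [peptide_set()].
#' @export
read_fasta <- function(path, label = "unknown", mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  recs <- tryCatch(
    seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                       forceDNAtolower = FALSE),
    error = function(e) stop("could not parse FASTA file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (length(recs) == 0) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- vapply(recs, function(r) attr(r, "name"), character(1))
  seqs <- toupper(vapply(recs, as.character, character(1)))

  labels <- rep_len(label, length(ids))
  has_lab <- grepl("\\|label=", ids)
  labels[has_lab] <- sub(".*\\|label=([a-z]+).*", "\\1", ids[has_lab])
  ids[has_lab] <- sub("\\|label=[a-z]+", "", ids[has_lab])

  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad <- validate_residues(seqs)
  if (nrow(bad) > 0) {
    if (mode == "strict") {
      stop(sprintf("invalid residue '%s' in record '%s' at offset %d",
                   bad$residue[1], ids[bad$record[1]], bad$offset[1]),
           call. = FALSE)
    }
    drop <- unique(bad$record)
    warning(sprintf("dropped %d record(s) with non-standard residues: %s",
                    length(drop), paste(ids[drop], collapse = ", ")),
            call. = FALSE)
    ids <- ids[-drop]; seqs <- seqs[-drop]; labels <- labels[-drop]
  }
  if (length(ids) == 0) stop("no valid records in ", path, call. = FALSE)
  peptide_set(ids, seqs, labels, name = basename(path))
}

#' Write a peptide set to FASTA
#'
#' Round-trips losslessly with [read_fasta()] for valid records.
#'
#' @param x a [peptide_set()].
#' @param path output file path.
#' @param with_labels if `TRUE`, append `"|label=<label>"` to each header.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, with_labels = FALSE) {
  stopifnot(inherits(x, "peptide_set"))
  ids <- if (with_labels) paste0(x$id, "|label=", x$label) else x$id
  seqinr::write.fasta(as.list(x$seq), names = ids, file.out = path,
                      nbchar = 60, as.string = TRUE)
  invisible(path)
}

#' Remove exact duplicate sequences
#'
#' Keeps the first occurrence of each distinct sequence, preserving input
#' order. Duplicate means 100% identity of the full sequence; no
#' similarity-based redundancy reduction is performed.
#'
#' @param x a [peptide_set()].
#' @return The deduplicated `peptide_set`, with the number of removed
#'   records in attribute `"n_removed"`.
#' @export
deduplicate <- function(x) {
  stopifnot(inherits(x, "peptide_set"))
  keep <- !duplicated(x$seq)
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(x)
  attr(out, "name") <- attr(x, "name")
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Split positive and negative sets into training and validation parts
#'
#' Holds out `n_holdout` peptides per class, sampled uniformly without
#' replacement under `seed`; the remainder forms the training set. The two
#' parts are disjoint and together contain every input peptide.
#'
#' @param pos,neg positive and negative [peptide_set()]s; their labels are
#'   set to `"positive"` / `"negative"`.
#' @param n_holdout number of peptides to hold out from each class.
#' @param seed integer random seed.
#' @return A list with elements `train` and `validation`, each a labelled
#'   `peptide_set`.
#' @export
split_peptides <- function(pos, neg, n_holdout, seed = 1L) {
  stopifnot(inherits(pos, "peptide_set"), inherits(neg, "peptide_set"))
  if (n_holdout < 0 || n_holdout > nrow(pos) || n_holdout > nrow(neg)) {
    stop("`n_holdout` must be between 0 and the smaller class size",
         call. = FALSE)
  }
  pos$label <- "positive"
  neg$label <- "negative"
  idx <- with_seed(seed, list(
    pos = sample.int(nrow(pos), n_holdout),
    neg = sample.int(nrow(neg), n_holdout)))
  bind <- function(a, b) {
    out <- rbind(as.data.frame(a), as.data.frame(b))
    rownames(out) <- NULL
    class(out) <- c("peptide_set", "data.frame")
    out
  }
  list(
    train = bind(pos[setdiff(seq_len(nrow(pos)), idx$pos), ],
                 neg[setdiff(seq_len(nrow(neg)), idx$neg), ]),
    validation = bind(pos[idx$pos, , drop = FALSE],
                      neg[idx$neg, , drop = FALSE]))
}

#' Scramble peptide sequences to build a composition-matched negative set
#'
#' Each output sequence is an independent uniformly random permutation of the
#' corresponding input's residues, so the per-sequence residue multiset (and
#' hence the amino-acid composition) is preserved exactly. Output labels are
#' `"negative"` and ids gain a `"_scr"` suffix.
#'
#' @param x a [peptide_set()].
#' @param seed integer random seed.
#' @return A `peptide_set` of scrambled negatives, in the input order.
#' @export
scramble_peptides <- function(x, seed = 1L) {
  stopifnot(inherits(x, "peptide_set"))
  seqs <- with_seed(seed, vapply(x$seq, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    paste(ch[sample.int(length(ch))], collapse = "")
  }, character(1), USE.NAMES = FALSE))
  peptide_set(paste0(x$id, "_scr"), seqs, "negative",
              name = paste0(attr(x, "name"), "_scrambled"))
}

#' @export
print.peptide_set <- function(x, ...) {
  lab <- table(factor(x$label, c("positive", "negative", "unknown")))
  cat(sprintf("peptide_set '%s': %d peptide(s) (%d positive, %d negative, %d unknown)\n",
              attr(x, "name") %||% "", nrow(x),
              lab[["positive"]], lab[["negative"]], lab[["unknown"]]))
  if (nrow(x) > 0) {
    rng <- range(nchar(x$seq))
    cat(sprintf("  length range %d-%d\n", rng[1], rng[2]))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}
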