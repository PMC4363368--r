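# Peptide design and protein scanning tools: exhaustive single-position
# mutants (MutGen / QSPepDesign) and sliding-window fragments
# (ProtFrag / QSPepMap), wired to the trained classifier.

#' Generate all single-position mutants of a peptide
#'
#' Emits exactly `19 * L` mutants — every position crossed with every
#' alternative residue — in deterministic order (position-major, residues
#' alphabetical). Each mutant is at Hamming distance 1 from the parent.
#'
#' @param seq parent amino-acid sequence.
#' @param id parent identifier.
#' @return Data frame with columns `parent_id`, `position` (0-based),
#'   `original`, `substituted`, `seq`.
#' @export
mutgen <- function(seq, id = "peptide") {
  ch <- aa_chars(seq)
  L <- length(ch)
  rows <- vector("list", L)
  for (i in seq_len(L)) {
    subs <- setdiff(AA_ALPHABET, ch[i])
    muts <- vapply(subs, function(r) {
      m <- ch; m[i] <- r; paste(m, collapse = "")
    }, character(1))
    rows[[i]] <- data.frame(parent_id = id, position = i - 1L,
                            original = ch[i], substituted = subs,
                            seq = unname(muts), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sliding-window fragments of a protein
#'
#' Windows of length `w` at starts `0, step, 2*step, ...` while
#' `start + w <= L`; the number of fragments is
#' `floor((L - w) / step) + 1`. Coordinates are 0-based and half-open.
#'
#' @param seq protein sequence.
#' @param w window length (`1 <= w <= L`).
#' @param step stride between window starts.
#' @param id protein identifier.
#' @return Data frame with columns `protein_id`, `start` (0-based), `end`
#'   (exclusive), `seq`.
#' @export
protfrag <- function(seq, w, step = 1L, id = "protein") {
  ch <- aa_chars(seq)
  L <- length(ch)
  if (w < 1 || w > L) stop("window length must be in 1..L", call. = FALSE)
  if (step < 1) stop("step must be >= 1", call. = FALSE)
  starts <- seq.int(0L, L - w, by = step)
  data.frame(protein_id = id, start = as.integer(starts),
             end = as.integer(starts + w),
             seq = substring(seq, starts + 1, starts + w),
             stringsAsFactors = FALSE)
}

#' Design and score all single-position mutants of a peptide
#'
#' Runs [mutgen()], scores the parent and every mutant with the trained
#' model, and returns them sorted by decision value (descending) with the
#' parent row flagged. Unscorable records are reported per-row, not dropped.
#'
#' @param model a [qsp_train()] model.
#' @param seq parent peptide sequence.
#' @param id parent identifier.
#' @return Data frame: mutant fields plus `decision`, `label`, `scorable`,
#'   `reason`, `is_parent`; `19 * L + 1` rows.
#' @export
qspepdesign <- function(model, seq, id = "peptide") {
  stopifnot(inherits(model, "qsp_model"))
  muts <- mutgen(seq, id)
  all_rows <- rbind(
    data.frame(parent_id = id, position = NA_integer_,
               original = NA_character_, substituted = NA_character_,
               seq = toupper(seq), stringsAsFactors = FALSE),
    muts)
  all_rows$is_parent <- c(TRUE, rep(FALSE, nrow(muts)))
  ps <- peptide_set(paste0(id, "_v", seq_len(nrow(all_rows)) - 1),
                    all_rows$seq)
  sc <- predict(model, ps)
  out <- cbind(all_rows, sc[, c("decision", "label", "scorable", "reason")])
  out <- out[order(-out$decision, !out$is_parent), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a protein for potential QSP regions
#'
#' Scores every sliding window with the trained model and merges runs of
#' overlapping or adjacent positive windows into candidate regions
#' (0-based, half-open, aligned to window bounds).
#'
#' @param model a [qsp_train()] model.
#' @param seq protein sequence.
#' @param w window length (default 12, a typical QSP length).
#' @param step stride between windows.
#' @param id protein identifier.
#' @return A list of class `qspepmap` with elements `windows` (scored
#'   fragment data frame) and `regions` (merged positive regions with
#'   `start`, `end`, `n_windows`, `max_decision`).
#' @export
qspepmap <- function(model, seq, w = 12L, step = 1L, id = "protein") {
  stopifnot(inherits(model, "qsp_model"))
  frags <- protfrag(seq, w, step, id)
  ps <- peptide_set(paste0(id, "_w", frags$start), frags$seq)
  sc <- predict(model, ps)
  windows <- cbind(frags, sc[, c("decision", "label", "scorable", "reason")])

  pos <- windows[!is.na(windows$label) & windows$label == "positive", ,
                 drop = FALSE]
  regions <- if (nrow(pos) == 0) {
    data.frame(start = integer(0), end = integer(0), n_windows = integer(0),
               max_decision = numeric(0))
  } else {
    pos <- pos[order(pos$start), , drop = FALSE]
    grp <- cumsum(c(1, as.integer(pos$start[-1] > pos$end[-nrow(pos)])))
    do.call(rbind, lapply(split(pos, grp), function(g) {
      data.frame(start = min(g$start), end = max(g$end),
                 n_windows = nrow(g), max_decision = max(g$decision))
    }))
  }
  rownames(regions) <- NULL
  structure(list(windows = windows, regions = regions, id = id,
                 w = as.integer(w), step = as.integer(step)),
            class = "qspepmap")
}

#' @export
print.qspepmap <- function(x, ...) {
  cat(sprintf("qspepmap '%s': %d window(s) of length %d (step %d), %d positive region(s)\n",
              x$id, nrow(x$windows), x$w, x$step, nrow(x$regions)))
  if (nrow(x$regions) > 0) print(x$regions)
  invisible(x)
}
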