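# Bracket-class motif patterns (PROSITE-like: literal residues and [..]
# alternative classes), scanning, and peptide-level PPV / coverage
# evaluation.

#' Parse a bracket-class motif pattern
#'
#' A pattern is a sequence of positions, each either a literal residue or a
#' non-empty bracketed alternative class such as `[YP]`; every match has
#' length equal to the number of positions.
#'
#' @param expr pattern string, e.g. `"[YP][NS][PTI][CF]GQ[YW][MF]"`.
#' @param id identifier carried into scan results.
#' @return An object of class `motif_pattern` with elements `id`, `expr`,
#'   `positions` (list of allowed residue vectors), `length` and `regex`.
#' @export
parse_motif <- function(expr, id = expr) {
  if (!is.character(expr) || length(expr) != 1 || !nzchar(expr)) {
    stop("motif expression must be a non-empty string", call. = FALSE)
  }
  ch <- strsplit(expr, "", fixed = TRUE)[[1]]
  positions <- list()
  i <- 1
  while (i <= length(ch)) {
    if (ch[i] == "[") {
      close <- which(ch == "]" & seq_along(ch) > i)
      if (length(close) == 0) {
        stop("unbalanced '[' in motif '", expr, "'", call. = FALSE)
      }
      close <- close[1]
      cls <- ch[seq.int(i + 1, length.out = close - i - 1)]
      if (length(cls) == 0) {
        stop("empty residue class in motif '", expr, "'", call. = FALSE)
      }
      positions <- c(positions, list(cls))
      i <- close + 1
    } else if (ch[i] == "]") {
      stop("unbalanced ']' in motif '", expr, "'", call. = FALSE)
    } else {
      positions <- c(positions, list(ch[i]))
      i <- i + 1
    }
  }
  bad <- setdiff(unique(unlist(positions)), AA_ALPHABET)
  if (length(bad) > 0) {
    stop("invalid residue letter(s) in motif '", expr, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  regex <- paste(vapply(positions, function(p) {
    if (length(p) == 1) p else paste0("[", paste(p, collapse = ""), "]")
  }, character(1)), collapse = "")
  structure(list(id = id, expr = expr, positions = positions,
                 length = length(positions), regex = regex),
            class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat(sprintf("motif_pattern '%s': %s (%d positions)\n",
              x$id, x$expr, x$length))
  invisible(x)
}

#' The bundled quorum-sensing-peptide motif set
#'
#' Nine bracket-class motifs recovered from QSP sets, shipped as the default
#' pattern file (`extdata/qsp_motifs.tsv`); users may supply their own file
#' in the same `id<TAB>expression` format via [read_motifs()].
#'
#' @return A list of [parse_motif()] patterns.
#' @export
qsp_motifs <- function() {
  read_motifs(system.file("extdata", "qsp_motifs.tsv", package = "qsppred",
                          mustWork = TRUE))
}

#' @rdname qsp_motifs
#' @param path a tab-separated pattern file: one `id<TAB>expression` per
#'   line, `#` comments allowed.
#' @export
read_motifs <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  lapply(parts, function(p) {
    if (length(p) != 2) {
      stop("malformed motif line (need id<TAB>expression): ",
           paste(p, collapse = " "), call. = FALSE)
    }
    parse_motif(p[2], id = p[1])
  })
}

#' Scan peptides for motif matches
#'
#' Reports every substring match of every pattern, including overlapping
#' matches, with 0-based start offsets.
#'
#' @param x a [peptide_set()].
#' @param patterns a list of [parse_motif()] patterns (default: the bundled
#'   QSP motif set).
#' @return Data frame with columns `peptide_id`, `motif_id`, `start`
#'   (0-based) and `match`.
#' @export
scan_motifs <- function(x, patterns = qsp_motifs()) {
  stopifnot(inherits(x, "peptide_set"))
  if (inherits(patterns, "motif_pattern")) patterns <- list(patterns)
  res <- list()
  for (p in patterns) {
    lookahead <- paste0("(?=", p$regex, ")")
    for (i in seq_len(nrow(x))) {
      m <- gregexpr(lookahead, x$seq[[i]], perl = TRUE)[[1]]
      starts <- m[m > 0]
      if (length(starts) > 0) {
        res[[length(res) + 1]] <- data.frame(
          peptide_id = x$id[[i]], motif_id = p$id, start = starts - 1L,
          match = substring(x$seq[[i]], starts, starts + p$length - 1),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(res) == 0) {
    return(data.frame(peptide_id = character(0), motif_id = character(0),
                      start = integer(0), match = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Evaluate a motif set against positive and negative peptides
#'
#' A peptide counts as motif-positive when it has at least one match from
#' any pattern. TP = motif-positive peptides in `pos`, FP = motif-positive
#' in `neg`, FN = motif-negative in `pos`; `PPV = TP / (TP + FP)` and
#' `coverage = 100 * TP / (TP + FN)`. Per-pattern counts report both the
#' number of peptides hit and the total number of occurrences.
#'
#' @param pos,neg non-empty [peptide_set()]s.
#' @inheritParams scan_motifs
#' @return A list of class `motif_eval`: `tp, fp, fn, ppv, coverage,
#'   ppv_undefined, hits` (the positive-set scan), `per_pattern`.
#' @export
evaluate_motifs <- function(pos, neg, patterns = qsp_motifs()) {
  stopifnot(inherits(pos, "peptide_set"), inherits(neg, "peptide_set"),
            nrow(pos) > 0, nrow(neg) > 0)
  if (inherits(patterns, "motif_pattern")) patterns <- list(patterns)
  hits_pos <- scan_motifs(pos, patterns)
  hits_neg <- scan_motifs(neg, patterns)
  tp <- length(unique(hits_pos$peptide_id))
  fp <- length(unique(hits_neg$peptide_id))
  fn <- nrow(pos) - tp
  ppv_undefined <- (tp + fp) == 0
  ppv <- if (ppv_undefined) NA_real_ else tp / (tp + fp)
  per_pattern <- do.call(rbind, lapply(patterns, function(p) {
    h <- hits_pos[hits_pos$motif_id == p$id, , drop = FALSE]
    data.frame(motif_id = p$id, expr = p$expr,
               n_peptides = length(unique(h$peptide_id)),
               n_occurrences = nrow(h), stringsAsFactors = FALSE)
  }))
  structure(list(tp = tp, fp = fp, fn = fn, ppv = ppv,
                 coverage = 100 * tp / (tp + fn),
                 ppv_undefined = ppv_undefined,
                 hits = hits_pos, per_pattern = per_pattern),
            class = "motif_eval")
}

#' @export
print.motif_eval <- function(x, ...) {
  cat(sprintf("motif evaluation: TP %d, FP %d, FN %d\n", x$tp, x$fp, x$fn))
  if (x$ppv_undefined) {
    cat("PPV undefined (no motif-positive peptides)\n")
  } else {
    cat(sprintf("PPV %.3f, coverage %.2f%%\n", x$ppv, x$coverage))
  }
  invisible(x)
}
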