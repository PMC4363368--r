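test_that("bracket-class patterns parse to position lists", {
  p <- parse_motif("DPITRQW")
  expect_equal(p$length, 7)
  expect_true(all(lengths(p$positions) == 1))

  q <- parse_motif("[YP][NS][PTI][CF]GQ[YW][MF]")
  expect_equal(q$length, 8)
  expect_equal(lengths(q$positions), c(2, 2, 3, 2, 1, 1, 2, 2))
  expect_identical(q$positions[[3]], c("P", "T", "I"))

  expect_error(parse_motif("[]A"), "empty residue class")
  expect_error(parse_motif("[YP"), "unbalanced")
  expect_error(parse_motif("A]B"), "unbalanced")
  expect_error(parse_motif("AX[ZB]"), "invalid residue")
  expect_error(parse_motif(""), "non-empty")
})

test_that("the bundled motif set parses and literal motifs match themselves", {
  pats <- qsp_motifs()
  expect_length(pats, 9)
  for (p in pats) {
    # a sequence built from the first residue of every class must match
    self <- paste(vapply(p$positions, `[`, character(1), 1), collapse = "")
    hits <- scan_motifs(peptide_set("self", self), list(p))
    expect_equal(nrow(hits), 1)
    expect_equal(hits$start, 0)
    expect_identical(hits$match, self)
  }
  # the constructed instance of the bracket motif matches it
  hits <- scan_motifs(peptide_set("m2", "YNPCGQYM"), pats[[2]])
  expect_equal(nrow(hits), 1)
})

test_that("scanning reports all matches with 0-based offsets, overlaps included", {
  p9 <- parse_motif("DPITRQW", "Motif 9")
  x <- peptide_set(c("exact", "flanked", "short"),
                   c("DPITRQW", "ADPITRQWA", "DPI"))
  hits <- scan_motifs(x, list(p9))
  expect_equal(hits$start[hits$peptide_id == "exact"], 0)
  expect_equal(hits$start[hits$peptide_id == "flanked"], 1)
  expect_false("short" %in% hits$peptide_id)

  # overlapping matches are all reported
  pp <- parse_motif("AA")
  h <- scan_motifs(peptide_set("runs", "AAAA"), pp)
  expect_equal(h$start, 0:2)
})

test_that("scanning agrees with a naive sliding-window oracle", {
  pats <- list(parse_motif("[GA]W[CW]"), parse_motif("SS"))
  seqs <- random_peptides(40, c(3, 30), seed = 12)
  x <- as_set(seqs)
  hits <- scan_motifs(x, pats)
  for (p in pats) {
    for (i in seq_along(seqs)) {
      ch <- strsplit(seqs[i], "")[[1]]
      naive <- integer(0)
      if (length(ch) >= p$length) {
        for (s in 0:(length(ch) - p$length)) {
          ok <- all(vapply(seq_len(p$length), function(j) {
            ch[s + j] %in% p$positions[[j]]
          }, logical(1)))
          if (ok) naive <- c(naive, s)
        }
      }
      got <- hits$start[hits$peptide_id == x$id[i] & hits$motif_id == p$id]
      expect_identical(sort(got), naive)
    }
  }
})

test_that("motif evaluation computes peptide-level PPV and coverage", {
  pat <- list(parse_motif("WWW", "w3"))
  pos <- as_set(c("AWWWA", "WWWG", "GGGG", "KKKK"), "positive", "p")
  neg <- as_set(c("LLLL", "MMMM"), "negative", "n")
  ev <- evaluate_motifs(pos, neg, pat)
  expect_equal(ev$tp, 2)
  expect_equal(ev$fp, 0)
  expect_equal(ev$fn, 2)
  expect_equal(ev$ppv, 1)
  expect_equal(ev$coverage, 50)
  # PPV * (TP + FP) == TP identically
  expect_equal(ev$ppv * (ev$tp + ev$fp), ev$tp)

  # perfect motif: all positives hit, no negative
  ev2 <- evaluate_motifs(as_set(c("WWW", "AWWW"), "positive"),
                         as_set(c("GGG", "LLL"), "negative"), pat)
  expect_equal(ev2$ppv, 1)
  expect_equal(ev2$coverage, 100)

  # no hits anywhere: PPV undefined and flagged
  ev3 <- evaluate_motifs(as_set("GGG"), as_set("LLL"), pat)
  expect_true(ev3$ppv_undefined)

  # swapping pos/neg redefines TP/FP/FN as documented
  sw <- evaluate_motifs(neg, pos, pat)
  expect_equal(sw$tp, 0)
  expect_equal(sw$fp, 2)
  expect_equal(sw$fn, 2)
})

test_that("adding a pattern never decreases TP, FP or coverage", {
  pos <- as_set(random_peptides(30, c(5, 20), seed = 13), "positive", "p")
  neg <- as_set(random_peptides(30, c(5, 20), seed = 14), "negative", "n")
  p1 <- list(parse_motif("[AG][LV]"))
  p2 <- c(p1, list(parse_motif("S")))
  e1 <- evaluate_motifs(pos, neg, p1)
  e2 <- evaluate_motifs(pos, neg, p2)
  expect_gte(e2$tp, e1$tp)
  expect_gte(e2$fp, e1$fp)
  expect_gte(e2$coverage, e1$coverage)
})

test_that("per-pattern counts report both peptides and occurrences", {
  pat <- list(parse_motif("AA", "m"))
  ev <- evaluate_motifs(as_set(c("AAAA", "GAAG")), as_set("LLL"), pat)
  expect_equal(ev$per_pattern$n_peptides, 2)
  expect_equal(ev$per_pattern$n_occurrences, 4)  # 3 overlapping + 1
})

test_that("motif files round-trip through the reader", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "m1\tDPITRQW", "m2\t[AG]W"), f)
  pats <- read_motifs(f)
  expect_length(pats, 2)
  expect_identical(pats[[1]]$id, "m1")
  writeLines("broken line with no tab", f)
  expect_error(read_motifs(f), "malformed")
})
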