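test_that("amino-acid composition is a normalized, order-free 20-vector", {
  v <- encode_aac("AAAAA")
  expect_equal(unname(v[["A"]]), 1)
  expect_equal(sum(v), 1)
  expect_equal(unname(encode_aac("ACDE")[c("A", "C", "D", "E")]),
               rep(0.25, 4))
  for (s in random_peptides(20, c(5, 50), seed = 4)) {
    expect_equal(sum(encode_aac(s)), 1, tolerance = 1e-9)
    scr <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
    expect_identical(encode_aac(s), encode_aac(scr))
  }
  expect_error(encode_aac(""), "empty")
})

test_that("dipeptide composition counts overlapping pairs", {
  expect_equal(unname(encode_dpc("AAA")[["AA"]]), 1)
  v <- encode_dpc("ACAC")
  expect_equal(unname(v[["AC"]]), 2 / 3)
  expect_equal(unname(v[["CA"]]), 1 / 3)
  expect_equal(sum(v), 1)
  for (s in random_peptides(15, c(5, 50), seed = 5)) {
    expect_equal(sum(encode_dpc(s)), 1, tolerance = 1e-9)
  }
  expect_error(encode_dpc("A"), "length >= 2")
  # DPC is order-sensitive: witness
  expect_false(identical(encode_dpc("ACAC"), encode_dpc("AACC")))
})

test_that("terminal binary profiles are one-hot with overlap allowed", {
  v <- encode_binary("ACDEFGHIKL", 5, 5)
  expect_length(v, 200)
  expect_setequal(unique(v), c(0, 1))
  expect_equal(sum(v), 10)
  # block structure: N1 marks 'A' (slot 1), C5 marks 'G'... check two blocks
  expect_equal(unname(v[["N1.A"]]), 1)   # first residue A
  expect_equal(unname(v[["C1.G"]]), 1)   # 5th-from-last residue G
  expect_equal(unname(v[["C5.L"]]), 1)   # last residue L

  # full-overlap: length-5 peptide has identical N and C blocks
  w <- encode_binary("ACDEF", 5, 5)
  expect_identical(unname(w[1:100]), unname(w[101:200]))
  expect_error(encode_binary("ACDE", 5, 5), "shorter than")
})

test_that("physicochemical encoding averages AAindex values per residue", {
  tab <- aaindex_table()
  expect_equal(dim(tab), c(544, 20))
  ids <- c("NAGK730101", "WOEC730101")
  expect_true(all(qsp_physico_preset() %in% rownames(tab)))

  # homopolymer: each component equals the index's Gly value
  v <- encode_physico("GGGG", tab, ids)
  expect_equal(unname(v), unname(tab[ids, "G"]))
  # two-residue peptide: pairwise mean from direct table lookup
  v2 <- encode_physico("AC", tab, ids)
  expect_equal(unname(v2), unname((tab[ids, "A"] + tab[ids, "C"]) / 2))
  # order-free
  expect_equal(encode_physico("ACWY", tab, ids),
               encode_physico("YWCA", tab, ids))
  expect_error(encode_physico("AC", tab, "NOPE999999"), "unknown AAindex")
})

test_that("hybrid encodings concatenate components in order", {
  hyb2 <- encoding_spec("hybrid", components = list(
    encoding_spec("AAC"), encoding_spec("DPC")))
  expect_equal(hyb2$n_features, 420)
  hyb4 <- encoding_spec("hybrid", components = list(
    encoding_spec("AAC"), encoding_spec("DPC"), encoding_spec("N5C5Bin"),
    encoding_spec("Physico", aaindex_ids = qsp_physico_preset()[1:10])))
  expect_equal(hyb4$n_features, 630)

  x <- as_set(random_peptides(6, c(10, 20), seed = 6))
  tab <- aaindex_table()
  M <- encode(hyb4, x, tab)
  expect_equal(dim(M), c(6, 630))
  expect_identical(rownames(M), x$id)
  # first 20 columns are the AAC block
  expect_equal(unname(M[1, 1:20]), unname(encode_aac(x$seq[1])))

  # permutation-equivariance in peptide order
  perm <- c(3, 1, 6, 2, 5, 4)
  xp <- x[perm, ]
  class(xp) <- class(x)
  expect_equal(unname(encode(hyb4, xp, tab)), unname(M[perm, ]))

  # empty set gives a 0-row matrix with full width
  e <- x[0, ]
  class(e) <- class(x)
  expect_equal(dim(encode(hyb2, e)), c(0, 420))

  # encoding errors carry the peptide id
  short <- peptide_set("tiny", "ACD")
  expect_error(encode(encoding_spec("N5C5Bin"), short), "tiny")
})

test_that("index screening ranks a perfectly separating scale first", {
  # synthetic 3-scale table: SEPW separates W-rich from W-free peptides,
  # FLAT and FLATB are identical constants (tie broken lexically)
  tab <- rbind(SEPW = ifelse(AA20 == "W", 10, 0),
               FLATB = rep(1, 20), FLAT = rep(1, 20))
  colnames(tab) <- AA20
  x <- make_separable(40, seed = 11)
  top <- select_top_indices(x, tab, k = 3, folds = 5, seed = 2)
  expect_identical(top[1], "SEPW")
  expect_identical(top[2:3], c("FLAT", "FLATB"))
  expect_setequal(top, rownames(tab))
  expect_error(select_top_indices(as_set(c("AC", "GH"), "positive"), tab, 1),
               "both classes")
})

test_that("min-max scaling learned on training data maps into [0,1]", {
  X <- matrix(c(0, 5, 10, 2, 2, 2), ncol = 2)
  r <- scaling_ranges(X)
  S <- apply_scaling(X, r)
  expect_equal(S[, 1], c(0, 0.5, 1))
  expect_equal(S[, 2], c(0, 0, 0))  # constant column
  # new data outside the training range extrapolates linearly
  expect_equal(apply_scaling(matrix(c(20, 3), ncol = 2), r)[1, 1], 2)
})
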