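# Shared helpers: random peptide construction under a local seed.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_peptides <- function(n, len_range = c(5, 50), seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    L <- sample(len_range[1]:len_range[2], 1)
    paste(sample(AA20, L, replace = TRUE), collapse = "")
  }, character(1))
}

as_set <- function(seqs, label = "unknown", prefix = "t") {
  peptide_set(sprintf("%s%d", prefix, seq_along(seqs)), seqs, label)
}

# Small grid keeping SVM fits cheap in tests.
test_config <- function(folds = 10L, seed = 1L) {
  cv_config(folds = folds, seed = seed,
            c_grid = c(0.5, 2, 8), g_grid = c(0.02, 0.1, 0.5))
}
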