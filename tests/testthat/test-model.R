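test_that("classification metrics match hand-evaluated formulas", {
  perfect <- classification_metrics(10, 10, 0, 0)
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$mcc, 1)
  inverted <- classification_metrics(0, 0, 10, 10)
  expect_equal(inverted$accuracy, 0)
  expect_equal(inverted$mcc, -1)

  m <- classification_metrics(9, 8, 2, 1)
  expect_equal(m$accuracy, 85)
  expect_equal(m$sensitivity, 90)
  expect_equal(m$specificity, 80)
  expect_equal(m$mcc, 70 / sqrt(11 * 10 * 10 * 9))

  expect_warning(z <- classification_metrics(5, 0, 0, 5), "MCC undefined")
  expect_equal(z$mcc, 0)
  expect_true(z$mcc_undefined)
})

test_that("MCC equals the Pearson correlation of the binary vectors", {
  set.seed(21)
  for (i in 1:200) {
    cm <- rpois(4, 6) + 1  # all marginals positive
    m <- classification_metrics(cm[1], cm[2], cm[3], cm[4])
    truth <- rep(c(1, 0, 0, 1), cm)          # actual class
    pred <- rep(c(1, 0, 1, 0), cm)           # predicted class
    expect_equal(m$mcc, suppressWarnings(cor(truth, pred)))
    expect_equal(m$accuracy, 100 * mean(truth == pred))
    expect_equal(m$sensitivity, 100 * mean(pred[truth == 1]))
    expect_equal(m$specificity, 100 * mean(1 - pred[truth == 0]))
  }
})

test_that("metrics swap Sn and Sp under class relabelling", {
  m <- classification_metrics(9, 8, 2, 1)
  sw <- classification_metrics(8, 9, 1, 2)
  expect_equal(m$sensitivity, sw$specificity)
  expect_equal(m$specificity, sw$sensitivity)
  expect_equal(m$accuracy, sw$accuracy)
  expect_equal(m$mcc, sw$mcc)
})

test_that("AUC equals exhaustive pair counting, with ties at one half", {
  labels <- rep(c("positive", "negative"), each = 6)
  set.seed(22)
  for (i in 1:20) {
    scores <- sample(1:8, 12, replace = TRUE)  # forces ties
    pairs <- expand.grid(p = scores[1:6], n = scores[7:12])
    brute <- mean((pairs$p > pairs$n) + 0.5 * (pairs$p == pairs$n))
    expect_equal(auc_score(scores, labels), brute)
    # trapezoidal integration of the ROC curve agrees
    r <- roc_points(scores, labels)
    trap <- sum(diff(r$fpr) * (head(r$tpr, -1) + tail(r$tpr, -1)) / 2)
    expect_equal(trap, brute)
    # orientation antisymmetry
    expect_equal(auc_score(-scores, labels), 1 - brute)
  }
  expect_equal(auc_score(c(5, 6, 1, 2), c("positive", "positive", "negative", "negative")), 1)
  expect_equal(auc_score(rep(3, 10), rep(c("positive", "negative"), 5)), 0.5)
  expect_error(auc_score(1:3, rep("positive", 3)), "both classes")
})

test_that("AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  scores <- rnorm(40)
  labels <- rep(c("positive", "negative"), 20)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores, levels = c("negative", "positive"),
    direction = "<", quiet = TRUE)))
  expect_equal(auc_score(scores, labels), ref)
})

test_that("cross-validation separates a constructed fixture and not permuted labels", {
  sep <- make_separable(100, seed = 31)
  cv <- qsp_cv(sep, encoding_spec("AAC"), test_config(seed = 1))
  expect_gte(cv$metrics$accuracy, 95)
  expect_gte(cv$auc, 0.95)

  # label permutation collapses accuracy to chance (3 binomial SEs)
  perm <- sep
  perm$label <- withr::with_seed(32, sample(perm$label))
  cvp <- qsp_cv(perm, encoding_spec("AAC"),
                cv_config(folds = 10, seed = 1, c_grid = 2, g_grid = 0.1))
  se3 <- 3 * 100 * sqrt(0.25 / nrow(perm))
  expect_lt(abs(cvp$metrics$accuracy - 50), se3)
})

test_that("cross-validation is deterministic given the seed", {
  sep <- make_separable(40, seed = 33)
  a <- qsp_cv(sep, encoding_spec("AAC"), test_config(folds = 5, seed = 5))
  b <- qsp_cv(sep, encoding_spec("AAC"), test_config(folds = 5, seed = 5))
  expect_identical(a$scores, b$scores)
  expect_identical(a$metrics, b$metrics)
  expect_identical(a$cost, b$cost)
  c2 <- qsp_cv(sep, encoding_spec("AAC"), test_config(folds = 5, seed = 6))
  expect_false(identical(a$fold_id, c2$fold_id))
})

test_that("stratified folds balance classes", {
  y <- factor(rep(c("positive", "negative"), each = 50),
              c("positive", "negative"))
  f <- qsppred:::stratified_folds(y, 10, seed = 3)
  tab <- table(f, y)
  expect_true(all(tab == 5))
})

test_that("trained models predict, persist and respect the threshold", {
  sep <- make_separable(60, seed = 34)
  fit <- qsp_train(sep, encoding_spec("AAC"), test_config(folds = 5, seed = 2))
  pred <- predict(fit, sep)
  expect_true(all(pred$scorable))
  # almost all training positives score positive on the separable fixture
  acc <- mean(pred$label == sep$label)
  expect_gte(acc, 0.95)

  # persistence round trip is bit-identical
  f <- withr::local_tempfile(fileext = ".rds")
  qsp_save(fit, f)
  fit2 <- qsp_load(f)
  expect_identical(predict(fit2, sep)$decision, pred$decision)

  # threshold monotonicity: +Inf -> none positive, -Inf -> all positive
  hi <- fit; hi$threshold <- Inf
  lo <- fit; lo$threshold <- -Inf
  expect_true(all(predict(hi, sep)$label == "negative"))
  expect_true(all(predict(lo, sep)$label == "positive"))

  # empty set in, empty report out
  e <- sep[0, ]; class(e) <- class(sep)
  expect_equal(nrow(predict(fit, e)), 0)
})

test_that("raising the threshold trades sensitivity for specificity monotonically", {
  set.seed(35)
  scores <- rnorm(100)
  y <- factor(rep(c("positive", "negative"), 50), c("positive", "negative"))
  prev <- NULL
  for (t in sort(scores)) {
    cm <- qsppred:::confusion_at(scores, y, t)
    m <- suppressWarnings(classification_metrics(cm[1], cm[2], cm[3], cm[4]))
    if (!is.null(prev)) {
      expect_lte(m$sensitivity, prev$sensitivity)
      expect_gte(m$specificity, prev$specificity)
    }
    prev <- m
  }
})

test_that("unscorable peptides are reported with a reason, never dropped", {
  sep <- make_separable(40, seed = 36)
  fit <- qsp_train(sep, encoding_spec("N5C5Bin"),
                   test_config(folds = 5, seed = 2))
  mixed <- peptide_set(c("long", "short"), c("WWWWWWWWWWAC", "ACD"))
  pred <- predict(fit, mixed)
  expect_equal(nrow(pred), 2)
  expect_true(pred$scorable[1])
  expect_false(pred$scorable[2])
  expect_match(pred$reason[2], "shorter")
  expect_true(is.na(pred$decision[2]))
})

test_that("threshold optimization finds the accuracy-maximizing cut", {
  scores <- c(-2, -1, 1, 2, 3)
  labels <- c("negative", "negative", "positive", "positive", "positive")
  t <- optimize_threshold(scores, labels)
  expect_equal(mean((scores >= t) == (labels == "positive")), 1)
})
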