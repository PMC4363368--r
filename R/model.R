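# RBF-kernel SVM classifier: grid-searched, stratified k-fold
# cross-validation, threshold-dependent metrics (Sn/Sp/Acc/MCC) and
# threshold-independent ROC/AUC, plus final model fitting and prediction.

#' Cross-validation configuration
#'
#' @param folds number of cross-validation folds (default 10).
#' @param seed integer seed controlling fold assignment.
#' @param c_grid SVM cost values searched (default `2^seq(-5, 15, 2)`).
#' @param g_grid RBF gamma values searched (default `2^seq(-15, 3, 2)`).
#' @param stratified keep class proportions equal across folds.
#' @return A list of class `cv_config`.
#' @export
cv_config <- function(folds = 10L, seed = 1L,
                      c_grid = 2^seq(-5, 15, 2),
                      g_grid = 2^seq(-15, 3, 2),
                      stratified = TRUE) {
  stopifnot(folds >= 2, length(c_grid) > 0, length(g_grid) > 0,
            all(c_grid > 0), all(g_grid > 0))
  structure(list(folds = as.integer(folds), seed = as.integer(seed),
                 c_grid = c_grid, g_grid = g_grid,
                 stratified = isTRUE(stratified)),
            class = "cv_config")
}

# Seeded (optionally stratified) fold assignment; returns an integer
# vector of fold ids in 1..folds.
stratified_folds <- function(y, folds, seed, stratified = TRUE) {
  n <- length(y)
  with_seed(seed, {
    fold_id <- integer(n)
    if (stratified) {
      for (lev in levels(y)) {
        i <- which(y == lev)
        fold_id[i] <- sample(rep_len(seq_len(folds), length(i)))
      }
    } else {
      fold_id <- sample(rep_len(seq_len(folds), n))
    }
    fold_id
  })
}

#' Threshold-dependent classification metrics
#'
#' Sensitivity `100 * TP / (TP + FN)`, specificity `100 * TN / (TN + FP)`,
#' accuracy `100 * (TP + TN) / total`, and the Matthews correlation
#' coefficient `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))` on
#' `[-1, 1]`. When an MCC marginal is zero the coefficient is undefined; it
#' is reported as 0 with `mcc_undefined = TRUE` so batch cross-validation
#' runs survive degenerate folds.
#'
#' @param tp,tn,fp,fn confusion counts (true/false positive/negative).
#' @return A list of class `qsp_metrics`: `tp, tn, fp, fn, sensitivity,
#'   specificity, accuracy, mcc, mcc_undefined`.
#' @examples
#' classification_metrics(tp = 9, tn = 8, fp = 2, fn = 1)
#' @export
classification_metrics <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  total <- tp + tn + fp + fn
  sn <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  acc <- 100 * (tp + tn) / total
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  undefined <- denom == 0
  mcc <- if (undefined) {
    warning("MCC undefined (zero marginal); reporting 0", call. = FALSE)
    0
  } else {
    (tp * tn - fp * fn) / sqrt(denom)
  }
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 sensitivity = sn, specificity = sp, accuracy = acc,
                 mcc = mcc, mcc_undefined = undefined),
            class = "qsp_metrics")
}

#' @export
print.qsp_metrics <- function(x, ...) {
  cat(sprintf("TP %d  TN %d  FP %d  FN %d\n", x$tp, x$tn, x$fp, x$fn))
  cat(sprintf("Sn %.2f%%  Sp %.2f%%  Acc %.2f%%  MCC %.3f%s\n",
              x$sensitivity, x$specificity, x$accuracy, x$mcc,
              if (x$mcc_undefined) " (undefined, zero marginal)" else ""))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney pair statistic: the fraction of
#' (positive, negative) pairs in which the positive scores higher, with
#' ties counting one half. This equals trapezoidal integration of the ROC
#' curve.
#'
#' @param scores numeric decision values, higher meaning more positive.
#' @param labels class labels (`"positive"` / `"negative"`, or a factor
#'   whose first level is the positive class).
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  y <- as_binary_labels(labels)
  np <- sum(y); nn <- sum(!y)
  if (np == 0 || nn == 0) {
    stop("AUC requires both classes present", call. = FALSE)
  }
  r <- rank(scores)  # midranks handle ties as 1/2
  (sum(r[y]) - np * (np + 1) / 2) / (np * nn)
}

#' ROC curve points
#'
#' Sensitivity / 1-specificity pairs at every distinct score threshold.
#'
#' @inheritParams auc_score
#' @return Data frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  y <- as_binary_labels(labels)
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]; s <- scores[ord]
  keep <- c(diff(s) != 0, TRUE)  # last point of each tie group
  tpr <- cumsum(y) / sum(y)
  fpr <- cumsum(!y) / sum(!y)
  data.frame(threshold = c(Inf, s[keep]),
             fpr = c(0, fpr[keep]),
             tpr = c(0, tpr[keep]))
}

as_binary_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.logical(labels)) return(labels)
  if (!all(labels %in% c("positive", "negative"))) {
    stop("labels must be 'positive'/'negative'", call. = FALSE)
  }
  labels == "positive"
}

# Decision values oriented so that >= 0 means the positive class,
# regardless of libsvm's internal level ordering.
oriented_decision <- function(fit, newx) {
  dv <- attr(stats::predict(fit, newx, decision.values = TRUE),
             "decision.values")
  flip <- if (grepl("^positive/", colnames(dv)[1])) 1 else -1
  as.numeric(dv[, 1]) * flip
}

#' Cross-validate an SVM model over a feature encoding
#'
#' Encodes the labelled set, partitions it into seeded stratified folds,
#' and for every (cost, gamma) pair on the grid trains on the complement of
#' each fold and scores the held-out fold; min-max feature scaling is
#' learned on the training folds only. The pair maximizing pooled CV
#' accuracy is selected (ties: higher MCC, then smaller cost, then smaller
#' gamma), and its pooled held-out decision values yield the confusion
#' counts at threshold 0, the metrics and the ROC/AUC.
#'
#' @param x a labelled [peptide_set()] with both classes.
#' @param spec an [encoding_spec()].
#' @param config a [cv_config()].
#' @param table AAindex matrix, if the encoding needs one.
#' @param fold_id optional integer vector assigning each peptide to a fold,
#'   overriding the seeded stratified partition. Use this for grouped
#'   cross-validation when peptides are derived from one another (e.g. a
#'   scramble and its parent share identical composition features and must
#'   share a fold, or the held-out twin's opposite label leaks into
#'   training).
#' @return An object of class `qsp_cv`: `metrics`, `auc`, `roc`, `cost`,
#'   `gamma`, `fold_id`, `scores`, `labels`, `per_fold` accuracy, `grid`.
#' @export
qsp_cv <- function(x, spec, config = cv_config(), table = NULL,
                   fold_id = NULL) {
  stopifnot(inherits(x, "peptide_set"), inherits(spec, "encoding_spec"),
            inherits(config, "cv_config"))
  y <- peptide_labels(x)
  if (min(table(y)) < config$folds) {
    stop("each class needs at least as many peptides as folds", call. = FALSE)
  }
  X <- encode(spec, x, table)
  if (is.null(fold_id)) {
    fold_id <- stratified_folds(y, config$folds, config$seed,
                                config$stratified)
  } else {
    stopifnot(length(fold_id) == nrow(x))
    fold_id <- as.integer(fold_id)
  }

  grid <- expand.grid(cost = config$c_grid, gamma = config$g_grid,
                      KEEP.OUT.ATTRS = FALSE)
  results <- lapply(seq_len(nrow(grid)), function(g) {
    cv_scores(X, y, fold_id, grid$cost[g], grid$gamma[g])
  })
  stats_tab <- t(vapply(results, function(sc) {
    cm <- confusion_at(sc, y, 0)
    m <- suppressWarnings(classification_metrics(cm[1], cm[2], cm[3], cm[4]))
    c(accuracy = m$accuracy, mcc = m$mcc)
  }, c(accuracy = 0, mcc = 0)))
  grid$accuracy <- stats_tab[, "accuracy"]
  grid$mcc <- stats_tab[, "mcc"]
  best <- order(-grid$accuracy, -grid$mcc, grid$cost, grid$gamma)[1]

  scores <- results[[best]]
  cm <- confusion_at(scores, y, 0)
  metrics <- suppressWarnings(classification_metrics(cm[1], cm[2], cm[3], cm[4]))
  per_fold <- vapply(sort(unique(fold_id)), function(f) {
    i <- fold_id == f
    mean((scores[i] >= 0) == (y[i] == "positive")) * 100
  }, numeric(1))

  structure(list(
    spec = spec, config = config, cost = grid$cost[best],
    gamma = grid$gamma[best], metrics = metrics,
    auc = auc_score(scores, y), roc = roc_points(scores, y),
    scores = stats::setNames(scores, x$id), labels = y,
    fold_id = fold_id, per_fold = per_fold, grid = grid),
    class = "qsp_cv")
}

# Pooled held-out decision values for one (cost, gamma) pair.
cv_scores <- function(X, y, fold_id, cost, gamma) {
  scores <- numeric(length(y))
  for (f in sort(unique(fold_id))) {
    tr <- fold_id != f
    rng <- scaling_ranges(X[tr, , drop = FALSE])
    fit <- e1071::svm(x = apply_scaling(X[tr, , drop = FALSE], rng),
                      y = y[tr], kernel = "radial", cost = cost,
                      gamma = gamma, scale = FALSE)
    scores[!tr] <- oriented_decision(
      fit, apply_scaling(X[!tr, , drop = FALSE], rng))
  }
  scores
}

confusion_at <- function(scores, y, threshold) {
  pos <- y == "positive"
  pred <- scores >= threshold
  c(tp = sum(pred & pos), tn = sum(!pred & !pos),
    fp = sum(pred & !pos), fn = sum(!pred & pos))
}

#' @export
print.qsp_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation, %s encoding (%d features)\n",
              x$config$folds, scheme_label(x$spec), x$spec$n_features))
  cat(sprintf("selected cost = %g, gamma = %g\n", x$cost, x$gamma))
  print(x$metrics)
  cat(sprintf("AUC %.3f\n", x$auc))
  invisible(x)
}

#' @export
plot.qsp_cv <- function(x, ...) {
  plot(x$roc$fpr, x$roc$tpr, type = "l", xlab = "1 - specificity",
       ylab = "Sensitivity", main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

scheme_label <- function(spec) {
  if (spec$scheme == "hybrid") {
    paste(vapply(spec$components, scheme_label, character(1)), collapse = "+")
  } else spec$scheme
}

#' Train a quorum-sensing-peptide SVM classifier
#'
#' The main fitting function. Runs [qsp_cv()] on the labelled training set
#' to select the RBF cost and gamma by grid search, then refits on the full
#' set at the selected pair, storing the encoding spec, min-max scaling
#' ranges learned on the full training set, and the decision threshold
#' (default 0: decision values at or above it are labelled positive).
#'
#' @inheritParams qsp_cv
#' @param threshold decision threshold on the SVM decision value.
#' @return An object of class `qsp_model` with `print`, `summary`,
#'   [predict.qsp_model()] and `plot` methods.
#' @examples
#' \donttest{
#' sep <- make_separable(60, seed = 1)
#' fit <- qsp_train(sep, encoding_spec("AAC"),
#'                  cv_config(folds = 5, c_grid = c(1, 8), g_grid = c(0.05, 0.5)))
#' predict(fit, sep[1:3, ])
#' }
#' @export
qsp_train <- function(x, spec, config = cv_config(), table = NULL,
                      threshold = 0) {
  if (uses_physico(spec) && is.null(table)) table <- aaindex_table()
  cv <- qsp_cv(x, spec, config, table)
  y <- peptide_labels(x)
  X <- encode(spec, x, table)
  rng <- scaling_ranges(X)
  fit <- e1071::svm(x = apply_scaling(X, rng), y = y, kernel = "radial",
                    cost = cv$cost, gamma = cv$gamma, scale = FALSE)
  structure(list(
    spec = spec, config = cv$config, cost = cv$cost, gamma = cv$gamma,
    svm = fit, scaling = rng, threshold = threshold, cv = cv,
    table = if (uses_physico(spec)) table else NULL,
    n_train = nrow(x), call = match.call()),
    class = "qsp_model")
}

#' Predict QSP status for new peptides
#'
#' Scores each peptide with the trained SVM; the label is `"positive"` when
#' the decision value is at or above the model's threshold. Peptides that
#' fail the encoding's length preconditions are reported as unscorable with
#' the reason, never silently dropped.
#'
#' @param object a [qsp_train()] model.
#' @param newdata a [peptide_set()].
#' @param ... unused.
#' @return Data frame with columns `id`, `decision`, `label`, `scorable`,
#'   `reason`.
#' @export
predict.qsp_model <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "peptide_set"))
  n <- nrow(newdata)
  out <- data.frame(id = newdata$id, decision = rep(NA_real_, n),
                    label = rep(NA_character_, n),
                    scorable = rep(TRUE, n), reason = rep("", n),
                    stringsAsFactors = FALSE)
  if (n == 0) return(out)
  feats <- vector("list", n)
  for (i in seq_len(n)) {
    feats[[i]] <- tryCatch(
      encode_one(object$spec, newdata$seq[[i]], object$table),
      error = function(e) conditionMessage(e))
    if (is.character(feats[[i]])) {
      out$scorable[i] <- FALSE
      out$reason[i] <- feats[[i]]
    }
  }
  ok <- out$scorable
  if (any(ok)) {
    X <- do.call(rbind, feats[ok])
    dv <- oriented_decision(object$svm, apply_scaling(X, object$scaling))
    out$decision[ok] <- dv
    out$label[ok] <- ifelse(dv >= object$threshold, "positive", "negative")
  }
  out
}

#' @export
print.qsp_model <- function(x, ...) {
  cat(sprintf("qsp_model: RBF SVM on %s features (%d-dim)\n",
              scheme_label(x$spec), x$spec$n_features))
  cat(sprintf("  trained on %d peptides; cost = %g, gamma = %g, threshold = %g\n",
              x$n_train, x$cost, x$gamma, x$threshold))
  cat(sprintf("  CV accuracy %.2f%%, MCC %.3f, AUC %.3f\n",
              x$cv$metrics$accuracy, x$cv$metrics$mcc, x$cv$auc))
  invisible(x)
}

#' @export
summary.qsp_model <- function(object, ...) {
  print(object)
  cat("\nCross-validation detail:\n")
  print(object$cv$metrics)
  cat(sprintf("per-fold accuracy: %s\n",
              paste(sprintf("%.1f", object$cv$per_fold), collapse = " ")))
  invisible(object)
}

#' @export
plot.qsp_model <- function(x, ...) plot(x$cv, ...)

#' Persist and restore a trained model
#'
#' The archive stores the encoding spec, kernel parameters, support data,
#' scaling ranges and threshold; restored models reproduce pre-save decision
#' values bit-identically.
#'
#' @param model a `qsp_model`.
#' @param path file path for the archive.
#' @return `qsp_save` returns `path` invisibly; `qsp_load` the model.
#' @export
qsp_save <- function(model, path) {
  stopifnot(inherits(model, "qsp_model"))
  saveRDS(list(format = "qsp_model", version = 1L, model = model), path)
  invisible(path)
}

#' @rdname qsp_save
#' @export
qsp_load <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "qsp_model")) {
    stop("not a qsp_model archive: ", path, call. = FALSE)
  }
  obj$model
}

#' Choose the accuracy-maximizing decision threshold
#'
#' Scans the midpoints between consecutive distinct scores and returns the
#' threshold maximizing accuracy (ties: threshold closest to 0).
#'
#' @inheritParams auc_score
#' @return A numeric threshold.
#' @export
optimize_threshold <- function(scores, labels) {
  y <- as_binary_labels(labels)
  s <- sort(unique(scores))
  cand <- c(s[1] - 1, (s[-1] + s[-length(s)]) / 2, s[length(s)] + 1, 0)
  acc <- vapply(cand, function(t) mean((scores >= t) == y), numeric(1))
  best <- acc == max(acc)
  cand[best][which.min(abs(cand[best]))]
}
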