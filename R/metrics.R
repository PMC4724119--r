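#' Confusion matrix, optionally imbalance-weighted
#'
#' Counts TP (true TSS predicted TSS), TN (true FSS predicted FSS), FN and
#' FP. When weights `(w1, w2)` are supplied — typically from
#' [class_weights()] on an imbalanced test set — TP and FN are scaled by w1
#' and FP and TN by w2, so metrics computed from the weighted matrix treat
#' the classes evenly.
#'
#' @param true_labels,pred_labels Aligned label vectors over TSS/FSS.
#' @param weights Optional numeric `c(w1, w2)`.
#' @return A `confusion` list: `tp`, `fp`, `tn`, `fn`, `weighted`, `w1`, `w2`.
#' @export
confusion <- function(true_labels, pred_labels, weights = NULL) {
  y <- as_class_factor(true_labels)
  p <- as_class_factor(pred_labels)
  if (length(y) != length(p)) stop("label vectors must align")
  tp <- sum(y == "TSS" & p == "TSS")
  fn <- sum(y == "TSS" & p == "FSS")
  fp <- sum(y == "FSS" & p == "TSS")
  tn <- sum(y == "FSS" & p == "FSS")
  w1 <- 1; w2 <- 1; weighted <- FALSE
  if (!is.null(weights)) {
    stopifnot(length(weights) == 2, all(weights >= 0))
    w1 <- weights[[1]]; w2 <- weights[[2]]; weighted <- TRUE
    tp <- tp * w1; fn <- fn * w1
    fp <- fp * w2; tn <- tn * w2
  }
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 weighted = weighted, w1 = w1, w2 = w2),
            class = "confusion")
}

#' Imbalance weights from test-set class sizes
#'
#' `w1` is the FSS share of the test set (applied to TP and FN) and `w2`
#' the TSS share (applied to FP and TN); they sum to 1.
#'
#' @param n_tss,n_fss Class counts in the test set.
#' @return Named numeric `c(w1, w2)`.
#' @export
class_weights <- function(n_tss, n_fss) {
  total <- n_tss + n_fss
  if (total <= 0) stop("at least one class must be non-empty")
  c(w1 = n_fss / total, w2 = n_tss / total)
}

#' Performance metrics of a confusion matrix
#'
#' The seven confusion-matrix metrics used throughout the evaluation:
#' sensitivity (TPR), specificity (TNR), precision,
#' `F(alpha) = (1+alpha)*recall*precision / (alpha*recall + precision)`,
#' `F(beta) = (1+beta^2)*recall*precision / (beta^2*recall + precision)`,
#' weighted accuracy `WA = (TPR+TNR)/2`, `G-mean = sqrt(TPR*TNR)` and the
#' Matthews correlation coefficient. A zero MCC denominator yields 0 with a
#' warning (degenerate predictions), and precision/F default to 0 when no
#' instance is predicted positive, so extreme-cutoff sweeps do not abort.
#'
#' @param cm A [confusion()] object.
#' @param alpha,beta F-measure parameters (defaults 1 and 2, the values the
#'   benchmark tables report).
#' @return One-row data frame: tpr, tnr, precision, f_alpha, f_beta, wa,
#'   g_mean, mcc (plus alpha, beta).
#' @export
compute_metrics <- function(cm, alpha = 1, beta = 2) {
  tp <- cm$tp; fp <- cm$fp; tn <- cm$tn; fn <- cm$fn
  if (tp + fn == 0 || tn + fp == 0) {
    stop("undefined metric: a class is empty")
  }
  tpr <- tp / (tp + fn)
  tnr <- tn / (tn + fp)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  fm <- function(w) {
    den <- w * tpr + precision
    if (den == 0) 0 else (1 + w) * tpr * precision / den
  }
  f_alpha <- fm(alpha)
  f_beta <- fm(beta^2)
  wa <- (tpr + tnr) / 2
  g_mean <- sqrt(tpr * tnr)
  mcc_den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (mcc_den == 0) {
    warning("MCC denominator zero; reporting 0")
    0
  } else {
    (tp * tn - fp * fn) / mcc_den
  }
  data.frame(tpr = tpr, tnr = tnr, precision = precision,
             f_alpha = f_alpha, f_beta = f_beta, wa = wa, g_mean = g_mean,
             mcc = mcc, alpha = alpha, beta = beta)
}

#' Expected out-of-bag fraction
#'
#' The expected fraction of instances left out of a bootstrap sample of
#' size n: `(1 - 1/n)^n`, which tends to `1/e` (about 36.8%) for large n.
#'
#' @param n Sample size (at least 1).
#' @return The fraction in `[0, 1)`.
#' @export
oob_fraction <- function(n) {
  if (n < 1) stop("n must be at least 1")
  (1 - 1 / n)^n
}

#' Mann-Whitney comparison of fold-wise values
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) p-value comparing two sets of
#' fold-wise metric values: exact for small tie-free samples (n, m <= 50 in
#' the underlying routine, covering the 10-fold protocol), normal
#' approximation with tie correction otherwise.
#'
#' @param a,b Numeric vectors of per-fold values (each length >= 2).
#' @return Two-sided p-value in `(0, 1]`.
#' @export
mann_whitney_compare <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("need at least 2 values per sample")
  p <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))$p.value
  # a fully tied comparison (z = 0 with zero variance) is no evidence at all
  if (is.nan(p)) p <- 1
  min(p, 1)
}

#' Leakage-free k-fold cross-validation of the full pipeline
#'
#' For each fold: association score matrices for TSS and FSS and their
#' difference matrix are built from the training windows only; training and
#' test windows are encoded through that matrix; the classifier is trained
#' and evaluated on the held-out fold. Metrics may be computed from the
#' imbalance-weighted confusion matrix of each test fold.
#'
#' @param tss,fss `splice_windows` of true and false sites (equal lengths).
#' @param procedure Encoding procedure `"P-1"`, `"P-2"` or `"P-3"`.
#' @param classifier List with `name` (`"rf"` or a [train_baseline()] name)
#'   and optional parameters: for `"rf"` the [forest_config()] arguments
#'   `mtry`, `ntree`, `cutoffs`; otherwise the adapter's `params`.
#' @param k Number of folds (default 10).
#' @param seed Integer seed driving fold assignment and classifier training.
#' @param pseudo Pseudo count for the score matrices.
#' @param weighted Compute metrics from the w1/w2-weighted confusion matrix
#'   (use for imbalanced test folds).
#' @param alpha,beta F-measure parameters.
#' @return A `cv_result`: `per_fold` (k-row data frame of metrics),
#'   `summary` (metric, mean, se with se = sd/sqrt(k)), `procedure`,
#'   `classifier`, `k`, and per-fold `margins`.
#' @export
cross_validate <- function(tss, fss, procedure = "P-1",
                           classifier = list(name = "rf"), k = 10, seed = 1,
                           pseudo = 0.001, weighted = FALSE,
                           alpha = 1, beta = 2) {
  if (nrow(tss) < k || nrow(fss) < k) stop("each class needs at least k windows")
  folds <- make_folds(nrow(tss), nrow(fss), k = k, seed = derive_seed(seed, 0))
  per_fold <- vector("list", k)
  margins <- vector("list", k)
  for (f in seq_len(k)) {
    res <- tryCatch(
      run_fold(tss, fss, folds, f, procedure, classifier,
               seed = derive_seed(seed, f), pseudo = pseudo,
               weighted = weighted, alpha = alpha, beta = beta),
      error = function(e) stop("fold ", f, ": ", conditionMessage(e))
    )
    per_fold[[f]] <- res$metrics
    margins[[f]] <- res$margins
  }
  per_fold <- do.call(rbind, per_fold)
  per_fold$fold <- seq_len(k)
  metric_cols <- c("tpr", "tnr", "precision", "f_alpha", "f_beta", "wa",
                   "g_mean", "mcc")
  summary <- data.frame(
    metric = metric_cols,
    mean = vapply(metric_cols, function(m) mean(per_fold[[m]]), numeric(1)),
    se = vapply(metric_cols, function(m) stats::sd(per_fold[[m]]) / sqrt(k),
                numeric(1)),
    row.names = NULL
  )
  structure(list(per_fold = per_fold, summary = summary,
                 procedure = procedure, classifier = classifier$name, k = k,
                 margins = margins),
            class = "cv_result")
}

run_fold <- function(tss, fss, folds, f, procedure, classifier, seed, pseudo,
                     weighted, alpha, beta) {
  tr_tss <- tss[folds$pos != f, , drop = FALSE]
  tr_fss <- fss[folds$neg != f, , drop = FALSE]
  te_tss <- tss[folds$pos == f, , drop = FALSE]
  te_fss <- fss[folds$neg == f, , drop = FALSE]

  diff <- fold_difference_matrix(tr_tss, tr_fss, procedure, pseudo)

  lab <- function(w, l) { w$label <- l; w }
  train <- rbind_windows(lab(tr_tss, "TSS"), lab(tr_fss, "FSS"))
  test <- rbind_windows(lab(te_tss, "TSS"), lab(te_fss, "FSS"))
  train_enc <- encode_dataset(train, diff)
  test_enc <- encode_dataset(test, diff)

  name <- classifier$name %||% "rf"
  if (name == "rf") {
    cfg <- forest_config(mtry = classifier$mtry,
                         ntree = classifier$ntree %||% 1000,
                         cutoffs = classifier$cutoffs %||% c(TSS = 0.5, FSS = 0.5),
                         seed = seed)
    model <- train_forest(train_enc, cfg)
    cutoffs <- cfg$cutoffs
  } else {
    params <- classifier$params %||% classifier[setdiff(names(classifier), "name")]
    params$seed <- params$seed %||% seed
    model <- train_baseline(name, train_enc, params)
    cutoffs <- classifier$cutoffs %||% c(TSS = 0.5, FSS = 0.5)
  }
  probs <- predict_prob(model, test_enc)
  pred <- classify_with_cutoff(probs, cutoffs)
  w <- if (weighted) class_weights(nrow(te_tss), nrow(te_fss)) else NULL
  cm <- confusion(test_enc$labels, pred, weights = w)
  list(metrics = compute_metrics(cm, alpha = alpha, beta = beta),
       margins = margin_values(probs, test_enc$labels))
}

# Score-matrix construction for one training split; exported workhorse so
# callers can verify leakage-freeness directly.
#' Difference matrix from a training split
#'
#' Builds the TSS and FSS association score matrices and their difference
#' from the supplied (training) windows only.
#'
#' @param tr_tss,tr_fss Training windows per class.
#' @inheritParams cross_validate
#' @return A `diff_matrix`.
#' @export
fold_difference_matrix <- function(tr_tss, tr_fss, procedure = "P-1",
                                   pseudo = 0.001) {
  score <- function(w) {
    association_scores(count_adjacent_dinucleotides(w), compute_pwm(w),
                       procedure = procedure, pseudo = pseudo)
  }
  build_difference_matrix(score(tr_tss), score(tr_fss))
}

#' @export
print.cv_result <- function(x, ...) {
  cat(x$k, "-fold cross-validation, procedure ", x$procedure,
      ", classifier ", x$classifier, "\n", sep = "")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-9s %.4f (%.4f)\n", s$metric[i], s$mean[i], s$se[i]))
  }
  invisible(x)
}

#' Export a cross-validation result as CSV
#'
#' Writes a tidy long table (fold, procedure, classifier, metric, value)
#' and a wide summary with mean and standard-error columns.
#'
#' @param cv A `cv_result`.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Paths of the two files, invisibly.
#' @export
write_cv_result <- function(cv, dir, prefix = "cv") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  metric_cols <- c("tpr", "tnr", "precision", "f_alpha", "f_beta", "wa",
                   "g_mean", "mcc")
  long <- do.call(rbind, lapply(metric_cols, function(m) {
    data.frame(fold = cv$per_fold$fold, procedure = cv$procedure,
               classifier = cv$classifier, metric = m,
               value = cv$per_fold[[m]])
  }))
  p1 <- file.path(dir, paste0(prefix, "_folds.csv"))
  p2 <- file.path(dir, paste0(prefix, "_summary.csv"))
  utils::write.csv(long, p1, row.names = FALSE)
  wide <- cv$summary
  wide$se_label <- sprintf("(%.4f)", wide$se)
  utils::write.csv(wide, p2, row.names = FALSE)
  invisible(c(p1, p2))
}
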