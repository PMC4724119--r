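test_that("confusion counts and imbalance weighting follow the stated rule", {
  truths <- c("TSS", "TSS", "TSS", "FSS", "FSS", "FSS")
  preds <- c("TSS", "TSS", "FSS", "FSS", "FSS", "FSS")
  cm <- confusion(truths, preds)
  expect_equal(c(cm$tp, cm$fn, cm$tn, cm$fp), c(2, 1, 3, 0))
  expect_false(cm$weighted)

  perfect <- confusion(truths, truths)
  expect_equal(c(perfect$fn, perfect$fp), c(0, 0))

  wcm <- confusion(truths, preds, weights = c(0.95, 0.05))
  expect_equal(c(wcm$tp, wcm$fn, wcm$fp, wcm$tn), c(1.9, 0.95, 0, 0.15))
  expect_error(confusion(c("TSS", "??"), c("TSS", "TSS")), "unknown label")
})

test_that("class weights are the opposite-class shares", {
  expect_equal(class_weights(5, 95), c(w1 = 0.95, w2 = 0.05))
  expect_equal(class_weights(50, 50), c(w1 = 0.5, w2 = 0.5))
  expect_equal(class_weights(1, 3), c(w1 = 0.75, w2 = 0.25))
  expect_error(class_weights(0, 0), "non-empty")
})

test_that("the seven metrics match hand arithmetic on cm(2,1,3,0)", {
  cm <- confusion(rep(c("TSS", "FSS"), c(3, 3)),
                  c("TSS", "TSS", "FSS", "FSS", "FSS", "FSS"))
  m <- compute_metrics(cm, alpha = 1, beta = 2)
  expect_equal(m$tpr, 2 / 3, tolerance = 1e-12)
  expect_equal(m$tnr, 1, tolerance = 1e-12)
  expect_equal(m$precision, 1, tolerance = 1e-12)
  expect_equal(m$f_alpha, 0.8, tolerance = 1e-12)
  expect_equal(m$f_beta, 10 / 11, tolerance = 1e-12)
  expect_equal(m$wa, 5 / 6, tolerance = 1e-12)
  expect_equal(m$g_mean, sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(m$mcc, 6 / sqrt(72), tolerance = 1e-12)
})

random_cm <- function(seed) {
  set.seed(seed)
  structure(list(tp = sample(1:50, 1), fp = sample(1:50, 1),
                 tn = sample(1:50, 1), fn = sample(1:50, 1),
                 weighted = FALSE, w1 = 1, w2 = 1), class = "confusion")
}

test_that("metric identities hold on randomized confusion matrices", {
  for (seed in 1:20) {
    cm <- random_cm(seed)
    m <- compute_metrics(cm)
    expect_equal(m$wa, (m$tpr + m$tnr) / 2, tolerance = 1e-12)
    expect_equal(m$g_mean, sqrt(m$tpr * m$tnr), tolerance = 1e-12)
    # F at beta = 1 is the same function as F at alpha = 1
    m11 <- compute_metrics(cm, alpha = 1, beta = 1)
    expect_equal(m11$f_beta, m11$f_alpha, tolerance = 1e-12)
    # weighting scales TP/FN together, so TPR is weight-invariant
    w <- class_weights(sample(1:20, 1), sample(1:20, 1))
    cmw <- cm
    cmw$tp <- cm$tp * w[1]; cmw$fn <- cm$fn * w[1]
    cmw$fp <- cm$fp * w[2]; cmw$tn <- cm$tn * w[2]
    expect_equal(compute_metrics(cmw)$tpr, m$tpr, tolerance = 1e-12)
    expect_equal(compute_metrics(cmw)$tnr, m$tnr, tolerance = 1e-12)
    # MCC is symmetric under a simultaneous class swap
    swapped <- cm
    swapped$tp <- cm$tn; swapped$tn <- cm$tp
    swapped$fp <- cm$fn; swapped$fn <- cm$fp
    expect_equal(compute_metrics(swapped)$mcc, m$mcc, tolerance = 1e-12)
  }
})

test_that("extreme confusion matrices hit the documented edge behaviour", {
  perfect <- structure(list(tp = 10, fp = 0, tn = 10, fn = 0,
                            weighted = FALSE, w1 = 1, w2 = 1),
                       class = "confusion")
  expect_true(all(compute_metrics(perfect)[
    c("tpr", "tnr", "precision", "f_alpha", "f_beta", "wa", "g_mean", "mcc")] == 1))
  all_wrong <- structure(list(tp = 0, fp = 10, tn = 0, fn = 10,
                              weighted = FALSE, w1 = 1, w2 = 1),
                         class = "confusion")
  expect_equal(compute_metrics(all_wrong)$mcc, -1)
  degenerate <- structure(list(tp = 0, fp = 0, tn = 10, fn = 10,
                               weighted = FALSE, w1 = 1, w2 = 1),
                          class = "confusion")
  expect_warning(m <- compute_metrics(degenerate), "MCC")
  expect_equal(m$mcc, 0)
  empty_class <- structure(list(tp = 0, fp = 5, tn = 0, fn = 0,
                                weighted = FALSE, w1 = 1, w2 = 1),
                           class = "confusion")
  expect_error(compute_metrics(empty_class), "undefined metric")
})

test_that("the expected out-of-bag fraction follows (1 - 1/n)^n", {
  expect_equal(oob_fraction(1), 0)
  expect_equal(oob_fraction(2), 0.25)
  expect_equal(oob_fraction(1e6), exp(-1), tolerance = 1e-5)
  expect_error(oob_fraction(0), "at least 1")
})

test_that("Mann-Whitney p-values match exhaustive enumeration", {
  set.seed(71)
  cases <- list(c(3, 3), c(4, 6), c(5, 5), c(7, 4))
  for (nm in cases) {
    a <- round(rnorm(nm[1]), 6)
    b <- round(rnorm(nm[2], mean = 0.5), 6)
    expect_equal(mann_whitney_compare(a, b), mw_enumerate(a, b),
                 tolerance = 1e-12, info = paste(nm, collapse = "x"))
  }
  expect_equal(mann_whitney_compare(rep(1, 5), rep(1, 5)), 1)
  expect_error(mann_whitney_compare(1, 1:5), "at least 2")
})

test_that("complete and near-complete separation give the tabulated floors", {
  expect_equal(mann_whitney_compare(1:10, 11:20), 2 / choose(20, 10),
               tolerance = 1e-9)
  # one inversion from complete separation: U = 1, p = 2 * 2 / C(20,10)
  a <- c(1:9, 10.5)
  b <- c(10, 11:19)
  expect_equal(mann_whitney_compare(a, b), 4 / choose(20, 10),
               tolerance = 1e-9)
})

cv_fixture <- local({
  spec <- synthetic_spec(n_tss = 60, n_fss = 80, flank = 5,
                         consensus_strength = 0.8, dependency_strength = 0.5,
                         seed = 401)
  generate_dataset(spec)
})

test_that("cross-validation returns one report per fold with fold hygiene", {
  cv <- cross_validate(cv_fixture$tss, cv_fixture$fss, procedure = "P-1",
                       classifier = list(name = "rf", ntree = 80), k = 5,
                       seed = 17)
  expect_equal(nrow(cv$per_fold), 5L)
  expect_equal(cv$summary$metric[1], "tpr")
  for (m in c("tpr", "tnr", "wa", "g_mean")) {
    i <- match(m, cv$summary$metric)
    expect_gte(cv$summary$mean[i], min(cv$per_fold[[m]]))
    expect_lte(cv$summary$mean[i], max(cv$per_fold[[m]]))
  }
  expect_length(cv$margins, 5L)
  expect_true(all(unlist(cv$margins) >= -1 & unlist(cv$margins) <= 1))
})

test_that("per-fold matrices are built from training windows only", {
  folds <- make_folds(nrow(cv_fixture$tss), nrow(cv_fixture$fss), k = 5,
                      seed = 23)
  tr_tss <- cv_fixture$tss[folds$pos != 1, , drop = FALSE]
  tr_fss <- cv_fixture$fss[folds$neg != 1, , drop = FALSE]
  d1 <- fold_difference_matrix(tr_tss, tr_fss, "P-2")

  mutated <- cv_fixture$tss
  idx <- which(folds$pos == 1)[1]
  mutated$seq[idx] <- paste(rev(strsplit(mutated$seq[idx], "")[[1]]),
                            collapse = "")
  d2 <- fold_difference_matrix(mutated[folds$pos != 1, , drop = FALSE],
                               tr_fss, "P-2")
  expect_identical(unclass(d1), unclass(d2))
})

test_that("a majority-class predictor zeroes one rate in every fold", {
  # more FSS than TSS in training, so the null model always answers FSS;
  # its degenerate confusion matrices warn about the zero MCC denominator
  cv <- suppressWarnings(
    cross_validate(cv_fixture$tss, cv_fixture$fss,
                   classifier = list(name = "majority"), k = 5, seed = 19))
  expect_true(all(cv$per_fold$tpr == 0))
  expect_true(all(cv$per_fold$tnr == 1))
})

test_that("weighted cross-validation applies the test-fold class shares", {
  cv <- cross_validate(cv_fixture$tss, cv_fixture$fss,
                       classifier = list(name = "rf", ntree = 60), k = 5,
                       seed = 29, weighted = TRUE)
  expect_equal(nrow(cv$per_fold), 5L)
  expect_true(all(cv$per_fold$tpr >= 0 & cv$per_fold$tpr <= 1))
})

test_that("cross-validation results export to tidy and summary CSVs", {
  cv <- cross_validate(cv_fixture$tss, cv_fixture$fss,
                       classifier = list(name = "rf", ntree = 40), k = 5,
                       seed = 37)
  dir <- withr::local_tempdir()
  paths <- write_cv_result(cv, dir, prefix = "unit")
  long <- read.csv(file.path(dir, "unit_folds.csv"))
  expect_equal(nrow(long), 5L * 8L)
  expect_setequal(unique(long$metric),
                  c("tpr", "tnr", "precision", "f_alpha", "f_beta", "wa",
                    "g_mean", "mcc"))
})
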