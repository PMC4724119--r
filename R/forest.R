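#' Random-forest configuration
#'
#' @param mtry Features tried per split; `NULL` defers to `floor(sqrt(p))`
#'   at training time. The tuned value for 101-feature windows is 50.
#' @param ntree Trees in the forest; the final model uses 1000.
#' @param cutoffs Named per-class vote cutoffs summing to 1. Balanced
#'   default `c(TSS = 0.5, FSS = 0.5)`; the imbalanced protocol assigns 0.9
#'   to the major class (FSS) and 0.1 to the minor (TSS).
#' @param seed Integer seed for the bootstrap/feature sampling.
#' @return A `forest_config` list.
#' @export
forest_config <- function(mtry = NULL, ntree = 1000, cutoffs = c(TSS = 0.5, FSS = 0.5),
                          seed = 1) {
  if (!is.null(mtry) && mtry < 1) stop("mtry must be at least 1")
  if (ntree < 1) stop("ntree must be at least 1")
  check_cutoffs(cutoffs)
  structure(list(mtry = mtry, ntree = as.integer(ntree),
                 cutoffs = cutoffs[CLASS_LEVELS], seed = as.integer(seed)),
            class = "forest_config")
}

check_cutoffs <- function(cutoffs) {
  if (is.null(names(cutoffs))) names(cutoffs) <- CLASS_LEVELS
  if (!all(CLASS_LEVELS %in% names(cutoffs))) stop("cutoffs must be named TSS/FSS")
  if (any(cutoffs <= 0)) stop("cutoffs must be positive")
  if (abs(sum(cutoffs) - 1) > 1e-9) stop("cutoffs must sum to 1")
  invisible(cutoffs)
}

#' Train the random-forest classifier
#'
#' Fits an ensemble of classification trees on encoded vectors, each tree on
#' a bootstrap sample, with the out-of-bag (OOB) instances providing an
#' internal error estimate. Reproducible for a fixed config seed.
#'
#' @param data An `encoded_dataset` with labels covering both classes.
#' @param config A [forest_config()].
#' @return A `splice_rf` model: the fitted ensemble, the config, the final
#'   OOB error, the OOB error curve over trees, and the feature names.
#' @export
train_forest <- function(data, config = forest_config()) {
  if (is.null(data$labels)) stop("training data must be labelled")
  if (nlevels(droplevels(data$labels)) < 2) stop("training data must contain both classes")
  p <- ncol(data$x)
  mtry <- config$mtry %||% max(1L, floor(sqrt(p)))
  if (mtry > p) stop("mtry exceeds the number of features (", p, ")")
  fit <- with_seed(config$seed,
    randomForest::randomForest(x = data$x, y = data$labels,
                               mtry = mtry, ntree = config$ntree,
                               cutoff = config$cutoffs[levels(data$labels)],
                               keep.forest = TRUE))
  structure(list(fit = fit, config = config, mtry = mtry,
                 oob_error = unname(fit$err.rate[config$ntree, "OOB"]),
                 oob_curve = unname(fit$err.rate[, "OOB"]),
                 feature_names = colnames(data$x)),
            class = "splice_rf")
}

#' @export
print.splice_rf <- function(x, ...) {
  cat("Random-forest splice-site model:", x$config$ntree, "trees, mtry =",
      x$mtry, "\n  OOB error:", format(x$oob_error, digits = 4), "\n")
  invisible(x)
}

#' Candidate mtry grid
#'
#' The tuning grid over the feature count p: 1, sqrt(p), 20%, 30% and 50% of
#' p, and p itself. Fractional entries are rounded half-up by default;
#' `rounding = "down"` truncates instead (for p = 101 the half of p is then
#' 50 rather than 51, the value the tuned model uses).
#'
#' @param p Number of features.
#' @param rounding `"half-up"` or `"down"`.
#' @return Increasing integer vector of distinct grid values in `[1, p]`.
#' @export
mtry_grid <- function(p, rounding = c("half-up", "down")) {
  rounding <- match.arg(rounding)
  raw <- c(1, sqrt(p), 0.2 * p, 0.3 * p, 0.5 * p, p)
  vals <- if (rounding == "half-up") floor(raw + 0.5) else floor(raw)
  sort(unique(pmin(pmax(as.integer(vals), 1L), as.integer(p))))
}

#' Tune mtry by out-of-bag error
#'
#' Trains one forest per grid value and picks the one with the lowest final
#' OOB error (ties broken toward the smaller mtry).
#'
#' @param data Labelled `encoded_dataset`.
#' @param grid Integer mtry candidates; `NULL` uses [mtry_grid()].
#' @param ntree Trees per candidate forest.
#' @param seed Integer seed (same data+grid+seed reproduce the table).
#' @param rounding Passed to [mtry_grid()] when `grid` is `NULL`.
#' @return List with `best_mtry` and `table` (data frame mtry / oob_error).
#' @export
tune_mtry <- function(data, grid = NULL, ntree = 200, seed = 1,
                      rounding = "half-up") {
  p <- ncol(data$x)
  grid <- grid %||% mtry_grid(p, rounding)
  if (length(grid) == 0) stop("empty mtry grid")
  if (any(grid < 1 | grid > p)) stop("grid values must lie in [1, p]")
  oob <- vapply(seq_along(grid), function(i) {
    m <- train_forest(data, forest_config(mtry = grid[i], ntree = ntree,
                                          seed = derive_seed(seed, i)))
    m$oob_error
  }, numeric(1))
  tab <- data.frame(mtry = grid, oob_error = oob)
  list(best_mtry = grid[which.min(oob)], table = tab)
}

#' First stabilization point of an OOB error curve
#'
#' The smallest tree count t such that the curve's range (max minus min)
#' over the trailing window `[t-window+1, t]` is at most `tol`; the curve
#' length if no window qualifies.
#'
#' @param oob_curve Numeric OOB error per cumulative tree count.
#' @param tol Non-negative stabilization tolerance on the error range.
#' @param window Trailing window width (at least 2).
#' @return Integer tree count.
#' @export
stable_ntree <- function(oob_curve, tol = 0.005, window = 50) {
  if (tol < 0) stop("tol must be non-negative")
  n <- length(oob_curve)
  if (window < 2 || n < window) stop("curve shorter than window")
  for (t in seq(window, n)) {
    seg <- oob_curve[(t - window + 1L):t]
    if (max(seg) - min(seg) <= tol) return(as.integer(t))
  }
  as.integer(n)
}

#' Tune ntree by OOB stabilization
#'
#' Grows a forest of `max_trees` and returns the first point where the OOB
#' error curve stabilizes, formalized as a trailing-window range test
#' (see [stable_ntree()]).
#'
#' @param data Labelled `encoded_dataset`.
#' @param mtry Features per split for the probe forest.
#' @param max_trees Maximum trees grown.
#' @param tol,window Stabilization tolerance and window width.
#' @param seed Integer seed.
#' @return List with `ntree` (stable point) and `oob_curve`.
#' @export
tune_ntree <- function(data, mtry, max_trees = 1000, tol = 0.005, window = 50,
                       seed = 1) {
  if (max_trees < window) stop("max_trees must be at least window")
  model <- train_forest(data, forest_config(mtry = mtry, ntree = max_trees,
                                            seed = seed))
  list(ntree = stable_ntree(model$oob_curve, tol, window),
       oob_curve = model$oob_curve)
}

#' Class-vote probabilities
#'
#' Fraction of trees (or the adapter's probability estimate) voting each
#' class for every instance. Columns are always TSS, FSS and sum to 1.
#'
#' @param model A `splice_rf` or baseline adapter model.
#' @param data An `encoded_dataset` with matching feature names.
#' @return n x 2 matrix with columns `TSS`, `FSS`.
#' @export
predict_prob <- function(model, data) UseMethod("predict_prob")

#' @export
predict_prob.splice_rf <- function(model, data) {
  if (!identical(colnames(data$x), model$feature_names)) {
    stop("feature names do not match the training data")
  }
  p <- predict(model$fit, newdata = data$x, type = "prob")
  p <- p[, CLASS_LEVELS, drop = FALSE]
  rownames(p) <- NULL
  p
}

#' Cutoff-based class assignment
#'
#' Assigns the class maximizing the ratio of vote probability to its cutoff
#' (the vote-ratio rule of the reference forest implementation). Balanced
#' cutoffs (0.5, 0.5) reduce to plain argmax; the imbalanced protocol uses
#' 0.9 for the major class (FSS) and 0.1 for the minor (TSS). Ties go to TSS.
#'
#' @param probs n x 2 probability matrix with columns TSS, FSS.
#' @param cutoffs Named positive cutoffs summing to 1.
#' @return Factor of predicted labels with levels TSS, FSS.
#' @export
classify_with_cutoff <- function(probs, cutoffs = c(TSS = 0.5, FSS = 0.5)) {
  check_cutoffs(cutoffs)
  ratio <- sweep(probs[, CLASS_LEVELS, drop = FALSE], 2,
                 cutoffs[CLASS_LEVELS], "/")
  pred <- ifelse(ratio[, "TSS"] >= ratio[, "FSS"], "TSS", "FSS")
  factor(pred, levels = CLASS_LEVELS)
}

#' Margin of each prediction
#'
#' The vote share of the true class minus the largest vote share of any
#' other class; in the binary case `P(true) - P(other)`, always in
#' `[-1, 1]`. Instances with non-negative margin are counted correctly
#' classified (ties at zero count as correct).
#'
#' @param probs n x 2 probability matrix with columns TSS, FSS.
#' @param true_labels Aligned true labels.
#' @return Numeric margins in `[-1, 1]`.
#' @export
margin_values <- function(probs, true_labels) {
  y <- as_class_factor(true_labels)
  if (length(y) != nrow(probs)) stop("probs and labels must align")
  p_true <- probs[cbind(seq_along(y), match(as.character(y), CLASS_LEVELS))]
  p_other <- 1 - p_true
  unname(p_true - p_other)
}

#' Persist a trained model with its encoder
#'
#' Saves the model, the difference matrix used to encode its training data,
#' and the feature names in one archive so prediction on raw sequence can be
#' reproduced exactly.
#'
#' @param model A trained model exposing [predict_prob()].
#' @param diff The `diff_matrix` the training data was encoded with.
#' @param path Output path (single file).
#' @return `path`, invisibly.
#' @export
save_model_archive <- function(model, diff, path) {
  fn <- model$feature_names
  if (!identical(fn, colnames(unclass(diff)))) {
    stop("feature names of model and difference matrix disagree")
  }
  saveRDS(list(model = model, diff = diff, feature_names = fn,
               package_version = as.character(utils::packageVersion("spliceRF"))),
          path)
  invisible(path)
}

#' Load a model archive written by [save_model_archive()]
#' @param path Archive path.
#' @return List with `model`, `diff`, `feature_names`.
#' @export
load_model_archive <- function(path) {
  if (!file.exists(path)) stop("archive not found: ", path)
  arch <- readRDS(path)
  if (!identical(arch$feature_names, colnames(unclass(arch$diff)))) {
    stop("corrupt archive: feature names mismatch")
  }
  arch
}
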