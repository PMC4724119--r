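# Thin adapters over standard classifiers so the cross-validation harness
# can compare the forest against common alternatives under one contract:
# every adapter exposes predict_prob() returning TSS/FSS columns summing to 1.

#' Train a baseline classifier adapter
#'
#' Delegates to a standard implementation; no bespoke training logic.
#' Supported: `svm` (RBF kernel, default gamma 0.01, optional
#' `class.weights`), `ann` (single-hidden-layer perceptron; `size`
#' required), `bagging` (bootstrap trees with every feature available at
#' each split), `boosting` (gradient-boosted trees), `logistic`, `knn`
#' (`k`, default 5), `naive_bayes`, and `majority` (constant majority-class
#' predictor, useful as a null reference).
#'
#' @param name Adapter name.
#' @param data Labelled `encoded_dataset`.
#' @param params Named list of adapter parameters (see above); all adapters
#'   accept `seed`.
#' @return A `splice_baseline` model usable with [predict_prob()].
#' @export
train_baseline <- function(name, data, params = list()) {
  supported <- c("svm", "ann", "bagging", "boosting", "logistic", "knn",
                 "naive_bayes", "majority")
  if (!name %in% supported) {
    stop("unknown baseline '", name, "'; supported: ",
         paste(supported, collapse = ", "))
  }
  if (is.null(data$labels)) stop("training data must be labelled")
  x <- data$x
  y <- data$labels
  seed <- params$seed %||% 1
  prob_fun <- switch(name,
    svm = {
      fit <- with_seed(seed, e1071::svm(
        x = x, y = y, kernel = "radial", gamma = params$gamma %||% 0.01,
        class.weights = params$class.weights, probability = TRUE))
      function(newx) {
        p <- attr(predict(fit, newx, probability = TRUE), "probabilities")
        p[, CLASS_LEVELS, drop = FALSE]
      }
    },
    ann = {
      size <- params$size
      if (is.null(size)) stop("ann adapter requires params$size (hidden units)")
      fit <- with_seed(seed, nnet::nnet(
        x = x, y = as.numeric(y == "TSS"), size = size,
        decay = params$decay %||% 0, maxit = params$maxit %||% 200,
        entropy = TRUE, trace = FALSE))
      function(newx) {
        p_tss <- as.numeric(predict(fit, newx))
        cbind(TSS = p_tss, FSS = 1 - p_tss)
      }
    },
    bagging = {
      fit <- with_seed(seed, randomForest::randomForest(
        x = x, y = y, mtry = ncol(x), ntree = params$ntree %||% 200))
      function(newx) {
        p <- predict(fit, newx, type = "prob")
        p[, CLASS_LEVELS, drop = FALSE]
      }
    },
    boosting = {
      dtrain <- xgboost::xgb.DMatrix(x, label = as.numeric(y == "TSS"))
      fit <- with_seed(seed, xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = params$max_depth %||% 3,
                      eta = params$eta %||% 0.3, nthread = 1),
        data = dtrain, nrounds = params$nrounds %||% 50, verbose = 0))
      function(newx) {
        p_tss <- predict(fit, xgboost::xgb.DMatrix(newx))
        cbind(TSS = p_tss, FSS = 1 - p_tss)
      }
    },
    logistic = {
      df <- data.frame(x, check.names = FALSE)
      df$.y <- as.numeric(y == "TSS")
      fit <- suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
      function(newx) {
        p_tss <- suppressWarnings(
          as.numeric(predict(fit, data.frame(newx, check.names = FALSE),
                             type = "response")))
        cbind(TSS = p_tss, FSS = 1 - p_tss)
      }
    },
    knn = {
      k <- params$k %||% 5
      function(newx) {
        pred <- with_seed(seed, class::knn(train = x, test = newx, cl = y,
                                           k = k, prob = TRUE))
        p_win <- attr(pred, "prob")
        p_tss <- ifelse(pred == "TSS", p_win, 1 - p_win)
        cbind(TSS = p_tss, FSS = 1 - p_tss)
      }
    },
    naive_bayes = {
      fit <- e1071::naiveBayes(x = x, y = y)
      function(newx) {
        p <- predict(fit, newx, type = "raw")
        p[, CLASS_LEVELS, drop = FALSE]
      }
    },
    majority = {
      maj <- names(which.max(table(y)))
      function(newx) {
        p_tss <- rep(as.numeric(maj == "TSS"), nrow(newx))
        cbind(TSS = p_tss, FSS = 1 - p_tss)
      }
    }
  )
  structure(list(name = name, params = params, prob_fun = prob_fun,
                 feature_names = colnames(x)),
            class = "splice_baseline")
}

#' @export
predict_prob.splice_baseline <- function(model, data) {
  if (!identical(colnames(data$x), model$feature_names)) {
    stop("feature names do not match the training data")
  }
  p <- model$prob_fun(data$x)
  rownames(p) <- NULL
  p
}
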