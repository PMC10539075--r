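# Disease prediction model: algorithm registry, nested cross-validation
# selection, probability estimation.
#
# The prediction model is fit on labeled subjects only, using endophenotype
# predictors (e.g. regional MRI measures, cognitive scores) plus demographic
# covariates.  SNP/genotype columns are refused as predictors: reusing the
# genotype both to impute the phenotype and to test association would
# manufacture false positives.

.algo_env <- new.env(parent = emptyenv())

#' Register a prediction algorithm
#'
#' The registry maps an algorithm id to a `fit(x, y, inner_folds, seed)`
#' function returning an opaque fitted object plus chosen hyperparameters, and
#' a `predict(object, x)` function returning probabilities.  Built-in entries:
#' `"logistic"` (plain logistic regression), `"penalized"` (elastic-net
#' penalized logistic via glmnet, penalty strength chosen by inner CV),
#' `"rf"` (random forest via ranger, `mtry` tuned by inner CV) and `"svm"`
#' (RBF support-vector machine via e1071 with Platt-scaled probabilities,
#' cost tuned by inner CV); the last two register only if their backing
#' package is installed.
#'
#' @param id character id.
#' @param fit,predict functions as described above.
#' @export
register_algorithm <- function(id, fit, predict) {
  assign(id, list(fit = fit, predict = predict), envir = .algo_env)
  invisible(id)
}

#' @rdname register_algorithm
#' @export
algorithm_registry <- function() ls(.algo_env)

.algo <- function(id) {
  if (!exists(id, envir = .algo_env))
    stop("unknown algorithm '", id, "'; registered: ",
         paste(algorithm_registry(), collapse = ", "))
  get(id, envir = .algo_env)
}

# ---- built-in algorithms ---------------------------------------------------

.register_builtins <- function() {
  register_algorithm(
    "logistic",
    fit = function(x, y, inner_folds, seed) {
      f <- wgee_fit(cbind(`(Intercept)` = 1, x), y)
      list(coef = f$coefficients, hyper = NULL)
    },
    predict = function(object, x) {
      stats::plogis(drop(cbind(1, x) %*% object$coef))
    })

  register_algorithm(
    "penalized",
    fit = function(x, y, inner_folds, seed) {
      if (!is.null(seed)) set.seed(seed)
      foldid <- .stratified_folds(y, inner_folds)
      cv <- glmnet::cv.glmnet(x, y, family = "binomial", foldid = foldid,
                              alpha = 0.5, type.measure = "auc")
      list(model = cv$glmnet.fit, lambda = cv$lambda.min,
           hyper = list(lambda = cv$lambda.min, alpha = 0.5))
    },
    predict = function(object, x) {
      drop(stats::predict(object$model, x, s = object$lambda,
                          type = "response"))
    })

  if (requireNamespace("ranger", quietly = TRUE)) {
    register_algorithm(
      "rf",
      fit = function(x, y, inner_folds, seed) {
        grid <- unique(pmax(1L, round(c(sqrt(ncol(x)), ncol(x) / 3, ncol(x) / 2))))
        best <- .tune_by_inner_cv(x, y, inner_folds, seed, grid, function(xtr, ytr, m)
          ranger::ranger(x = xtr, y = factor(ytr), mtry = m, probability = TRUE,
                         num.trees = 300, seed = seed %||% 1L,
                         num.threads = 1L),
          function(fit, xte) stats::predict(fit, xte,
                                            num.threads = 1L)$predictions[, "1"])
        fit <- ranger::ranger(x = x, y = factor(y), mtry = best,
                              probability = TRUE, num.trees = 500,
                              seed = seed %||% 1L, num.threads = 1L)
        list(model = fit, hyper = list(mtry = best))
      },
      predict = function(object, x) {
        stats::predict(object$model, x, num.threads = 1L)$predictions[, "1"]
      })
  }

  if (requireNamespace("e1071", quietly = TRUE)) {
    register_algorithm(
      "svm",
      fit = function(x, y, inner_folds, seed) {
        grid <- c(0.1, 1, 10)
        best <- .tune_by_inner_cv(x, y, inner_folds, seed, grid, function(xtr, ytr, cost)
          e1071::svm(xtr, factor(ytr), cost = cost, probability = TRUE,
                     kernel = "radial"),
          function(fit, xte) attr(stats::predict(fit, xte, probability = TRUE),
                                  "probabilities")[, "1"])
        fit <- e1071::svm(x, factor(y), cost = best, probability = TRUE,
                          kernel = "radial")
        list(model = fit, hyper = list(cost = best))
      },
      predict = function(object, x) {
        attr(stats::predict(object$model, x, probability = TRUE),
             "probabilities")[, "1"]
      })
  }
  invisible(TRUE)
}

# Inner-CV hyperparameter choice by mean held-out AUC over a small grid.
.tune_by_inner_cv <- function(x, y, inner_folds, seed, grid, fit_fn, pred_fn) {
  if (!is.null(seed)) set.seed(seed)
  folds <- .stratified_folds(y, inner_folds)
  auc <- vapply(grid, function(h) {
    mean(vapply(seq_len(inner_folds), function(k) {
      tr <- folds != k
      f <- fit_fn(x[tr, , drop = FALSE], y[tr], h)
      auc_rank(pred_fn(f, x[!tr, , drop = FALSE]), y[!tr])
    }, numeric(1)))
  }, numeric(1))
  grid[which.max(auc)]
}

# Stratified fold ids: classes allocated separately so every fold sees both.
.stratified_folds <- function(y, k) {
  id <- integer(length(y))
  for (cl in unique(y)) {
    i <- which(y == cl)
    id[i] <- sample(rep_len(seq_len(k), length(i)))
  }
  id
}

#' Rank-statistic AUC
#'
#' Area under the ROC curve computed as the normalized Mann-Whitney rank sum,
#' with midranks for ties.
#' @param p predicted scores.
#' @param y binary labels.
#' @export
auc_rank <- function(p, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes needed for AUC")
  r <- rank(p)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Fit and select the disease prediction model by nested cross-validation
#'
#' Outer folds estimate a test AUC for each candidate algorithm; inner folds
#' (inside each outer training set) choose the hyperparameters.  The algorithm
#' with the highest mean outer-fold AUC wins — ties break by the order of
#' `algorithms` — and is refit on all labeled subjects with hyperparameters
#' chosen by inner CV on the full data.
#'
#' @param x predictor table: data frame or matrix of endophenotype predictors;
#'   one row per subject.  Genotype-like columns (names matching an rs-id, or
#'   integer columns with the three values 0/1/2) are rejected.  Rows with
#'   missing predictor values are dropped with a warning; non-finite values
#'   are an error naming the column.
#' @param y binary labels (0/1) for the same subjects; both classes must be
#'   present.
#' @param algorithms character vector of registry ids, tried in order.
#' @param outer_folds,inner_folds fold counts of the nested CV.
#' @param seed one top-level seed; fold assignment and stochastic learners
#'   derive deterministic child seeds from it.
#' @return an object of class `"wip_prediction_model"` with the winning
#'   algorithm id, the refit model, per-outer-fold AUCs of every candidate,
#'   the selected hyperparameters and the training column names.
#' @export
fit_prediction_model <- function(x, y,
                                 algorithms = c("logistic", "penalized"),
                                 outer_folds = 5L, inner_folds = 5L,
                                 seed = NULL) {
  x <- .as_predictor_matrix(x)
  y <- as.integer(y)
  keep <- stats::complete.cases(x) & !is.na(y)
  if (!all(keep)) {
    warning(sum(!keep), " subject(s) with missing predictor values dropped")
    x <- x[keep, , drop = FALSE]; y <- y[keep]
  }
  for (j in seq_len(ncol(x)))
    if (any(!is.finite(x[, j])))
      stop("non-finite values in predictor column '", colnames(x)[j], "'")
  if (length(unique(y)) < 2L)
    stop("labels contain a single class; cannot fit a prediction model")
  lapply(algorithms, .algo)  # validate ids upfront

  if (!is.null(seed)) set.seed(seed)
  child <- sample.int(2^30, length(algorithms) * (outer_folds + 1L))
  folds <- .stratified_folds(y, outer_folds)

  auc <- matrix(NA_real_, outer_folds, length(algorithms),
                dimnames = list(NULL, algorithms))
  for (a in seq_along(algorithms)) {
    alg <- .algo(algorithms[a])
    for (k in seq_len(outer_folds)) {
      tr <- folds != k
      fit <- alg$fit(x[tr, , drop = FALSE], y[tr], inner_folds,
                     seed = child[(a - 1L) * (outer_folds + 1L) + k])
      p <- alg$predict(fit, x[!tr, , drop = FALSE])
      auc[k, a] <- auc_rank(p, y[!tr])
    }
  }
  mean_auc <- colMeans(auc)
  best <- algorithms[which.max(mean_auc)]  # which.max keeps first on ties
  alg <- .algo(best)
  final <- alg$fit(x, y, inner_folds,
                   seed = child[(which.max(mean_auc)) * (outer_folds + 1L)])
  structure(list(algorithm = best, model = final,
                 auc = auc, mean_auc = mean_auc,
                 hyper = final$hyper, columns = colnames(x),
                 n = length(y)),
            class = "wip_prediction_model")
}

#' @export
print.wip_prediction_model <- function(x, ...) {
  cat("Disease prediction model —", x$algorithm, "\n")
  cat("trained on", x$n, "labeled subjects,", length(x$columns), "predictors\n")
  cat("mean outer-CV AUC:",
      paste(sprintf("%s %.3f", names(x$mean_auc), x$mean_auc), collapse = ", "),
      "\n")
  invisible(x)
}

#' Affection probabilities from a fitted prediction model
#'
#' @param model a `"wip_prediction_model"`.
#' @param newdata predictor table whose columns must match the training
#'   columns exactly (an error lists missing/extra columns otherwise).
#' @return numeric vector of probabilities in \[0, 1\].
#' @export
predict_probability <- function(model, newdata) {
  x <- .as_predictor_matrix(newdata)
  missing <- setdiff(model$columns, colnames(x))
  extra <- setdiff(colnames(x), model$columns)
  if (length(missing) || length(extra))
    stop("predictor columns do not match training columns",
         if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; extra: ", paste(extra, collapse = ", ")))
  x <- x[, model$columns, drop = FALSE]
  p <- .algo(model$algorithm)$predict(model$model, x)
  pmin(pmax(as.numeric(p), 0), 1)
}

#' @export
predict.wip_prediction_model <- function(object, newdata, ...) {
  predict_probability(object, newdata)
}

# Coerce predictors to a numeric matrix and refuse genotype-like columns.
.as_predictor_matrix <- function(x) {
  if (is.data.frame(x)) {
    nonnum <- names(x)[!vapply(x, is.numeric, logical(1))]
    if (length(nonnum))
      stop("non-numeric predictor column(s): ", paste(nonnum, collapse = ", "))
    x <- as.matrix(x)
  }
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  snpish <- grepl("^rs[0-9]+", colnames(x), ignore.case = TRUE)
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    vv <- unique(v[is.finite(v)])
    if (snpish[j] ||
        (length(vv) == 3L && setequal(vv, c(0, 1, 2))))
      stop("column '", colnames(x)[j], "' looks like a genotype; ",
           "SNPs must not be used as phenotype predictors")
  }
  x
}
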