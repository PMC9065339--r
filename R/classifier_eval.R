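#' Model configuration
#'
#' Defaults: gradient boosting with 500 trees, depth 6, learning rate 0.1;
#' SVM with radial kernel, cost 1, gamma = 1/n_features; CART with the Gini
#' criterion, complexity pruning disabled (cp = 0) and depth effectively
#' unlimited. All hyperparameters can be overridden through `params`.
#'
#' @param algorithm `"xgboost"`, `"svm"` or `"cart"`.
#' @param params Named list of hyperparameter overrides.
#' @param seed Integer seed controlling every stochastic element of
#'   training.
#' @return A `model_config` list.
#' @export
model_config <- function(algorithm = c("xgboost", "svm", "cart"),
                         params = list(), seed = 1L) {
  algorithm <- match.arg(algorithm)
  defaults <- switch(algorithm,
    xgboost = list(nrounds = 500, max_depth = 6, eta = 0.1,
                   objective = "binary:logistic", nthread = 1),
    svm = list(kernel = "radial", cost = 1, gamma = NULL),
    cart = list(cp = 0, maxdepth = 30, minsplit = 20)
  )
  params <- utils::modifyList(defaults, params)
  structure(list(algorithm = algorithm, params = params,
                 seed = as.integer(seed)),
            class = "model_config")
}

feature_matrix <- function(tbl, cols) {
  missing_cols <- setdiff(cols, names(tbl))
  extra <- setdiff(intersect(names(tbl), .FEATURE_COLS), cols)
  if (length(missing_cols)) {
    abort(paste0("feature schema mismatch; missing column(s): ",
                 paste(missing_cols, collapse = ", "),
                 if (length(extra)) paste0("; extra: ",
                                           paste(extra, collapse = ", "))))
  }
  as.matrix(tbl[, cols, drop = FALSE])
}

#' Train a binding-site classifier
#'
#' Fits the configured algorithm on the feature columns of a labelled table.
#' Training is deterministic for a fixed seed (gradient boosting runs
#' single-threaded).
#'
#' @param tbl Feature-table tibble with a 0/1 `label` column; all
#'   `feature_columns()` names present in the table are used.
#' @param config A [model_config()].
#' @return A `site_model`: list with the fitted model, `algorithm`,
#'   `feature_names` and `config`.
#' @export
train_classifier <- function(tbl, config = model_config()) {
  stopifnot(inherits(config, "model_config"), "label" %in% names(tbl))
  if (nrow(tbl) == 0) abort("empty training table")
  y <- tbl$label
  if (length(unique(y)) < 2) {
    abort("training table contains a single class; both labels required")
  }
  cols <- intersect(.FEATURE_COLS, names(tbl))
  if (length(cols) == 0) abort("no recognised feature columns in table")
  x <- feature_matrix(tbl, cols)
  p <- config$params

  fit <- switch(config$algorithm,
    xgboost = {
      dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = p$nthread)
      xgboost::xgb.train(
        params = list(max_depth = p$max_depth, eta = p$eta,
                      objective = p$objective, nthread = p$nthread,
                      seed = config$seed),
        data = dtrain, nrounds = p$nrounds, verbose = 0
      )
    },
    svm = {
      gamma <- p$gamma %||% 1 / ncol(x)
      withr::with_seed(config$seed,
        e1071::svm(x = x, y = factor(y, levels = c(0, 1)),
                   kernel = p$kernel, cost = p$cost, gamma = gamma,
                   probability = TRUE, scale = TRUE))
    },
    cart = {
      df <- as.data.frame(x)
      df$.label <- factor(y, levels = c(0, 1))
      withr::with_seed(config$seed,
        rpart::rpart(.label ~ ., data = df, method = "class",
                     parms = list(split = "gini"),
                     control = rpart::rpart.control(
                       cp = p$cp, maxdepth = p$maxdepth,
                       minsplit = p$minsplit)))
    }
  )
  structure(list(fit = fit, algorithm = config$algorithm,
                 feature_names = cols, config = config),
            class = "site_model")
}

#' @export
print.site_model <- function(x, ...) {
  cat("<site_model> ", x$algorithm, ", ", length(x$feature_names),
      " features\n", sep = "")
  invisible(x)
}

#' Predict binding-site scores and labels
#'
#' Scores are in \[0, 1\]; the hard label is 1 when the score is at least
#' 0.5 (ties classified positive). Input columns are realigned to the
#' training schema, so column order does not matter; missing or unknown
#' feature columns raise an error naming them.
#'
#' @param object A `site_model`.
#' @param new_data Tibble containing the model's feature columns.
#' @param ... Unused.
#' @return The input with `score` and `pred` columns appended.
#' @export
predict.site_model <- function(object, new_data, ...) {
  x <- feature_matrix(new_data, object$feature_names)
  score <- switch(object$algorithm,
    xgboost = predict(object$fit,
                      xgboost::xgb.DMatrix(x, nthread = 1)),
    svm = {
      pr <- attr(predict(object$fit, x, probability = TRUE), "probabilities")
      as.vector(pr[, "1"])
    },
    cart = {
      df <- as.data.frame(x)
      as.vector(predict(object$fit, df, type = "prob")[, "1"])
    }
  )
  mutate(new_data, score = as.numeric(score),
         pred = as.integer(score >= 0.5))
}

#' Confusion counts
#'
#' @param truth 0/1 vector of true labels.
#' @param estimate 0/1 vector of predicted labels.
#' @return A `confusion_counts` list with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(truth, estimate) {
  stopifnot(length(truth) == length(estimate),
            all(truth %in% 0:1), all(estimate %in% 0:1))
  structure(list(
    TP = sum(truth == 1 & estimate == 1),
    TN = sum(truth == 0 & estimate == 0),
    FP = sum(truth == 0 & estimate == 1),
    FN = sum(truth == 1 & estimate == 0)
  ), class = "confusion_counts")
}

#' Rank-based ROC AUC
#'
#' Mann-Whitney formulation: average ranks handle score ties, which makes
#' the value identical to the trapezoidal area under the ROC curve.
#'
#' @param truth 0/1 vector.
#' @param score Numeric scores (larger = more positive).
#' @return AUC in \[0, 1\]; `NaN` when a class is absent.
#' @export
auc_score <- function(truth, score) {
  stopifnot(length(truth) == length(score))
  n1 <- sum(truth == 1)
  n0 <- sum(truth == 0)
  if (n1 == 0 || n0 == 0) return(NaN)
  r <- rank(score)
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

safe_ratio <- function(num, den, name) {
  if (den == 0) {
    warn(paste0(name, " undefined (zero denominator); reported as NaN"))
    return(NaN)
  }
  num / den
}

#' Binary evaluation metrics
#'
#' Accuracy, sensitivity, specificity, precision and the Matthews
#' correlation coefficient from confusion counts, plus rank-based AUC when
#' scores are supplied. The standard specificity TN/(TN+FP) is the default;
#' `spe_literal = TRUE` switches to TN/(TN+FN). Ratios with a zero
#' denominator are reported as `NaN` with a warning, never silently 0.
#'
#' @param counts A `confusion_counts` object (or list with TP/TN/FP/FN).
#' @param truth,score Optional 0/1 labels and scores for AUC; when absent
#'   AUC is omitted (`NA`), never fabricated.
#' @param spe_literal Use TN/(TN+FN) for specificity. Default `FALSE`.
#' @param protocol Label recorded in the report (e.g. `"kfold(10)"`).
#' @return A `site_eval` object.
#' @export
eval_metrics <- function(counts, truth = NULL, score = NULL,
                         spe_literal = FALSE, protocol = "direct") {
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  tot <- TP + TN + FP + FN
  stopifnot(tot > 0)
  acc <- (TP + TN) / tot
  sen <- safe_ratio(TP, TP + FN, "SEN")
  spe <- if (spe_literal) safe_ratio(TN, TN + FN, "SPE") else
    safe_ratio(TN, TN + FP, "SPE")
  pre <- safe_ratio(TP, TP + FP, "PRE")
  mcc_den <- sqrt(prod(c(TP + FP, TP + FN, TN + FP, TN + FN)))
  mcc <- if (mcc_den == 0) {
    warn("MCC undefined (zero denominator); reported as NaN")
    NaN
  } else {
    (TP * TN - FP * FN) / mcc_den
  }
  auc <- if (!is.null(score)) auc_score(truth, score) else NA_real_
  structure(list(
    ACC = acc, SEN = sen, SPE = spe, PRE = pre, MCC = mcc, AUC = auc,
    counts = counts, protocol = protocol,
    predictions = if (!is.null(score)) tibble(truth = truth, score = score)
  ), class = "site_eval")
}

#' @export
print.site_eval <- function(x, ...) {
  cat("<site_eval> ", x$protocol, "\n", sep = "")
  v <- unlist(x[c("ACC", "SEN", "SPE", "PRE", "MCC", "AUC")])
  print(round(v, 4))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an evaluation report
#' @param x A `site_eval`.
#' @param ... Unused.
#' @return Long tibble with `metric`, `value`.
#' @export
tidy.site_eval <- function(x, ...) {
  tibble(metric = c("ACC", "SEN", "SPE", "PRE", "MCC", "AUC"),
         value = unlist(x[c("ACC", "SEN", "SPE", "PRE", "MCC", "AUC")],
                        use.names = FALSE))
}

#' Glance at an evaluation report
#' @param x A `site_eval`.
#' @param ... Unused.
#' @return One-row tibble: metrics, counts and protocol.
#' @export
glance.site_eval <- function(x, ...) {
  tibble(ACC = x$ACC, SEN = x$SEN, SPE = x$SPE, PRE = x$PRE,
         MCC = x$MCC, AUC = x$AUC,
         TP = x$counts$TP, TN = x$counts$TN, FP = x$counts$FP,
         FN = x$counts$FN, protocol = x$protocol)
}

stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  withr::with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

#' Cross-validated evaluation
#'
#' Jackknife (leave-one-row-out) or stratified k-fold cross-validation.
#' Metrics are computed on the pooled out-of-fold predictions, so every row
#' is scored exactly once. Fold assignment is deterministic for a given
#' seed. If a training fold loses a class the folds are re-drawn once, then
#' an error is raised. `group_by_complex` assigns whole structures to folds
#' to prevent same-complex leakage.
#'
#' @param tbl Labelled feature table.
#' @param config A [model_config()].
#' @param protocol `"kfold"` (default) or `"jackknife"`.
#' @param k Folds for `"kfold"`; default 10.
#' @param seed Integer seed for fold assignment.
#' @param group_by_complex Keep rows of one `structure_id` in one fold.
#' @param spe_literal Passed to [eval_metrics()].
#' @return A `site_eval` with pooled out-of-fold predictions attached.
#' @export
cross_validate <- function(tbl, config = model_config(),
                           protocol = c("kfold", "jackknife"), k = 10,
                           seed = 1L, group_by_complex = FALSE,
                           spe_literal = FALSE) {
  protocol <- match.arg(protocol)
  n <- nrow(tbl)
  y <- tbl$label
  if (protocol == "jackknife") {
    fold <- seq_len(n)
    k <- n
    label <- "jackknife"
  } else {
    stopifnot(k >= 2, k <= n)
    label <- paste0("kfold(", k, ")")
    draw <- function(s) {
      if (k == n) {
        seq_len(n)                 # leave-one-out: one row per fold
      } else if (group_by_complex) {
        ids <- unique(tbl$structure_id)
        f <- withr::with_seed(s, sample(rep_len(seq_len(k), length(ids))))
        f[match(tbl$structure_id, ids)]
      } else {
        stratified_folds(y, k, s)
      }
    }
    fold <- draw(seed)
    bad <- any(vapply(seq_len(k), function(f) {
      length(unique(y[fold != f])) < 2
    }, logical(1)))
    if (bad) {
      fold <- draw(seed + 1L)
      bad <- any(vapply(seq_len(k), function(f) {
        length(unique(y[fold != f])) < 2
      }, logical(1)))
      if (bad) abort("a training fold lost a class even after re-drawing")
    }
  }

  score <- rep(NA_real_, n)
  for (f in seq_len(k)) {
    te <- which(fold == f)
    if (length(te) == 0) next
    tr <- tbl[-te, ]
    if (length(unique(tr$label)) < 2) {
      abort("a jackknife training set lost a class")
    }
    fit <- train_classifier(tr, config)
    score[te] <- predict(fit, tbl[te, ])$score
  }
  stopifnot(!anyNA(score))
  pred <- as.integer(score >= 0.5)
  eval_metrics(confusion_counts(y, pred), truth = y, score = score,
               spe_literal = spe_literal, protocol = label)
}

#' Evaluate a trained model on an independent test set
#'
#' No refitting; the test set is evaluated with its natural class balance.
#'
#' @param model A `site_model`.
#' @param test Labelled feature table.
#' @param spe_literal Passed to [eval_metrics()].
#' @return A `site_eval` with protocol `"independent"`.
#' @export
evaluate_independent <- function(model, test, spe_literal = FALSE) {
  if (nrow(test) == 0) abort("empty test set")
  stopifnot("label" %in% names(test))
  pr <- predict(model, test)
  eval_metrics(confusion_counts(test$label, pr$pred),
               truth = test$label, score = pr$score,
               spe_literal = spe_literal, protocol = "independent")
}
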