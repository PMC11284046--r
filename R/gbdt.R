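# Gradient-boosted decision-tree subtype classifier: one-vs-all binary
# ensembles (one per class) of depth-limited regression trees fit
# forward-stagewise against the binomial deviance, with per-stage row
# subsampling. xgboost is the boosting engine, configured so the fitted
# ensembles honor the reference hyperparameters: the sklearn-style
# min_samples_leaf is enforced through the hessian bound
# min_child_weight = min_samples_leaf * 0.25 (a binary-logistic hessian is
# at most 0.25 per sample), and xgboost's extra regularizers are disabled.

#' Gradient-boosting configuration
#'
#' Defaults follow the reference setting: learning rate 0.1, at most 300
#' estimators per class, tree depth 3, at least 5 samples per leaf, 5 per
#' split, per-stage row subsampling 0.8, deviance (log-loss) objective.
#'
#' @param learning_rate Shrinkage in (0, 1].
#' @param n_estimators Boosting stages per class (capped at 300).
#' @param max_depth Maximum tree depth.
#' @param min_samples_leaf Minimum samples per leaf.
#' @param min_samples_split Minimum samples to split a node (dominated by
#'   `min_samples_leaf` when, as here, it is not larger than twice the leaf
#'   minimum; recorded for completeness).
#' @param subsample Per-stage row-subsampling fraction in (0, 1].
#' @param loss Only `"deviance"` (binomial log-loss per class).
#' @param seed Integer seed.
#' @param early_stopping `NULL` (off) or a list with `validation_fraction`
#'   (default 0.15) and `patience` (default 10): a stratified validation
#'   split is monitored and boosting stops after `patience` non-improving
#'   rounds.
#' @return An object of class `gbdt_config`.
#' @export
gbdt_config <- function(learning_rate = 0.1, n_estimators = 300L,
                        max_depth = 3L, min_samples_leaf = 5L,
                        min_samples_split = 5L, subsample = 0.8,
                        loss = "deviance", seed = 1L,
                        early_stopping = NULL) {
  if (!(learning_rate > 0 && learning_rate <= 1)) {
    stop("gbdt_config: learning_rate must be in (0, 1]")
  }
  if (!(subsample > 0 && subsample <= 1)) {
    stop("gbdt_config: subsample must be in (0, 1]")
  }
  n_estimators <- as.integer(n_estimators)
  if (n_estimators < 1 || n_estimators > 300L) {
    stop("gbdt_config: n_estimators must be in 1..300 (estimator cap)")
  }
  if (!identical(loss, "deviance")) {
    stop("gbdt_config: only the 'deviance' loss is supported")
  }
  if (!is.null(early_stopping)) {
    early_stopping <- utils::modifyList(
      list(validation_fraction = 0.15, patience = 10L),
      as.list(early_stopping))
  }
  structure(list(learning_rate = learning_rate, n_estimators = n_estimators,
                 max_depth = as.integer(max_depth),
                 min_samples_leaf = as.integer(min_samples_leaf),
                 min_samples_split = as.integer(min_samples_split),
                 subsample = subsample, loss = loss,
                 seed = as.integer(seed), early_stopping = early_stopping),
            class = "gbdt_config")
}

as_feature_matrix <- function(features) {
  if (inherits(features, "assembled_features")) features$values
  else as.matrix(features)
}

xgb_params <- function(config) {
  list(objective = "binary:logistic",
       eta = config$learning_rate,
       max_depth = config$max_depth,
       min_child_weight = config$min_samples_leaf * 0.25,
       subsample = config$subsample,
       lambda = 0, alpha = 0, gamma = 0,
       colsample_bytree = 1,
       tree_method = "exact",
       nthread = 1,
       seed = config$seed)
}

#' Fit the one-vs-all boosted-tree classifier
#'
#' Fits one binary deviance-boosted ensemble per class (forward stagewise:
#' each stage adds a depth-limited regression tree fit against the current
#' loss gradient on a `subsample` fraction of rows). With `K` classes and
#' `M` stages the model holds `M * K` trees. The aggregated per-stage
#' training log-loss (summed over the class ensembles) is recorded.
#'
#' @param features An [assemble_features()] object or numeric matrix
#'   (samples x features).
#' @param labels A [label_vector()] (or factor/character vector).
#' @param config A [gbdt_config()].
#' @return Object of class `fitted_gbdt` with elements `boosters` (one per
#'   class), `config`, `class_names`, `staged_train_loss`, `n_trees`,
#'   `feature_width`, `layout`.
#' @export
fit_gbdt <- function(features, labels, config = gbdt_config()) {
  stopifnot(inherits(config, "gbdt_config"))
  X <- as_feature_matrix(features)
  layout <- if (inherits(features, "assembled_features")) features$layout
            else NULL
  if (!inherits(labels, "label_vector")) {
    labels <- label_vector(seq_len(nrow(X)), labels)
  }
  y <- labels$labels
  K <- length(labels$class_names)
  n <- nrow(X)
  if (length(y) != n) stop("fit_gbdt: features/labels length mismatch")
  if (length(unique(y)) < 2) {
    stop("fit_gbdt: labels contain a single class; need K >= 2")
  }
  if (n < config$min_samples_split) {
    stop("fit_gbdt: fewer samples than min_samples_split")
  }
  small <- table(factor(y, levels = 0:(K - 1))) < config$min_samples_leaf
  if (any(small)) {
    warning("fit_gbdt: class(es) ",
            paste(labels$class_names[small], collapse = ", "),
            " have fewer samples than min_samples_leaf")
  }
  set.seed(config$seed)
  val_idx <- NULL
  if (!is.null(config$early_stopping)) {
    vf <- config$early_stopping$validation_fraction
    val_idx <- unlist(lapply(0:(K - 1), function(k) {
      idx <- which(y == k)
      nv <- max(1L, round(length(idx) * vf))
      if (length(idx) > 1) sample(idx, nv) else integer(0)
    }), use.names = FALSE)
  }
  tr_idx <- if (is.null(val_idx)) seq_len(n) else setdiff(seq_len(n), val_idx)
  boosters <- vector("list", K)
  staged <- NULL
  n_trees <- integer(K)
  for (k in seq_len(K)) {
    yk <- as.numeric(y == (k - 1L))
    dtrain <- xgboost::xgb.DMatrix(X[tr_idx, , drop = FALSE],
                                   label = yk[tr_idx])
    evals <- list(train = dtrain)
    es <- NULL
    if (!is.null(val_idx)) {
      dval <- xgboost::xgb.DMatrix(X[val_idx, , drop = FALSE],
                                   label = yk[val_idx])
      evals <- list(train = dtrain, validation = dval)
      es <- config$early_stopping$patience
    }
    bst <- xgboost::xgb.train(params = xgb_params(config), data = dtrain,
                              nrounds = config$n_estimators,
                              evals = evals,
                              early_stopping_rounds = es,
                              verbose = 0)
    boosters[[k]] <- bst
    log_k <- attributes(bst)$evaluation_log$train_logloss
    n_trees[k] <- length(log_k)
    if (is.null(staged)) {
      staged <- log_k
    } else {
      m <- min(length(staged), length(log_k))
      staged <- staged[seq_len(m)] + log_k[seq_len(m)]
    }
  }
  structure(list(boosters = boosters, config = config,
                 class_names = labels$class_names,
                 staged_train_loss = staged, n_trees = n_trees,
                 feature_width = ncol(X), layout = layout),
            class = "fitted_gbdt")
}

#' @export
print.fitted_gbdt <- function(x, ...) {
  cat(sprintf(
    "<fitted_gbdt: %d classes (one-vs-all), %s trees, depth <= %d>\n",
    length(x$class_names), paste(x$n_trees, collapse = "+"),
    x$config$max_depth))
  invisible(x)
}

#' Binary log-loss (deviance)
#'
#' `-(1/N) * sum(y * log(p) + (1 - y) * log(1 - p))`, with probabilities
#' clipped to `[1e-15, 1 - 1e-15]`.
#'
#' @param y 0/1 labels.
#' @param p Predicted probabilities.
#' @return Scalar loss.
#' @examples
#' logloss(c(1, 0), c(0.5, 0.5))  # log(2)
#' @export
logloss <- function(y, p) {
  if (length(y) != length(p)) stop("logloss: length mismatch")
  p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Predict subtypes with a fitted boosted-tree model
#'
#' Each class ensemble produces an additive score (log-odds margin); scores
#' are softmax-normalized into per-class probabilities and the argmax class
#' is reported.
#'
#' @param object A [fit_gbdt()] model.
#' @param features Features with the training layout/width.
#' @param ... Unused.
#' @return List with `labels` (a [label_vector()]) and `prob`
#'   (`n x K` matrix, rows summing to 1).
#' @export
predict.fitted_gbdt <- function(object, features, ...) {
  X <- as_feature_matrix(features)
  if (inherits(features, "assembled_features") &&
      !is.null(object$layout)) {
    w_tr <- vapply(object$layout, function(l) l$width, numeric(1))
    w_new <- vapply(features$layout, function(l) l$width, numeric(1))
    if (!identical(w_tr, w_new)) {
      stop("predict: feature layout mismatch (training widths ",
           paste(w_tr, collapse = "+"), ", supplied ",
           paste(w_new, collapse = "+"), ")")
    }
  }
  if (ncol(X) != object$feature_width) {
    stop("predict: feature width ", ncol(X), " does not match training ",
         "width ", object$feature_width)
  }
  K <- length(object$class_names)
  scores <- vapply(seq_len(K), function(k) {
    stats::predict(object$boosters[[k]], xgboost::xgb.DMatrix(X),
                   outputmargin = TRUE)
  }, numeric(nrow(X)))
  scores <- matrix(scores, nrow = nrow(X), ncol = K)
  z <- scores - apply(scores, 1, max)
  prob <- exp(z) / rowSums(exp(z))
  pred <- max.col(prob, ties.method = "first") - 1L
  list(labels = label_vector(paste0("s", seq_len(nrow(X))), pred,
                             class_names = object$class_names),
       prob = prob)
}

#' Classification metrics report
#'
#' Accuracy plus macro-averaged precision, recall and F1 (per class
#' one-vs-rest, F1 as the per-class harmonic mean before averaging), all as
#' percentages rounded to one decimal, with the per-class table and the
#' K x K confusion matrix. A class never predicted gets precision 0.
#'
#' @param y_true A [label_vector()] or integer/factor vector.
#' @param y_pred Predictions of the same length (codes must be valid for
#'   the true label set).
#' @return Object of class `metrics_report`.
#' @examples
#' evaluate(c(0, 0, 1, 1), c(0, 1, 1, 1))$f1  # 73.3
#' @export
evaluate <- function(y_true, y_pred) {
  cn <- NULL
  if (inherits(y_true, "label_vector")) {
    cn <- y_true$class_names
    y_true <- y_true$labels
  }
  if (inherits(y_pred, "label_vector")) {
    if (is.null(cn)) cn <- y_pred$class_names
    y_pred <- y_pred$labels
  }
  if (length(y_true) != length(y_pred)) stop("evaluate: length mismatch")
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  if (is.null(cn)) cn <- as.character(sort(unique(c(y_true, y_pred))))
  K <- length(cn)
  if (any(y_pred < 0L | y_pred >= K)) {
    stop("evaluate: predicted class code outside the true label set")
  }
  conf <- table(factor(y_true, levels = 0:(K - 1)),
                factor(y_pred, levels = 0:(K - 1)))
  conf <- matrix(as.integer(conf), K, K,
                 dimnames = list(true = cn, predicted = cn))
  tp <- diag(conf)
  prec <- ifelse(colSums(conf) > 0, tp / colSums(conf), 0)
  rec <- ifelse(rowSums(conf) > 0, tp / rowSums(conf), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  pct <- function(x) round(100 * x, 1)
  structure(list(
    accuracy = pct(mean(y_true == y_pred)),
    precision = pct(mean(prec)),
    recall = pct(mean(rec)),
    f1 = pct(mean(f1)),
    per_class = data.frame(class = cn, precision = pct(prec),
                           recall = pct(rec), f1 = pct(f1),
                           support = rowSums(conf), row.names = NULL),
    confusion = conf,
    n = length(y_true)),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "accuracy %.1f | macro precision %.1f | macro recall %.1f | macro F1 %.1f  (n = %d)\n",
    x$accuracy, x$precision, x$recall, x$f1, x$n))
  print(x$per_class)
  invisible(x)
}
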