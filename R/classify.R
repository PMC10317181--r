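#' Winner-takes-all diagnosis from model-fit probabilities
#'
#' The group model with the highest fit probability is the predicted
#' diagnosis. A subject whose most probable stage under that winning model
#' is 0 carries too little pathology to classify and is labelled
#' `"Unclassified"` (such subjects are excluded from accuracy metrics).
#' Exact ties resolve to the first group in column order with a warning.
#'
#' @param fit_probs subjects x groups matrix of model-fit probabilities
#'   (one column per group model, in a fixed group order).
#' @param ml_stages subjects x groups matrix of most probable stages under
#'   each group model.
#' @return data.frame with `subject_id`, `predicted` (group name or
#'   `"Unclassified"`) and `unclassified` flag.
#' @export
classify_max_likelihood <- function(fit_probs, ml_stages) {
  fit_probs <- as.matrix(fit_probs)
  ml_stages <- as.matrix(ml_stages)
  stopifnot(identical(dim(fit_probs), dim(ml_stages)),
            !is.null(colnames(fit_probs)))
  ties <- apply(fit_probs, 1, function(p) sum(p == max(p)) > 1)
  if (any(ties))
    warning(sum(ties), " subject(s) with exactly tied fit probabilities; ",
            "resolved to the first group in column order")
  win <- max.col(fit_probs, ties.method = "first")
  n <- nrow(fit_probs)
  winning_stage <- ml_stages[cbind(seq_len(n), win)]
  predicted <- colnames(fit_probs)[win]
  unclassified <- winning_stage == 0
  predicted[unclassified] <- "Unclassified"
  data.frame(
    subject_id = rownames(fit_probs) %||% paste0("subj", seq_len(n)),
    predicted = predicted, unclassified = unclassified,
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classification metrics
#'
#' Confusion matrix plus accuracy, balanced accuracy (unweighted mean of
#' per-class recall), and per-class, macro and class-weighted precision,
#' recall and F1.
#'
#' @param true_labels character/factor vector of true classes.
#' @param predicted_labels vector of predicted classes (same length).
#' @return list with `confusion` (true x predicted), `accuracy`,
#'   `balanced_accuracy`, `per_class` data.frame, `macro` and `weighted`
#'   precision/recall/F1.
#' @export
classification_metrics <- function(true_labels, predicted_labels) {
  if (!length(true_labels)) stop("empty input")
  stopifnot(length(true_labels) == length(predicted_labels))
  classes <- sort(unique(as.character(true_labels)))
  lev <- sort(unique(c(classes, as.character(predicted_labels))))
  tl <- factor(as.character(true_labels), levels = lev)
  pl <- factor(as.character(predicted_labels), levels = lev)
  conf <- table(true = tl, predicted = pl)
  per <- do.call(rbind, lapply(classes, function(cl) {
    tp <- conf[cl, cl]
    prec <- if (sum(conf[, cl]) > 0) tp / sum(conf[, cl]) else NA_real_
    rec <- tp / sum(conf[cl, ])
    f1 <- if (!is.na(prec) && prec + rec > 0) 2 * prec * rec / (prec + rec)
          else 0
    data.frame(class = cl, n = sum(conf[cl, ]), precision = prec,
               recall = rec, f1 = f1, stringsAsFactors = FALSE)
  }))
  w <- per$n / sum(per$n)
  list(confusion = conf,
       accuracy = sum(diag(conf[classes, classes, drop = FALSE])) /
         length(true_labels),
       balanced_accuracy = mean(per$recall),
       per_class = per,
       macro = c(precision = mean(per$precision, na.rm = TRUE),
                 recall = mean(per$recall), f1 = mean(per$f1)),
       weighted = c(precision = sum(w * per$precision, na.rm = TRUE),
                    recall = sum(w * per$recall), f1 = sum(w * per$f1)))
}

#' L2 multinomial logistic-regression classifier on model-fit features
#'
#' Fits the three-way (or k-way) diagnosis model on per-subject features —
#' typically the fit probabilities under each group model, the most probable
#' stage and age at death. Each repeat draws a stratified 80/20 train/test
#' split; within the training set, 10-fold cross-validation selects the
#' inverse-regularisation hyperparameter C over a grid of 10 linearly spaced
#' values between 1e-4 and 1e4 (log spacing available via `log_grid`); test
#' metrics are recorded per repeat to give confidence intervals.
#'
#' Implemented with ridge-penalised multinomial [glmnet::glmnet()]; sklearn's
#' C maps to lambda = 1 / (n_train x C).
#'
#' @param features data.frame or matrix of numeric features (complete cases).
#' @param labels class label per subject (>= 2 classes present).
#' @param n_repeats number of train/test splits (default 100).
#' @param train_frac training fraction (default 0.8).
#' @param n_folds inner CV folds for the C grid (default 10).
#' @param c_grid hyperparameter grid (default 10 linearly spaced values
#'   between 1e-4 and 1e4).
#' @param log_grid use log-spaced C values instead.
#' @param seed optional RNG seed.
#' @return list with `metrics` (one row per repeat), `summary` (mean and
#'   2.5/97.5 percentiles per metric), `mean_confusion`, `chosen_c` per
#'   repeat and the final model fitted on all data at the modal C.
#' @export
classify_logistic <- function(features, labels, n_repeats = 100,
                              train_frac = 0.8, n_folds = 10,
                              c_grid = NULL, log_grid = FALSE, seed = NULL) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("features must be complete")
  y <- factor(labels)
  if (nlevels(y) < 2) stop("need at least two classes")
  if (is.null(c_grid))
    c_grid <- if (log_grid) 10^seq(-4, 4, length.out = 10)
              else seq(1e-4, 1e4, length.out = 10)
  if (!is.null(seed)) set.seed(seed)

  rows <- vector("list", n_repeats)
  chosen <- numeric(n_repeats)
  conf_acc <- NULL
  for (rep_i in seq_len(n_repeats)) {
    split <- .stratified_split(y, train_frac)
    cc <- .select_c(x[split$train, , drop = FALSE], y[split$train],
                    c_grid, n_folds)
    fit <- .ridge_multinom(x[split$train, , drop = FALSE], y[split$train], cc)
    pred <- .predict_class(fit, x[split$test, , drop = FALSE])
    met <- classification_metrics(y[split$test], pred)
    rows[[rep_i]] <- data.frame(
      repeat_id = rep_i, c = cc, accuracy = met$accuracy,
      balanced_accuracy = met$balanced_accuracy,
      precision_macro = met$macro["precision"],
      recall_macro = met$macro["recall"], f1_macro = met$macro["f1"],
      precision_weighted = met$weighted["precision"],
      recall_weighted = met$weighted["recall"],
      f1_weighted = met$weighted["f1"], row.names = NULL)
    chosen[rep_i] <- cc
    cm <- met$confusion[levels(y), levels(y), drop = FALSE]
    conf_acc <- if (is.null(conf_acc)) cm / sum(cm) else
      conf_acc + cm / sum(cm)
  }
  metrics <- do.call(rbind, rows)
  num <- metrics[, setdiff(names(metrics), "repeat_id")]
  summ <- data.frame(
    metric = names(num), mean = vapply(num, mean, numeric(1)),
    lo = vapply(num, quantile, numeric(1), probs = 0.025),
    hi = vapply(num, quantile, numeric(1), probs = 0.975), row.names = NULL)
  modal_c <- as.numeric(names(which.max(table(chosen))))
  list(metrics = metrics, summary = summ,
       mean_confusion = conf_acc / n_repeats, chosen_c = chosen,
       model = .ridge_multinom(x, y, modal_c), c_grid = c_grid)
}

.stratified_split <- function(y, train_frac, max_tries = 20) {
  for (i in seq_len(max_tries)) {
    train <- unlist(lapply(levels(y), function(cl) {
      idx <- which(y == cl)
      sample(idx, max(1, round(train_frac * length(idx))))
    }))
    test <- setdiff(seq_along(y), train)
    if (length(test) && all(levels(y) %in% y[train]))
      return(list(train = sort(train), test = test))
  }
  stop("could not draw a split with every class in the training set")
}

.ridge_multinom <- function(x, y, c_value) {
  # sklearn-style C maps to lambda = 1/(nC); the largest C values imply a
  # lambda so small that ridge solutions diverge on separable data, so the
  # effective lambda is floored at 1e-6 — prediction-indistinguishable in
  # the near-unpenalised regime but numerically well-posed
  lambda <- max(1 / (nrow(x) * c_value), 1e-6)
  fit <- glmnet::glmnet(x, y, family = "multinomial", alpha = 0,
                        lambda = lambda * 10^(4:0),
                        standardize = TRUE, maxit = 3e5)
  fit$target_lambda <- lambda
  fit
}

.predict_class <- function(fit, x) {
  p <- predict(fit, newx = x, type = "class", s = fit$target_lambda)
  factor(p[, 1], levels = fit$classnames)
}

.select_c <- function(x, y, c_grid, n_folds) {
  n <- nrow(x)
  folds <- integer(n)
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(seq_len(min(n_folds, n)), length(idx))
  }
  acc <- vapply(c_grid, function(cc) {
    hits <- 0
    for (f in unique(folds)) {
      tr <- folds != f
      if (length(unique(y[tr])) < nlevels(y)) next
      fit <- .ridge_multinom(x[tr, , drop = FALSE], y[tr], cc)
      pred <- .predict_class(fit, x[!tr, , drop = FALSE])
      hits <- hits + sum(pred == y[!tr])
    }
    hits / n
  }, numeric(1))
  c_grid[which.max(acc)]
}
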