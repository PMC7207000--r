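# Sevenfold cross-validation, exhaustive grid search and the metric set
# used to score models.

#' Performance metrics for pooled predictions
#'
#' Classification: misclassification rate (fraction of argmax labels not
#' equal to truth) and mean cross-entropy log loss. Regression: mean
#' squared error, r-squared (1 - SSres/SStot of predictions against
#' observations) and adjusted r-squared for a single predictor,
#' \code{1 - (1 - r2) (n - 1) / (n - 2)}.
#'
#' @param predictions class-probability matrix (columns named by class) or
#'   numeric regression predictions.
#' @param truth true labels or observed values.
#' @return named list of metrics.
#' @export
model_metrics <- function(predictions, truth) {
  if (is.matrix(predictions)) {
    classes <- colnames(predictions)
    lab <- classes[max.col(predictions, ties.method = "first")]
    p_true <- predictions[cbind(seq_along(truth),
                                match(as.character(truth), classes))]
    list(misclassification = mean(lab != as.character(truth)),
         log_loss = -mean(log(pmax(p_true, 1e-15))))
  } else {
    n <- length(truth)
    ss_res <- sum((truth - predictions)^2)
    ss_tot <- sum((truth - mean(truth))^2)
    r2 <- 1 - ss_res / ss_tot
    if (n < 3L) stop_cfg("adjusted r-squared needs at least 3 observations")
    list(mse = mean((truth - predictions)^2), r2 = r2,
         adj_r2 = 1 - (1 - r2) * (n - 1) / (n - 2))
  }
}

confusion_matrix <- function(predictions, truth) {
  classes <- colnames(predictions)
  lab <- factor(classes[max.col(predictions, ties.method = "first")],
                levels = classes)
  table(truth = factor(as.character(truth), levels = classes), predicted = lab)
}

# Stratified fold assignment: shuffled members are dealt to folds in
# rotation within each class, so fold sizes differ by at most one and each
# class is spread as evenly as possible.
make_folds <- function(y, k, stratify, seed) {
  n <- length(y)
  if (k > n) stop_cfg("k = %d exceeds sample count %d", k, n)
  with_seed(seed, {
    if (stratify) {
      # shuffle within class, then concatenate class blocks
      idx <- unlist(lapply(split(seq_len(n), as.character(y)),
                           function(i) i[sample.int(length(i))]), use.names = FALSE)
    } else {
      idx <- sample.int(n)
    }
    folds <- integer(n)
    folds[idx] <- rep(seq_len(k), length.out = n)
    folds
  })
}

#' k-fold cross-validation of a network spec
#'
#' Trains k models, each on the complement of one holdout fold
#' (stratified by class for classification), pools the holdout predictions
#' and computes overall metrics on the pooled set, as in sevenfold
#' cross-validation where each model sees 86% of the training data and 14%
#' is held out.
#'
#' @param spec [network_spec()].
#' @param X inputs (samples x features).
#' @param y labels or numeric response.
#' @param k fold count (default 7).
#' @return object of class \code{cv_result}: fold assignment, pooled
#'   holdout predictions with their truth, metrics, and (classification) a
#'   confusion matrix.
#' @export
kfold_cv <- function(spec, X, y, k = 7L) {
  classify <- spec$task == "classification"
  folds <- make_folds(y, k, stratify = classify, seed = spec$seed)
  preds <- if (classify)
    matrix(NA_real_, nrow(X), spec$n_classes,
           dimnames = list(rownames(X), sort(unique(as.character(y)))))
  else rep(NA_real_, nrow(X))
  for (f in seq_len(k)) {
    hold <- folds == f
    spec_f <- spec
    spec_f$seed <- spec$seed + f
    if (classify && length(unique(as.character(y)[!hold])) < length(unique(as.character(y))))
      warning(sprintf("fold %d: some class absent from the training portion", f))
    fit <- train_sgd(init_network(spec_f), X[!hold, , drop = FALSE], y[!hold])
    ph <- predict(fit, X[hold, , drop = FALSE])
    if (classify) preds[hold, colnames(ph)] <- ph else preds[hold] <- ph
  }
  if (classify) preds[is.na(preds)] <- 0  # class unseen in training folds
  structure(list(k = k, folds = folds, predictions = preds, truth = y,
                 metrics = model_metrics(preds, y),
                 confusion = if (classify) confusion_matrix(preds, y)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold CV: %s\n", x$k,
              paste(names(x$metrics), signif(unlist(x$metrics), 4),
                    sep = " = ", collapse = ", ")))
  invisible(x)
}

spec_signature <- function(spec) {
  paste(spec$activation, spec$hidden[1], spec$hidden[2], spec$l1, spec$l2,
        spec$input_dropout, spec$hidden_dropout, spec$epochs, sep = "/")
}

#' Exhaustive hyperparameter grid search with k-fold cross-validation
#'
#' Every combination of the declared parameter values is scored by
#' [kfold_cv()] (log loss for classification, MSE for regression); the
#' winner is refit on the full data. Ties are broken by smaller total
#' hidden size, then lexicographically on the spec signature.
#'
#' @param X inputs; @param y labels or response.
#' @param grid named list of parameter values to cross: \code{hidden} (a
#'   list of pairs), \code{activation}, \code{l1}, \code{l2},
#'   \code{input_dropout}, \code{hidden_dropout}, \code{epochs}. Omitted
#'   entries use [network_spec()] defaults.
#' @param task,n_classes passed to [network_spec()].
#' @param k CV folds (default 7).
#' @param seed base seed; grid point i trains with seed + i.
#' @param budget optional cap: at most this many grid points, subsampled
#'   deterministically from the full grid.
#' @param ... further fixed arguments for [network_spec()] (rate,
#'   minibatch, ...).
#' @return list with \code{best_spec}, \code{best_model} (refit on all
#'   data), \code{best_cv}, \code{leaderboard} (data.frame, one row per
#'   grid point, sorted by score) and \code{scoring}.
#' @export
grid_search <- function(X, y, grid = list(), task = "classification",
                        n_classes = 2L, k = 7L, seed = 1L, budget = NULL, ...) {
  defaults <- list(hidden = list(c(16L, 16L)), activation = "tanh",
                   l1 = 0, l2 = 0, input_dropout = 0, hidden_dropout = 0,
                   epochs = 300L)
  for (nm in names(defaults)) if (is.null(grid[[nm]])) grid[[nm]] <- defaults[[nm]]
  if (!is.list(grid$hidden)) grid$hidden <- list(grid$hidden)
  combos <- expand.grid(hidden = seq_along(grid$hidden),
                        activation = grid$activation, l1 = grid$l1,
                        l2 = grid$l2, input_dropout = grid$input_dropout,
                        hidden_dropout = grid$hidden_dropout,
                        epochs = grid$epochs,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (nrow(combos) == 0L) stop_cfg("empty hyperparameter grid")
  if (!is.null(budget) && budget < nrow(combos))
    combos <- combos[with_seed(seed, sort(sample.int(nrow(combos), budget))), ,
                     drop = FALSE]
  scoring <- if (task == "classification") "log_loss" else "mse"
  rows <- vector("list", nrow(combos))
  cvs <- vector("list", nrow(combos))
  specs <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    co <- combos[i, ]
    spec <- network_spec(n_inputs = ncol(X), hidden = grid$hidden[[co$hidden]],
                         activation = co$activation, task = task,
                         n_classes = n_classes, l1 = co$l1, l2 = co$l2,
                         input_dropout = co$input_dropout,
                         hidden_dropout = co$hidden_dropout,
                         epochs = co$epochs, seed = seed + i, ...)
    cv <- kfold_cv(spec, X, y, k = k)
    specs[[i]] <- spec
    cvs[[i]] <- cv
    rows[[i]] <- data.frame(signature = spec_signature(spec),
                            score = cv$metrics[[scoring]],
                            t(unlist(cv$metrics)))
  }
  lb <- do.call(rbind, rows)
  if (all(!is.finite(lb$score))) stop_cfg("all grid points diverged")
  hid_sum <- vapply(specs, function(s) sum(s$hidden), 0)
  ord <- order(lb$score, hid_sum, lb$signature)
  best <- ord[1L]
  best_model <- train_sgd(init_network(specs[[best]]), X, y)
  list(best_spec = specs[[best]], best_model = best_model,
       best_cv = cvs[[best]], leaderboard = lb[ord, , drop = FALSE],
       scoring = scoring)
}
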