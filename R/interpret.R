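# Model interpretation: weight-based variable importance, backward feature
# elimination, Profile-method methylation-response curves and neural
# interpretation diagram export.

#' Gedeon variable importance through two hidden layers
#'
#' Each input's importance is the absolute-weight ratio propagated through
#' both hidden layers: with \code{P1[i,j] = |W1[i,j]| / sum_i' |W1[i',j]|}
#' and \code{P2[j,k] = |W2[j,k]| / sum_j' |W2[j',k]|}, the raw importance
#' of input i is \code{sum_k sum_j P1[i,j] P2[j,k]}, normalized to sum to
#' one. For maxout layers |W| is the channel-wise maximum absolute weight.
#' Hidden units with all-zero incoming weights contribute zero.
#'
#' @param model fitted \code{epitrait_net} (two hidden layers).
#' @param through_output also propagate through the output weights W3
#'   (off by default; the standard formulation stops at the second hidden
#'   layer).
#' @return object of class \code{importance_ranking}: \code{scores} (named,
#'   nonnegative, summing to 1) and \code{order} (input ids, descending
#'   score, ties by input index).
#' @export
gedeon_importance <- function(model, through_output = FALSE) {
  absmax_ch <- function(W) apply(abs(W), c(1, 2), max)
  norm_cols <- function(A) {
    cs <- colSums(A)
    A[, cs > 0] <- sweep(A[, cs > 0, drop = FALSE], 2, cs[cs > 0], `/`)
    A[, cs == 0] <- 0
    A
  }
  P1 <- norm_cols(absmax_ch(model$W[[1]]))
  P2 <- norm_cols(absmax_ch(model$W[[2]]))
  raw <- as.vector(P1 %*% rowSums(P2))
  if (through_output) {
    P3 <- norm_cols(absmax_ch(model$W[[3]]))
    raw <- as.vector(P1 %*% (P2 %*% rowSums(P3)))
  }
  ids <- model$input_ids %||% paste0("in", seq_along(raw))
  scores <- stats::setNames(raw / sum(raw), ids)
  structure(list(scores = scores,
                 order = ids[order(-scores, seq_along(scores))]),
            class = "importance_ranking")
}

#' @export
print.importance_ranking <- function(x, ...) {
  cat("Variable importance (", length(x$scores), " inputs); top:\n", sep = "")
  print(utils::head(round(x$scores[x$order], 4)))
  invisible(x)
}

#' Fractional elimination schedule
#'
#' Successively removes \code{fraction} of the inputs (keeping
#' \code{floor(m * (1 - fraction))}) until \code{min_size} is reached.
#'
#' @param n starting input count.
#' @param fraction fraction eliminated per step (default 0.05).
#' @param min_size stop once the next step would fall below this.
#' @return strictly decreasing integer vector starting at n.
#' @export
elimination_schedule <- function(n, fraction = 0.05, min_size = 12L) {
  sched <- n
  m <- n
  repeat {
    m2 <- floor(m * (1 - fraction))
    if (m2 < min_size || m2 == m) break
    sched <- c(sched, m2)
    m <- m2
  }
  as.integer(sched)
}

#' Backward elimination of input CpG by variable importance
#'
#' At each schedule step the current selection is refit by a fresh
#' hyperparameter search; the next selection keeps the top-m inputs ranked
#' by the Gedeon importance of that step's best model. This mirrors
#' schedules such as 8400, 4000, 1500, ..., 14, 12 inputs, or eliminating
#' 5% of inputs per step.
#'
#' @param X training inputs with column names (the initial selection).
#' @param y labels or response.
#' @param schedule strictly decreasing input counts; must start at
#'   \code{ncol(X)}.
#' @param trainer function(X, y) -> list with \code{best_model},
#'   \code{best_cv}, \code{best_spec}; by default a [grid_search()] with
#'   the arguments in \code{...}.
#' @param ... passed to [grid_search()] when \code{trainer} is NULL.
#' @return object of class \code{elimination_trace}: list of steps, each
#'   with \code{n_inputs}, \code{selection}, \code{best_spec},
#'   \code{cv_metrics}, \code{importance}.
#' @export
backward_eliminate <- function(X, y, schedule, trainer = NULL, ...) {
  if (any(diff(schedule) >= 0)) stop_cfg("schedule must be strictly decreasing")
  if (schedule[1] != ncol(X))
    stop_cfg("schedule must start at the initial selection size (%d)", ncol(X))
  if (is.null(trainer)) {
    dots <- list(...)
    trainer <- function(Xs, ys) do.call(grid_search, c(list(X = Xs, y = ys), dots))
  }
  current <- colnames(X)
  steps <- vector("list", length(schedule))
  for (s in seq_along(schedule)) {
    m <- schedule[s]
    if (m > length(current))
      stop_cfg("schedule value %d exceeds current selection size %d", m,
               length(current))
    current <- current[seq_len(m)]
    fit <- trainer(X[, current, drop = FALSE], y)
    fit$best_model$input_ids <- current
    imp <- gedeon_importance(fit$best_model)
    steps[[s]] <- list(n_inputs = m, selection = current,
                       best_spec = fit$best_spec,
                       cv_metrics = fit$best_cv$metrics,
                       importance = imp)
    current <- imp$order  # descending importance; next step truncates
  }
  structure(steps, class = "elimination_trace")
}

#' @export
print.elimination_trace <- function(x, ...) {
  for (st in x)
    cat(sprintf("%6d inputs: %s\n", st$n_inputs,
                paste(names(st$cv_metrics), signif(unlist(st$cv_metrics), 3),
                      sep = "=", collapse = " ")))
  invisible(x)
}

#' Methylation-response curves (Profile sensitivity method)
#'
#' For each input CpG, its methylation value is set to each of 99 empirical
#' quantiles (0.01 to 0.99) of its training values while all remaining
#' inputs co-move jointly through their own 99 quantiles, yielding
#' 99 x 99 = 9801 input vectors per cytosine; each is passed through the
#' fitted model and the output activations are recorded. A 14-input model
#' therefore produces 14 x 9801 = 137,214 prediction rows.
#'
#' Quantiles use the linear-interpolation definition (type 7) on the raw
#' percentage scale; standardization happens inside the forward pass.
#'
#' @param model fitted \code{epitrait_net}.
#' @param train_X training matrix restricted to the model's inputs,
#'   complete (imputed), raw percent scale.
#' @param n_quantiles quantile grid size (default 99).
#' @return data.table in long format: \code{input_id}, \code{qf} (focal
#'   quantile), \code{focal_value}, \code{qb} (background quantile), and
#'   one activation column per class (or \code{output} for regression).
#'   Constant input columns are flagged in the \code{constant_inputs}
#'   attribute.
#' @export
profile_curves <- function(model, train_X, n_quantiles = 99L) {
  if (!model$fitted) stop_cfg("model must be fitted")
  if (anyNA(train_X)) stop_cfg("training matrix must be imputed (no NAs)")
  p <- ncol(train_X)
  probs <- seq_len(n_quantiles) / (n_quantiles + 1)
  Q <- apply(train_X, 2, quantile, probs = probs, type = 7, names = FALSE)
  constant <- names(which(apply(train_X, 2, function(x) diff(range(x)) == 0)))
  ids <- colnames(train_X) %||% paste0("in", seq_len(p))
  rows_per <- n_quantiles^2
  out <- vector("list", p)
  for (i in seq_len(p)) {
    # background: all inputs at their qb-quantile; rows cycle qb fastest
    bg <- Q[rep(seq_len(n_quantiles), times = n_quantiles), , drop = FALSE]
    focal <- rep(Q[, i], each = n_quantiles)
    bg[, i] <- focal
    act <- predict(model, bg)
    dt <- data.table::data.table(
      input_id = ids[i],
      qf = rep(probs, each = n_quantiles),
      focal_value = focal,
      qb = rep(probs, times = n_quantiles))
    if (is.matrix(act)) {
      for (cl in colnames(act)) dt[[paste0("prob_", cl)]] <- act[, cl]
    } else dt[["output"]] <- act
    out[[i]] <- dt
  }
  res <- data.table::rbindlist(out)
  data.table::setattr(res, "constant_inputs", constant)
  res
}

#' Data for a neural interpretation diagram
#'
#' Nodes (inputs ordered by variable importance, hidden units, biases,
#' outputs) and signed weighted edges; positive weights are stimulatory,
#' negative inhibitory. Maxout edges carry a channel column.
#'
#' @param model fitted \code{epitrait_net}.
#' @param ranking its [gedeon_importance()] ranking.
#' @return list with \code{nodes} and \code{edges} data.frames, ready for
#'   JSON serialization.
#' @export
diagram_data <- function(model, ranking) {
  spec <- model$spec
  in_ids <- names(ranking$scores)
  nodes <- rbind(
    data.frame(id = ranking$order, type = "input", layer = 0L,
               importance = unname(ranking$scores[ranking$order])),
    data.frame(id = paste0("H1_", seq_len(spec$hidden[1])), type = "hidden",
               layer = 1L, importance = NA_real_),
    data.frame(id = paste0("H2_", seq_len(spec$hidden[2])), type = "hidden",
               layer = 2L, importance = NA_real_),
    data.frame(id = paste0("O_", seq_len(n_outputs(spec))), type = "output",
               layer = 3L, importance = NA_real_),
    data.frame(id = paste0("B", 1:3), type = "bias", layer = 0:2,
               importance = NA_real_))
  edge_block <- function(W, from_ids, to_ids, layer) {
    C <- dim(W)[3]
    do.call(rbind, lapply(seq_len(C), function(c) {
      w <- W[, , c]
      data.frame(from = rep(from_ids, times = length(to_ids)),
                 to = rep(to_ids, each = length(from_ids)),
                 weight = as.vector(w), sign = ifelse(as.vector(w) >= 0,
                                                      "stimulatory", "inhibitory"),
                 channel = c, layer = layer)
    }))
  }
  bias_block <- function(b, to_ids, which_b, layer) {
    do.call(rbind, lapply(seq_len(ncol(b)), function(c)
      data.frame(from = paste0("B", which_b), to = to_ids, weight = b[, c],
                 sign = ifelse(b[, c] >= 0, "stimulatory", "inhibitory"),
                 channel = c, layer = layer)))
  }
  h1 <- paste0("H1_", seq_len(spec$hidden[1]))
  h2 <- paste0("H2_", seq_len(spec$hidden[2]))
  oo <- paste0("O_", seq_len(n_outputs(spec)))
  edges <- rbind(edge_block(model$W[[1]], in_ids, h1, 1L),
                 edge_block(model$W[[2]], h1, h2, 2L),
                 edge_block(model$W[[3]], h2, oo, 3L),
                 bias_block(model$b[[1]], h1, 1L, 1L),
                 bias_block(model$b[[2]], h2, 2L, 2L),
                 bias_block(model$b[[3]], oo, 3L, 3L))
  list(nodes = nodes, edges = edges)
}
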