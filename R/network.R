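# Two-hidden-layer feed-forward networks: tanh / rectifier / maxout
# activations, L1/L2 penalties, inverted dropout, minibatch SGD with
# Nesterov momentum and polynomial rate annealing.

#' Specify a two-hidden-layer network
#'
#' @param n_inputs number of input features.
#' @param hidden integer pair, neurons per hidden layer (each in 4..400).
#' @param activation "tanh", "rectifier" or "maxout" (maxout = per-unit max
#'   over \code{maxout_channels} linear channels).
#' @param task "classification" or "regression".
#' @param n_classes number of classes (classification only).
#' @param l1 lasso coefficient, 0 or in [5e-6, 5e-4].
#' @param l2 ridge coefficient, 0 or in [5e-7, 5e-5].
#' @param input_dropout,hidden_dropout dropout fractions in [0, 0.5].
#' @param epochs training epochs, 200..600.
#' @param rate,rate_annealing learning-rate schedule: step t uses
#'   \code{rate / (1 + rate_annealing * t)}.
#' @param momentum Nesterov momentum coefficient.
#' @param minibatch minibatch size.
#' @param maxout_channels linear channels per maxout unit (default 2).
#' @param seed integer; training is deterministic given the seed.
#' @return object of class \code{nn_spec}.
#' @export
network_spec <- function(n_inputs, hidden = c(16L, 16L),
                         activation = c("tanh", "rectifier", "maxout"),
                         task = c("classification", "regression"),
                         n_classes = 2L,
                         l1 = 0, l2 = 0,
                         input_dropout = 0, hidden_dropout = 0,
                         epochs = 300L, rate = 0.02, rate_annealing = 1e-4,
                         momentum = 0.9, minibatch = 8L,
                         maxout_channels = 2L, seed = 1L) {
  activation <- match.arg(activation)
  task <- match.arg(task)
  if (length(hidden) != 2L) stop_cfg("exactly two hidden layers are required")
  if (any(hidden < 4L) || any(hidden > 400L))
    stop_cfg("hidden layer sizes must lie in [4, 400]")
  if (l1 != 0 && (l1 < 5e-6 || l1 > 5e-4))
    stop_cfg("l1 must be 0 or in [5e-6, 5e-4]")
  if (l2 != 0 && (l2 < 5e-7 || l2 > 5e-5))
    stop_cfg("l2 must be 0 or in [5e-7, 5e-5]")
  if (input_dropout < 0 || input_dropout > 0.5 ||
      hidden_dropout < 0 || hidden_dropout > 0.5)
    stop_cfg("dropout fractions must lie in [0, 0.5]")
  if (epochs < 200L || epochs > 600L)
    stop_cfg("epochs must lie in [200, 600]")
  if (task == "classification" && n_classes < 2L)
    stop_cfg("classification needs >= 2 classes")
  structure(list(n_inputs = as.integer(n_inputs),
                 hidden = as.integer(hidden), activation = activation,
                 task = task, n_classes = as.integer(n_classes),
                 l1 = l1, l2 = l2,
                 input_dropout = input_dropout, hidden_dropout = hidden_dropout,
                 epochs = as.integer(epochs), rate = rate,
                 rate_annealing = rate_annealing, momentum = momentum,
                 minibatch = as.integer(minibatch),
                 maxout_channels = as.integer(maxout_channels),
                 seed = as.integer(seed)),
            class = "nn_spec")
}

n_outputs <- function(spec) if (spec$task == "classification") spec$n_classes else 1L
n_channels <- function(spec) if (spec$activation == "maxout") spec$maxout_channels else 1L

#' Initialize network weights
#'
#' Weights are drawn uniformly in \code{[-r, r]} with
#' \code{r = sqrt(6 / (fan_in + fan_out))} per layer; biases start at zero.
#' Hidden-layer weights are stored as (fan_in x units x channels) arrays
#' (channel dimension 1 except for maxout).
#'
#' @param spec an [network_spec()].
#' @return unfitted model of class \code{epitrait_net}.
#' @export
init_network <- function(spec) {
  stopifnot(inherits(spec, "nn_spec"))
  C <- n_channels(spec)
  dims <- list(c(spec$n_inputs, spec$hidden[1]),
               c(spec$hidden[1], spec$hidden[2]),
               c(spec$hidden[2], n_outputs(spec)))
  with_seed(spec$seed, {
    mk <- function(d, ch) {
      r <- sqrt(6 / sum(d))
      array(runif(prod(d) * ch, -r, r), dim = c(d, ch))
    }
    W1 <- mk(dims[[1]], C)
    W2 <- mk(dims[[2]], C)
    W3 <- mk(dims[[3]], 1L)
  })
  structure(list(spec = spec,
                 W = list(W1, W2, W3),
                 b = list(matrix(0, spec$hidden[1], C),
                          matrix(0, spec$hidden[2], C),
                          matrix(0, n_outputs(spec), 1L)),
                 center = rep(0, spec$n_inputs),
                 scale = rep(1, spec$n_inputs),
                 classes = NULL, history = NULL, fitted = FALSE),
            class = "epitrait_net")
}

# channel c of a (fan_in x units x channels) weight array, kept as a matrix
ch_mat <- function(W, c = 1L) matrix(W[, , c], dim(W)[1], dim(W)[2])

act_apply <- function(z, activation) {
  switch(activation, tanh = tanh(z), rectifier = pmax(z, 0), z)
}
act_grad <- function(z, a, activation) {
  switch(activation, tanh = 1 - a^2, rectifier = (z > 0) + 0, NULL)
}

# Forward through one hidden layer; returns activation, pre-activation (or
# argmax channel for maxout) for backprop.
hidden_forward <- function(A_prev, W, b, activation) {
  C <- dim(W)[3]
  if (activation != "maxout") {
    Z <- A_prev %*% ch_mat(W) + matrix(b[, 1L], nrow(A_prev), dim(W)[2], byrow = TRUE)
    list(A = act_apply(Z, activation), Z = Z, K = NULL)
  } else {
    n <- nrow(A_prev); h <- dim(W)[2]
    A <- matrix(-Inf, n, h); K <- matrix(1L, n, h)
    for (c in seq_len(C)) {
      Zc <- A_prev %*% ch_mat(W, c) + matrix(b[, c], n, h, byrow = TRUE)
      upd <- Zc > A
      A[upd] <- Zc[upd]
      K[upd] <- c
    }
    list(A = A, Z = NULL, K = K)
  }
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Forward pass
#'
#' Standardizes raw inputs with the model's stored per-feature center and
#' scale, propagates through both hidden layers, and applies softmax
#' (classification) or identity (regression) at the output. Dropout masks
#' are applied only when \code{training = TRUE}, with inverted-dropout
#' rescaling so inference needs none.
#'
#' @param model \code{epitrait_net}.
#' @param X numeric matrix (samples x features), raw scale.
#' @param training logical; resample and apply dropout masks.
#' @return list with \code{output} (probabilities or regression values) and
#'   the layer activations.
#' @export
nn_forward <- function(model, X, training = FALSE) {
  spec <- model$spec
  if (ncol(X) != spec$n_inputs) stop_cfg("input has %d features; model expects %d",
                                         ncol(X), spec$n_inputs)
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, `/`)
  drop_mask <- function(nr, nc, p) {
    if (!training || p <= 0) return(NULL)
    matrix((runif(nr * nc) >= p) / (1 - p), nr, nc)
  }
  M0 <- drop_mask(nrow(Xs), ncol(Xs), spec$input_dropout)
  X0 <- if (is.null(M0)) Xs else Xs * M0
  L1 <- hidden_forward(X0, model$W[[1]], model$b[[1]], spec$activation)
  M1 <- drop_mask(nrow(L1$A), ncol(L1$A), spec$hidden_dropout)
  A1 <- if (is.null(M1)) L1$A else L1$A * M1
  L2 <- hidden_forward(A1, model$W[[2]], model$b[[2]], spec$activation)
  M2 <- drop_mask(nrow(L2$A), ncol(L2$A), spec$hidden_dropout)
  A2 <- if (is.null(M2)) L2$A else L2$A * M2
  Zout <- A2 %*% ch_mat(model$W[[3]]) +
    matrix(model$b[[3]][, 1L], nrow(A2), n_outputs(spec), byrow = TRUE)
  out <- if (spec$task == "classification") softmax_rows(Zout) else Zout[, 1L]
  list(output = out, Zout = Zout, X0 = X0, L1 = L1, A1 = A1, L2 = L2, A2 = A2,
       M0 = M0, M1 = M1, M2 = M2)
}

one_hot <- function(y, classes) {
  Y <- matrix(0, length(y), length(classes))
  Y[cbind(seq_along(y), match(as.character(y), classes))] <- 1
  Y
}

penalty <- function(model) {
  w <- unlist(lapply(model$W, as.vector))
  model$spec$l1 * sum(abs(w)) + model$spec$l2 * sum(w^2)
}

#' Training loss
#'
#' Mean cross-entropy (classification, probabilities clipped at 1e-15) or
#' mean squared error (regression), plus the L1/L2 penalty over all weight
#' matrices (biases unpenalized).
#'
#' @param model \code{epitrait_net}.
#' @param X inputs (raw scale).
#' @param y labels (factor/character) or numeric response.
#' @return scalar loss.
#' @export
nn_loss <- function(model, X, y) {
  fw <- nn_forward(model, X, training = FALSE)
  data_loss(model, fw$output, y) + penalty(model)
}

data_loss <- function(model, output, y) {
  if (model$spec$task == "classification") {
    classes <- model$classes %||% sort(unique(as.character(y)))
    p <- output[cbind(seq_along(y), match(as.character(y), classes))]
    -mean(log(pmax(p, 1e-15)))
  } else {
    mean((output - y)^2)
  }
}

# Analytic gradients of nn_loss via backpropagation. With training = TRUE
# the dropout masks sampled in the forward pass are honoured.
nn_gradients <- function(model, X, y, training = FALSE, fw = NULL) {
  spec <- model$spec
  if (is.null(fw)) fw <- nn_forward(model, X, training = training)
  n <- nrow(X)
  if (spec$task == "classification") {
    classes <- model$classes %||% sort(unique(as.character(y)))
    dZout <- (fw$output - one_hot(y, classes)) / n
  } else {
    dZout <- matrix(2 * (fw$output - y) / n, ncol = 1L)
  }
  gW3 <- array(crossprod(fw$A2, dZout), dim = dim(model$W[[3]]))
  gb3 <- matrix(colSums(dZout), ncol = 1L)
  dA2 <- dZout %*% t(ch_mat(model$W[[3]]))
  if (!is.null(fw$M2)) dA2 <- dA2 * fw$M2

  bp_hidden <- function(dA, L, A_prev, W) {
    C <- dim(W)[3]
    gW <- array(0, dim = dim(W))
    gb <- matrix(0, dim(W)[2], C)
    if (spec$activation != "maxout") {
      dZ <- dA * act_grad(L$Z, L$A, spec$activation)
      gW[, , 1L] <- crossprod(A_prev, dZ)
      gb[, 1L] <- colSums(dZ)
      dPrev <- dZ %*% t(ch_mat(W))
    } else {
      dPrev <- matrix(0, nrow(dA), dim(W)[1])
      for (c in seq_len(C)) {
        dZc <- dA * (L$K == c)
        gW[, , c] <- crossprod(A_prev, dZc)
        gb[, c] <- colSums(dZc)
        dPrev <- dPrev + dZc %*% t(ch_mat(W, c))
      }
    }
    list(gW = gW, gb = gb, dPrev = dPrev)
  }

  h2 <- bp_hidden(dA2, fw$L2, fw$A1, model$W[[2]])
  dA1 <- h2$dPrev
  if (!is.null(fw$M1)) dA1 <- dA1 * fw$M1
  h1 <- bp_hidden(dA1, fw$L1, fw$X0, model$W[[1]])

  gW <- list(h1$gW, h2$gW, gW3)
  for (l in 1:3)
    gW[[l]] <- gW[[l]] + spec$l1 * sign(model$W[[l]]) + 2 * spec$l2 * model$W[[l]]
  list(W = gW, b = list(h1$gb, h2$gb, gb3))
}

#' Fit a network by minibatch stochastic gradient descent
#'
#' Standardization parameters are fitted on the training inputs; weights
#' are updated by backpropagated gradients (including the L1 subgradient
#' and L2 gradient, with dropout masks resampled per minibatch) under
#' Nesterov momentum and a polynomially annealed learning rate. Training
#' loss is recorded once per epoch. Deterministic given the spec seed.
#'
#' @param model unfitted model from [init_network()] (or a spec, which is
#'   initialized first).
#' @param X training inputs (samples x features, raw scale).
#' @param y class labels (factor/character) or numeric response.
#' @return fitted \code{epitrait_net} with \code{history} (loss per epoch).
#' @export
train_sgd <- function(model, X, y) {
  if (inherits(model, "nn_spec")) model <- init_network(model)
  spec <- model$spec
  if (nrow(X) < 2L) stop_cfg("need at least 2 training samples")
  if (spec$task == "classification") {
    model$classes <- sort(unique(as.character(y)))
    if (length(model$classes) > spec$n_classes)
      stop_cfg("found %d classes but spec declares %d", length(model$classes),
               spec$n_classes)
  }
  model$center <- colMeans(X)
  sds <- apply(X, 2, sd)
  model$scale <- ifelse(sds > 0, sds, 1)

  n <- nrow(X)
  vW <- lapply(model$W, function(w) array(0, dim = dim(w)))
  vb <- lapply(model$b, function(b) b * 0)
  mu <- spec$momentum
  history <- numeric(spec$epochs)
  iter <- 0L

  with_seed(spec$seed + 1L, {
    for (epoch in seq_len(spec$epochs)) {
      perm <- sample.int(n)
      starts <- seq(1L, n, by = spec$minibatch)
      for (s in starts) {
        idx <- perm[s:min(s + spec$minibatch - 1L, n)]
        iter <- iter + 1L
        lr <- spec$rate / (1 + spec$rate_annealing * iter)
        g <- nn_gradients(model, X[idx, , drop = FALSE],
                          if (is.matrix(y)) y[idx, ] else y[idx],
                          training = TRUE)
        for (l in 1:3) {
          # Nesterov momentum in its look-ahead-free rewrite
          vW_new <- mu * vW[[l]] - lr * g$W[[l]]
          model$W[[l]] <- model$W[[l]] - mu * vW[[l]] + (1 + mu) * vW_new
          vW[[l]] <- vW_new
          vb_new <- mu * vb[[l]] - lr * g$b[[l]]
          model$b[[l]] <- model$b[[l]] - mu * vb[[l]] + (1 + mu) * vb_new
          vb[[l]] <- vb_new
        }
      }
      history[epoch] <- nn_loss(model, X, y)
      if (!is.finite(history[epoch]))
        stop_cfg("training diverged (loss is not finite) at epoch %d; lower the learning rate",
                 epoch)
    }
  })
  model$history <- history
  model$fitted <- TRUE
  model
}

#' Predict from a fitted network
#'
#' @param object fitted \code{epitrait_net}.
#' @param X inputs (raw scale).
#' @param type "response" (class-probability matrix or regression values) or
#'   "class" (argmax labels; classification only).
#' @param ... unused.
#' @return probability matrix with one column per class, numeric vector for
#'   regression, or a character vector of labels.
#' @export
predict.epitrait_net <- function(object, X, type = c("response", "class"), ...) {
  type <- match.arg(type)
  fw <- nn_forward(object, X, training = FALSE)
  if (object$spec$task == "regression") return(fw$output)
  P <- fw$output
  colnames(P) <- object$classes
  rownames(P) <- rownames(X)
  if (type == "class") object$classes[max.col(P, ties.method = "first")] else P
}

#' @export
print.epitrait_net <- function(x, ...) {
  s <- x$spec
  cat(sprintf("%s network %d-%d-%d-%d (%s)%s\n",
              s$activation, s$n_inputs, s$hidden[1], s$hidden[2], n_outputs(s),
              s$task, if (x$fitted) sprintf(", fitted, final loss %.4g",
                                            tail(x$history, 1)) else ", unfitted"))
  invisible(x)
}

#' Export weights, biases and standardization as a lossless bundle
#'
#' @param model fitted \code{epitrait_net}.
#' @return list with the spec, flattened weight/bias arrays with their
#'   dimensions (the channel dimension is retained for maxout), the input
#'   standardization parameters and class levels. Re-importing via
#'   [import_weights_biases()] reproduces predictions exactly.
#' @export
export_weights_biases <- function(model) {
  pack <- function(a) list(data = as.vector(a), dim = dim(a))
  list(spec = unclass(model$spec),
       weights = lapply(model$W, pack),
       biases = lapply(model$b, pack),
       center = model$center, scale = model$scale,
       classes = model$classes, fitted = model$fitted)
}

#' @rdname export_weights_biases
#' @param bundle list from [export_weights_biases()] (or read from JSON).
#' @export
import_weights_biases <- function(bundle) {
  unpack <- function(p) {
    v <- unlist(p$data)
    if (is.character(v)) v <- as.numeric(v)
    array(v, dim = unlist(p$dim))
  }
  spec <- do.call(network_spec, lapply(bundle$spec, unlist))
  model <- init_network(spec)
  model$W <- lapply(bundle$weights, unpack)
  model$b <- lapply(bundle$biases, function(p) {
    b <- unpack(p)
    matrix(b, nrow = dim(b)[1])
  })
  as_num <- function(v) { v <- unlist(v); if (is.character(v)) as.numeric(v) else v }
  model$center <- as_num(bundle$center)
  model$scale <- as_num(bundle$scale)
  model$classes <- if (!is.null(bundle$classes)) unlist(bundle$classes)
  model$fitted <- isTRUE(bundle$fitted)
  model
}

#' @rdname export_weights_biases
#' @param path JSON file path.
#' @export
write_network <- function(model, path) {
  bundle <- export_weights_biases(model)
  # doubles as 17-significant-digit strings: lossless through JSON
  num2str <- function(x) sprintf("%.17g", x)
  bundle$weights <- lapply(bundle$weights, function(p)
    list(data = num2str(p$data), dim = p$dim))
  bundle$biases <- lapply(bundle$biases, function(p)
    list(data = num2str(p$data), dim = p$dim))
  bundle$center <- num2str(bundle$center)
  bundle$scale <- num2str(bundle$scale)
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname export_weights_biases
#' @export
read_network <- function(path) {
  import_weights_biases(jsonlite::read_json(path, simplifyVector = FALSE))
}
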