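# Shared fixtures: small synthetic studies and toy networks, all built in
# code at test time.

small_study <- function(seed = 7L, n_cpg = 1500L, planted = 40L, ...) {
  simulate_study(synthetic_config(
    n_cpg = n_cpg, n_tissue_cpg = planted, n_provenance_cpg = planted,
    n_trait_cpg = planted, seed = seed, ...))
}

null_study <- function(seed = 5L, n_cpg = 2000L, ...) {
  simulate_study(synthetic_config(
    n_cpg = n_cpg, n_tissue_cpg = 0L, n_provenance_cpg = 0L,
    n_trait_cpg = 0L, seed = seed, ...))
}

toy_classification <- function(n_per = 10L, seed = 1L, margin = 2) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(2 * n_per, -margin), n_per, 2),
             matrix(rnorm(2 * n_per, margin), n_per, 2))
  colnames(X) <- c("f1", "f2")
  list(X = X, y = rep(c("a", "b"), each = n_per))
}

# max relative error between backprop and central finite differences
finite_diff_check <- function(spec, n = 7L, seed = 3L, eps = 1e-5) {
  m <- init_network(spec)
  set.seed(seed)
  X <- matrix(rnorm(n * spec$n_inputs), n, spec$n_inputs)
  y <- if (spec$task == "classification")
    sample(letters[seq_len(spec$n_classes)], n, replace = TRUE)
  else rnorm(n)
  g <- epitrait:::nn_gradients(m, X, y)
  maxrel <- 0
  for (l in 1:3) for (part in c("W", "b")) {
    arr <- m[[part]][[l]]
    ga <- g[[part]][[l]]
    for (idx in seq_along(arr)) {
      mp <- m; mp[[part]][[l]][idx] <- arr[idx] + eps
      mm <- m; mm[[part]][[l]][idx] <- arr[idx] - eps
      num <- (nn_loss(mp, X, y) - nn_loss(mm, X, y)) / (2 * eps)
      denom <- max(abs(num), abs(ga[idx]), 1e-8)
      maxrel <- max(maxrel, abs(num - ga[idx]) / denom)
    }
  }
  maxrel
}

# independent step-up BH oracle (textbook arithmetic)
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[ord[i]] * m / i)
    q[ord[i]] <- prev
  }
  pmin(q, 1)
}
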