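test_that("Gedeon importance matches hand computation and its invariances", {
  # embed the 2-input, 2x2 hand example in minimal 4-unit layers
  m <- init_network(network_spec(2L, hidden = c(4L, 4L), seed = 1L))
  m$W[[1]][] <- 0; m$W[[1]][1, 1, 1] <- 1; m$W[[1]][2, 2, 1] <- 0.5
  m$W[[2]][] <- 0; m$W[[2]][1:2, 1:2, 1] <- 1
  imp <- gedeon_importance(m)
  expect_equal(unname(imp$scores), c(0.5, 0.5))
  expect_equal(sum(imp$scores), 1, tolerance = 1e-12)
  # per-layer positive rescaling leaves scores unchanged
  m2 <- m; m2$W[[1]] <- 7 * m2$W[[1]]; m2$W[[2]] <- 0.3 * m2$W[[2]]
  expect_equal(gedeon_importance(m2)$scores, imp$scores, tolerance = 1e-12)
  # an input with all-zero outgoing weights scores 0
  m3 <- init_network(network_spec(3L, hidden = c(4L, 4L), seed = 2L))
  m3$W[[1]][3, , ] <- 0
  expect_equal(unname(gedeon_importance(m3)$scores[3]), 0)
  # single input takes the whole mass
  m4 <- init_network(network_spec(1L, hidden = c(4L, 4L), seed = 3L))
  expect_equal(unname(gedeon_importance(m4)$scores), 1)
  # maxout uses channel-wise maximum magnitude
  m5 <- init_network(network_spec(2L, hidden = c(4L, 4L), activation = "maxout",
                                  seed = 4L))
  expect_equal(sum(gedeon_importance(m5)$scores), 1, tolerance = 1e-12)
})

test_that("a dominant planted input wins the importance ranking", {
  wins <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 40
    X <- matrix(rnorm(n * 5), n, 5,
                dimnames = list(NULL, paste0("cpg", 1:5)))
    y <- ifelse(10 * X[, 3] + rnorm(n, sd = 0.5) > 0, "a", "b")
    fit <- train_sgd(network_spec(5L, hidden = c(6L, 6L), epochs = 200L,
                                  seed = s), X, y)
    fit$input_ids <- colnames(X)
    gedeon_importance(fit)$order[1] == "cpg3"
  }, TRUE)
  expect_gte(sum(wins), 9)
})

test_that("elimination schedules follow the 5% rule and validate input", {
  sched <- elimination_schedule(600L, fraction = 0.05, min_size = 400L)
  expect_equal(sched[1:2], c(600L, 570L))
  expect_true(all(diff(sched) < 0))
  expect_error(backward_eliminate(matrix(1, 4, 3,
                                         dimnames = list(NULL, c("a", "b", "c"))),
                                  1:4, schedule = c(3L, 4L)), "decreasing")
})

test_that("backward elimination nests selections and records every step", {
  st <- small_study(seed = 12L, n_cpg = 800L, planted = 30L)
  m <- impute_missing(st$matrix)
  md <- st$metadata
  res <- suppressWarnings(test_all_cpg(m, md$sample_id[md$tissue == "X"],
                                       md$sample_id[md$tissue == "L"]))
  sel <- select_to_count(res, 20L, tolerance = 10L)
  X <- m[, sel$position_ids, drop = FALSE]
  y <- md$tissue
  trace <- backward_eliminate(X, y, schedule = c(ncol(X), 12L, 6L),
                              grid = list(hidden = list(c(8L, 8L)),
                                          epochs = 200L),
                              task = "classification", k = 4L, seed = 1L)
  expect_length(trace, 3)
  expect_equal(vapply(trace, `[[`, 0L, "n_inputs"), c(ncol(X), 12L, 6L))
  # each step's selection nests in the previous one
  for (s in 2:3)
    expect_true(all(trace[[s]]$selection %in% trace[[s - 1]]$selection))
  # schedule [n]: identity selection
  t1 <- backward_eliminate(X[, 1:10], y, schedule = 10L,
                           grid = list(hidden = list(c(4L, 4L)), epochs = 200L),
                           task = "classification", k = 4L, seed = 1L)
  expect_length(t1, 1)
  expect_setequal(t1[[1]]$selection, colnames(X)[1:10])
})

test_that("profile curves emit the exact permutation grid per input", {
  toy <- toy_classification(n_per = 10L, seed = 6L)
  fit <- train_sgd(network_spec(2L, hidden = c(6L, 6L), epochs = 200L,
                                seed = 6L), toy$X, toy$y)
  fit$input_ids <- colnames(toy$X)
  pc <- profile_curves(fit, toy$X)
  expect_equal(nrow(pc), 2 * 9801)
  expect_equal(unname(table(pc$input_id)), rep(9801, 2), ignore_attr = TRUE)
  # focal values nondecreasing in the focal quantile
  one <- pc[pc$input_id == "f1" & pc$qb == pc$qb[1], ]
  expect_true(!is.unsorted(one$focal_value))
  # classification activations sum to one on every row
  expect_equal(pc$prob_a + pc$prob_b, rep(1, nrow(pc)), tolerance = 1e-12)
  # an ignored input yields flat curves at fixed background quantile
  dead <- fit
  dead$W[[1]][2, , ] <- 0
  pcd <- profile_curves(dead, toy$X)
  flat <- pcd[pcd$input_id == "f2" & pcd$qb == 0.5, ]
  expect_lt(diff(range(flat$prob_a)), 1e-12)
  # regression models record a single output column
  yq <- as.numeric(toy$X[, 1]) * 2
  fr <- train_sgd(network_spec(2L, hidden = c(6L, 6L), task = "regression",
                               epochs = 200L, seed = 7L), toy$X, yq)
  fr$input_ids <- colnames(toy$X)
  pr <- profile_curves(fr, toy$X)
  expect_true("output" %in% names(pr))
  expect_equal(nrow(pr), 2 * 9801)
})

test_that("diagram data mirrors the network structure and importance order", {
  toy <- toy_classification(n_per = 8L, seed = 8L)
  fit <- train_sgd(network_spec(2L, hidden = c(4L, 5L), epochs = 200L,
                                seed = 8L), toy$X, toy$y)
  fit$input_ids <- colnames(toy$X)
  imp <- gedeon_importance(fit)
  dg <- diagram_data(fit, imp)
  n_edges <- 2 * 4 + 4 * 5 + 5 * 2 + 4 + 5 + 2  # weights plus bias edges
  expect_equal(nrow(dg$edges), n_edges)
  expect_setequal(unique(dg$edges$sign), c("stimulatory", "inhibitory"))
  inputs <- dg$nodes[dg$nodes$type == "input", ]
  expect_equal(inputs$id, imp$order)
  expect_true(!is.unsorted(rev(inputs$importance)))
  # all-positive weights leave no inhibitory edges
  pos <- fit
  for (l in 1:3) pos$W[[l]] <- abs(pos$W[[l]])
  for (l in 1:3) pos$b[[l]] <- abs(pos$b[[l]])
  dgp <- diagram_data(pos, gedeon_importance(pos))
  expect_false("inhibitory" %in% dgp$edges$sign)
})
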