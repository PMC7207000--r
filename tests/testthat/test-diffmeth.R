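test_that("Welch statistic matches the hand formula and t.test oracle", {
  res <- welch_t(c(10, 20, 30), c(40, 50, 60))
  expect_equal(round(res$t, 3), -3.674)
  expect_equal(round(res$df, 3), 4)
  # identical groups give t = 0; antisymmetry under group exchange
  expect_equal(welch_t(c(5, 10, 15), c(5, 10, 15))$t, 0)
  a <- rnorm(5); b <- rnorm(7)
  expect_equal(welch_t(a, b)$t, -welch_t(b, a)$t)
  # 1000 random small instances against stats::t.test
  set.seed(42)
  for (i in 1:1000) {
    na <- sample(2:8, 1); nb <- sample(2:8, 1)
    a <- rnorm(na, sd = runif(1, 0.5, 3)); b <- rnorm(nb, 2, 1)
    mine <- welch_t(a, b)
    ref <- stats::t.test(a, b, var.equal = FALSE)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  }
  expect_error(welch_t(c(1, 1), c(1, 1)), "zero variance")
  expect_error(welch_t(1, c(1, 2)), "at least 2")
})

test_that("BH adjustment matches an independent step-up oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(7)
  for (i in 1:50) {
    p <- runif(sample(1:200, 1))
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
    # permutation equivariance
    perm <- sample(length(p))
    expect_equal(bh_fdr(p[perm]), bh_fdr(p)[perm])
  }
})

test_that("matrix-wide tests agree with per-column Welch tests", {
  st <- null_study(seed = 2L, n_cpg = 60L, missing_rate = 0)
  m <- st$matrix
  md <- st$metadata
  ga <- md$sample_id[md$tissue == "X"][1:6]
  gb <- md$sample_id[md$tissue == "L"][1:6]
  res <- suppressWarnings(test_all_cpg(m, ga, gb))
  expect_equal(nrow(res), ncol(m))
  ok <- which(!is.na(res$t))
  for (j in sample(ok, 10)) {
    ref <- welch_t(m[ga, j], m[gb, j])
    expect_equal(res$t[j], ref$t, tolerance = 1e-12)
    expect_equal(res$p[j], ref$p, tolerance = 1e-12)
  }
  expect_equal(res$q[ok], bh_fdr(res$p[ok]))
  expect_true(all(res$q >= res$p, na.rm = TRUE))
  expect_error(test_all_cpg(m, ga, c(gb, ga[1])), "disjoint")
  # single-column family: q equals p
  r1 <- test_all_cpg(m[, 1, drop = FALSE], ga, gb)
  expect_equal(r1$q, r1$p)
})

test_that("empirical type-I error is calibrated on the synthetic null", {
  st <- null_study(seed = 5L, n_cpg = 10000L)
  m <- impute_missing(st$matrix)
  md <- st$metadata
  res <- suppressWarnings(test_all_cpg(m, md$sample_id[md$tissue == "X"],
                                       md$sample_id[md$tissue == "L"]))
  expect_lt(abs(mean(res$p <= 0.01, na.rm = TRUE) - 0.01), 0.005)
})

test_that("significance selection filters, orders and stays monotone", {
  st <- small_study(seed = 3L, n_cpg = 1000L, planted = 30L)
  m <- impute_missing(st$matrix)
  md <- st$metadata
  res <- suppressWarnings(test_all_cpg(m, md$sample_id[md$tissue == "X"],
                                       md$sample_id[md$tissue == "L"]))
  sel <- select_by_significance(res, alpha = 0.01, fdr_cutoff = 1)
  expect_equal(length(sel$position_ids), sum(res$p <= 0.01, na.rm = TRUE))
  expect_true(!is.unsorted(sel$stats$q))
  expect_warning(select_by_significance(res, fdr_cutoff = 0), "empty")
  # tightening the cutoff never grows the selection
  sizes <- vapply(c(1, 0.1, 0.01, 0.001, 1e-4), function(fc)
    length(suppressWarnings(select_by_significance(res, fdr_cutoff = fc))$position_ids), 0)
  expect_true(all(diff(sizes) <= 0))
  # planted CpG carry smaller q than the median null q; CpG planted at
  # extreme baselines (near 0/100% methylation) are allowed to escape, as
  # a percentage-point shift there is compressed by the unit interval
  nulls <- setdiff(res$position_id, unlist(st$truth[c("tissue", "provenance", "trait")]))
  med_null <- stats::median(res$q[res$position_id %in% nulls], na.rm = TRUE)
  expect_gte(mean(res$q[res$position_id %in% st$truth$tissue] < med_null), 0.9)
})

test_that("count-targeted selection hits its target or reports bounds", {
  st <- small_study(seed = 6L, n_cpg = 2000L, planted = 60L)
  m <- impute_missing(st$matrix)
  md <- st$metadata
  res <- suppressWarnings(test_all_cpg(m, md$sample_id[md$tissue == "X"],
                                       md$sample_id[md$tissue == "L"]))
  sel <- select_to_count(res, target = 40L, tolerance = 10L)
  expect_true(abs(length(sel$position_ids) - 40) <= 10)
  expect_true(all(sel$stats$p <= 0.01))
  expect_true(is.finite(sel$selection_params$fdr_cutoff))
  # all eligible positions when target equals their count, tolerance 0
  n_elig <- sum(res$p <= 0.01, na.rm = TRUE)
  sel_all <- select_to_count(res, target = n_elig, tolerance = 0L)
  expect_length(sel_all$position_ids, n_elig)
  expect_error(select_to_count(res, target = 1e6), "exceeds")
})

test_that("mean dichotomization sends boundary values to the low group", {
  sp <- dichotomize_at_mean(stats::setNames(c(1, 2, 3, 4), letters[1:4]))
  expect_setequal(sp$high, c("c", "d"))
  expect_setequal(sp$low, c("a", "b"))
  sp2 <- dichotomize_at_mean(stats::setNames(c(0, 0, 10, 10), letters[1:4]))
  expect_setequal(sp2$high, c("c", "d"))
  sp3 <- dichotomize_at_mean(stats::setNames(c(1, 2, 3, 2), letters[1:4]))
  expect_true("b" %in% sp3$low)  # exactly at the mean -> low
  expect_error(dichotomize_at_mean(c(1, 2, 3)), "at least 4")
  expect_error(dichotomize_at_mean(rep(2, 5)), "equal")
})

test_that("pooled selection keeps first occurrences up to the counts", {
  selA <- epitrait:::new_selection(paste0("Chr01.", 1:500), "differential")
  selB <- epitrait:::new_selection(paste0("Chr02.", 1:100), "differential")
  pool <- pooled_selection(list(selA, selB), c(500L, 100L))
  expect_length(pool$position_ids, 600)
  expect_equal(pool$origin, "pooled")
  # overlap deduplicates, first occurrence kept
  selC <- epitrait:::new_selection(paste0("Chr01.", 401:500), "differential")
  pool2 <- pooled_selection(list(selA, selC), c(500L, 100L))
  expect_length(pool2$position_ids, 500)
  expect_identical(pooled_selection(list(selA), 10L)$position_ids,
                   selA$position_ids[1:10])
  expect_error(pooled_selection(list(selB), 500L), "exceeds")
})

test_that("selections serialize as ranked TSV with a parameter sidecar", {
  st <- small_study(seed = 3L, n_cpg = 500L, planted = 20L)
  m <- impute_missing(st$matrix)
  md <- st$metadata
  res <- suppressWarnings(test_all_cpg(m, md$sample_id[md$tissue == "X"],
                                       md$sample_id[md$tissue == "L"]))
  sel <- select_by_significance(res, alpha = 0.01, fdr_cutoff = 0.5)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_selection(sel, f)
  back <- data.table::fread(f)
  expect_equal(back$position_id, sel$position_ids)
  expect_equal(back$rank, seq_along(sel$position_ids))
  expect_true(all(c("t", "df", "p", "q") %in% names(back)))
  side <- jsonlite::read_json(paste0(f, ".json"), simplifyVector = TRUE)
  expect_equal(side$origin, "differential")
  expect_equal(side$alpha, 0.01)
})

test_that("random selections are seed-deterministic with small overlap", {
  uni <- paste0("Chr01.", 1:10000)
  s1 <- random_selection(uni, 14L, seed = 1L)
  expect_identical(s1$position_ids, random_selection(uni, 14L, seed = 1L)$position_ids)
  picks <- lapply(1:3, function(s) random_selection(uni, 14L, seed = s)$position_ids)
  for (i in 1:2) for (j in (i + 1):3)
    expect_lte(length(intersect(picks[[i]], picks[[j]])), 2)
  all_of_it <- random_selection(uni[1:20], 20L, seed = 2L)
  expect_setequal(all_of_it$position_ids, uni[1:20])
  expect_error(random_selection(uni[1:5], 10L, seed = 1L), "universe")
})
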