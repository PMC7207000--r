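test_that("simulation is deterministic and respects its configuration", {
  cfg <- synthetic_config(n_cpg = 800L, n_tissue_cpg = 20L,
                          n_provenance_cpg = 20L, n_trait_cpg = 20L, seed = 2L)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$matrix, s2$matrix)
  expect_identical(s1$traits, s2$traits)
  expect_equal(nrow(s1$matrix), 9 * 2 * 2 * 2)
  expect_equal(ncol(s1$matrix), 800)
  # causal sets disjoint and valid columns
  truth <- unlist(s1$truth[c("tissue", "provenance", "trait")])
  expect_equal(anyDuplicated(truth), 0)
  expect_true(all(truth %in% colnames(s1$matrix)))
  # intensities live on the percent scale
  expect_true(all(s1$matrix >= 0 & s1$matrix <= 100, na.rm = TRUE))
})

test_that("an empty genome yields a zero-column study", {
  st <- simulate_study(synthetic_config(n_cpg = 0L, n_tissue_cpg = 0L,
                                        n_provenance_cpg = 0L, n_trait_cpg = 0L))
  expect_equal(ncol(st$matrix), 0)
  expect_length(st$truth$tissue, 0)
  expect_equal(nrow(st$matrix), nrow(st$metadata))
})

test_that("configurations load from YAML and JSON files", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_cpg: 500", "n_tissue_cpg: 10", "n_provenance_cpg: 0",
               "n_trait_cpg: 0", "tissue_effect: 30", "seed: 3"), f)
  cfg <- read_synthetic_config(f)
  expect_s3_class(cfg, "epitrait_config")
  expect_equal(cfg$n_cpg, 500L)
  expect_equal(cfg$tissue_effect, 30)
  expect_identical(simulate_study(cfg)$matrix,
                   simulate_study(synthetic_config(n_cpg = 500L,
                                                   n_tissue_cpg = 10L,
                                                   n_provenance_cpg = 0L,
                                                   n_trait_cpg = 0L,
                                                   tissue_effect = 30,
                                                   seed = 3L))$matrix)
  j <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(n_cpg = 200, n_tissue_cpg = 0,
                            n_provenance_cpg = 0, n_trait_cpg = 0), j,
                       auto_unbox = TRUE)
  expect_equal(read_synthetic_config(j)$n_cpg, 200L)
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(n_cpg = 10L, n_tissue_cpg = 20L,
                                n_provenance_cpg = 0L, n_trait_cpg = 0L),
               "exceed")
  expect_error(synthetic_config(missing_rate = 1), "missing_rate")
  expect_error(synthetic_config(n_cpg = -5L), "nonnegative")
  expect_error(synthetic_config(trait_tissue = "Z"), "tissue")
})

test_that("null study p-values are approximately uniform", {
  # no planted effects; arbitrary balanced grouping of 20 methylomes
  st <- null_study(seed = 3L, n_cpg = 2000L, n_provenances = 5L,
                   genotypes_per_provenance = 1L, sites = c("IH", "PA"),
                   missing_rate = 0)
  m <- impute_missing(st$matrix)
  ids <- rownames(m)
  res <- suppressWarnings(test_all_cpg(m, ids[seq(1, 20, 2)], ids[seq(2, 20, 2)]))
  p <- res$p[!is.na(res$p)]
  expect_gt(suppressWarnings(stats::ks.test(p, "punif"))$p.value, 0.01)
})

test_that("overall missingness tracks the configured rate", {
  st <- simulate_study(synthetic_config(n_cpg = 5000L, n_tissue_cpg = 0L,
                                        n_provenance_cpg = 0L, n_trait_cpg = 0L,
                                        missing_rate = 0.031, mean_coverage = 30,
                                        seed = 9L))
  expect_lt(abs(mean(is.na(st$matrix)) - 0.031), 0.01)
})

test_that("planted tissue CpG dominate the differential ranking", {
  # effect 25 points, coverage 30, 72 samples: planted CpG should rank in
  # the top 2 * n_tissue_cpg by p-value in the vast majority of draws
  fracs <- vapply(1:10, function(s) {
    st <- simulate_study(synthetic_config(n_cpg = 2000L, n_tissue_cpg = 40L,
                                          n_provenance_cpg = 0L, n_trait_cpg = 0L,
                                          seed = s))
    m <- impute_missing(st$matrix)
    md <- st$metadata
    res <- suppressWarnings(test_all_cpg(m, md$sample_id[md$tissue == "X"],
                                         md$sample_id[md$tissue == "L"]))
    top <- res$position_id[order(res$p)][seq_len(80)]
    mean(st$truth$tissue %in% top)
  }, 0)
  expect_true(all(fracs >= 0.8))
})

test_that("the trait regresses on its causal methylation with high r2", {
  # noise well below the causal signal sd
  st <- simulate_study(synthetic_config(n_cpg = 2000L, n_tissue_cpg = 0L,
                                        n_provenance_cpg = 0L, n_trait_cpg = 60L,
                                        trait_noise_sd = 0.5, seed = 8L))
  score <- rowMeans(st$matrix[, st$truth$trait], na.rm = TRUE)
  tree <- paste0(st$metadata$provenance, st$metadata$genotype, st$metadata$site)
  tree_score <- tapply(score, tree, mean)
  fit <- stats::lm(st$traits$biomass ~ tree_score[st$traits$tree_id])
  expect_gte(summary(fit)$r.squared, 0.8)
})

test_that("cytosine reports round-trip through the io module exactly", {
  st <- small_study(seed = 4L, n_cpg = 400L, planted = 10L)
  d <- withr::local_tempdir()
  files <- write_cytosine_reports(st, d)
  expect_length(files, nrow(st$metadata))
  m2 <- import_cytosine_reports(d)
  m2 <- m2[rownames(st$matrix), , drop = FALSE]
  expect_identical(dim(m2), dim(st$matrix))
  expect_equal(m2, st$matrix, tolerance = 0)
  # a missing cell is absent from its sample's file
  miss <- which(is.na(st$counts$coverage), arr.ind = TRUE)[1, ]
  sid <- rownames(st$matrix)[miss[1]]
  pos <- st$positions$pos[miss[2]]
  chrom <- st$positions$chrom[miss[2]]
  rep_dt <- read_cytosine_report(file.path(d, paste0(sid, ".CpG_report.txt")))
  expect_false(any(rep_dt$chrom == chrom & rep_dt$pos == pos))
})

test_that("report file count follows the factorial design", {
  st <- simulate_study(synthetic_config(n_provenances = 3L,
                                        genotypes_per_provenance = 2L,
                                        n_cpg = 50L, n_tissue_cpg = 0L,
                                        n_provenance_cpg = 0L, n_trait_cpg = 0L))
  d <- withr::local_tempdir()
  files <- write_cytosine_reports(st, d)
  expect_length(files, 3 * 2 * 2 * 2)
  meta <- parse_sample_name(sub("\\.CpG_report\\.txt$", "", basename(files)))
  expect_equal(sort(meta$sample_id), sort(st$metadata$sample_id))
})
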