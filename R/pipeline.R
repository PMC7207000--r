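# End-to-end orchestration: genotype-level train/test splits, the
# classification and regression workflows with a leakage audit, and a
# batch suite runner.

#' Genotype-level train/test split
#'
#' One randomly chosen genotype per provenance is assigned to the test set
#' together with all of its methylomes (both sites, both tissues, mature
#' and replicate samples), so no test genotype leaks into training.
#' Provenances with a single genotype contribute no test genotype (they are
#' logged, mirroring the one-provenance exception in the field study).
#' The rule \code{"full-data-cv"} trains on everything with an empty test
#' set; reports built from it carry an explicit leakage warning.
#'
#' @param metadata sample metadata (as from [parse_sample_name()] rows or a
#'   study's \code{metadata}).
#' @param rule "one-genotype-per-provenance" or "full-data-cv".
#' @param seed split seed; alternate splits come from distinct seeds.
#' @return object of class \code{study_design} with \code{train_ids},
#'   \code{test_ids}, \code{test_genotypes}, \code{rule}, \code{seed}.
#' @export
make_split <- function(metadata, rule = c("one-genotype-per-provenance",
                                          "full-data-cv"), seed = 1L) {
  rule <- match.arg(rule)
  if (rule == "full-data-cv") {
    return(structure(list(split_id = sprintf("full-data-cv"),
                          train_ids = metadata$sample_id,
                          test_ids = character(0), test_genotypes = NULL,
                          rule = rule, seed = seed,
                          leakage_note = "full-data CV: no held-out genotypes; metrics are not test-set estimates"),
                     class = "study_design"))
  }
  gt <- unique(metadata[, c("provenance", "genotype")])
  per_prov <- split(gt$genotype, gt$provenance)
  eligible <- names(per_prov)[vapply(per_prov, length, 0L) >= 2L]
  if (length(eligible) < 2L)
    stop_cfg("rule needs at least 2 provenances with >= 2 genotypes each")
  skipped <- setdiff(names(per_prov), eligible)
  if (length(skipped))
    message("provenance(s) with a single genotype contribute no test genotype: ",
            paste(skipped, collapse = ", "))
  test_geno <- with_seed(seed, sapply(per_prov[eligible], function(g)
    g[sample.int(length(g), 1L)]))
  key <- paste0(metadata$provenance, ".", metadata$genotype)
  test_key <- paste0(eligible, ".", test_geno)
  is_test <- key %in% test_key
  structure(list(split_id = sprintf("split-seed%d", seed),
                 train_ids = metadata$sample_id[!is_test],
                 test_ids = metadata$sample_id[is_test],
                 test_genotypes = data.frame(provenance = eligible,
                                             genotype = unname(test_geno)),
                 rule = rule, seed = seed, leakage_note = NULL),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("Study design %s: %d training / %d test methylomes\n",
              x$split_id, length(x$train_ids), length(x$test_ids)))
  invisible(x)
}

#' Task configuration for the modelling workflows
#'
#' @param task one of "tissue", "provenance", "biomass", "density",
#'   "soluble_lignin", "mannose".
#' @param tissue_subset "mixed" (all methylomes), "xylem" or "leaf".
#' @param feature_source list: \code{list(type = "differential", target =,
#'   tolerance =)}, \code{list(type = "random", n =, seed =)}, or
#'   \code{list(type = "fixed", positions =)}.
#' @param grid hyperparameter grid for [grid_search()].
#' @param k CV folds (default 7).
#' @param seed task seed.
#' @param ... fixed [network_spec()] arguments forwarded to the search.
#' @return list of class \code{task_config}.
#' @export
task_config <- function(task = c("tissue", "provenance", "biomass", "density",
                                 "soluble_lignin", "mannose"),
                        tissue_subset = c("mixed", "xylem", "leaf"),
                        feature_source = list(type = "differential",
                                              target = 200L, tolerance = 50L),
                        grid = list(), k = 7L, seed = 1L, ...) {
  structure(list(task = match.arg(task), tissue_subset = match.arg(tissue_subset),
                 feature_source = feature_source, grid = grid, k = as.integer(k),
                 seed = as.integer(seed), spec_args = list(...)),
            class = "task_config")
}

tissue_rows <- function(metadata, subset) {
  switch(subset,
         mixed = metadata$sample_id,
         xylem = metadata$sample_id[metadata$tissue == "X"],
         leaf = metadata$sample_id[metadata$tissue == "L"])
}

audit_entry <- function(audit, stage, sample_ids) {
  audit[[length(audit) + 1L]] <- list(stage = stage, sample_ids = sample_ids)
  audit
}

#' Check a task report's leakage audit
#'
#' Every training-time statistic (imputation, feature selection,
#' standardization, hyperparameter choice) must have been computed from
#' training samples only; test-prefixed stages may use test samples only.
#'
#' @param report a \code{task_report}.
#' @return TRUE if clean, otherwise a character vector describing the
#'   violating stages.
#' @export
leakage_audit <- function(report) {
  train <- report$design$train_ids
  test <- report$design$test_ids
  bad <- character(0)
  for (e in report$audit) {
    allowed <- if (grepl("^test_", e$stage)) test else train
    extra <- setdiff(e$sample_ids, allowed)
    if (length(extra))
      bad <- c(bad, sprintf("%s used out-of-scope samples: %s", e$stage,
                            paste(head(extra, 5), collapse = ", ")))
  }
  if (length(bad)) bad else TRUE
}

select_features <- function(train_mat, labels, traits_by_sample, config, audit) {
  fs <- config$feature_source
  train_ids <- rownames(train_mat)
  if (fs$type == "random") {
    sel <- random_selection(colnames(train_mat), fs$n, fs$seed %||% config$seed)
  } else if (fs$type == "fixed") {
    sel <- new_selection(fs$positions, "fixed")
  } else if (fs$type == "differential") {
    tol <- fs$tolerance %||% max(1L, fs$target %/% 10L)
    if (!is.null(labels)) {
      classes <- sort(unique(labels))
      if (length(classes) == 2L) {
        res <- test_all_cpg(train_mat, train_ids[labels == classes[1]],
                            train_ids[labels == classes[2]])
        sel <- select_to_count(res, fs$target, tol)
      } else {
        # multiclass: pool equal shares from each one-vs-rest comparison
        share <- fs$target %/% length(classes)
        sels <- lapply(classes, function(cl) {
          res <- test_all_cpg(train_mat, train_ids[labels == cl],
                              train_ids[labels != cl])
          select_to_count(res, share, tol)
        })
        sel <- pooled_selection(sels, rep(share, length(classes)))
      }
    } else {
      split <- dichotomize_at_mean(traits_by_sample)
      res <- test_all_cpg(train_mat, split$high, split$low)
      sel <- select_to_count(res, fs$target, tol)
    }
  } else stop_cfg("unknown feature source type '%s'", fs$type)
  list(selection = sel,
       audit = audit_entry(audit, "feature_selection", train_ids))
}

finish_report <- function(design, config, sel, gs, train_mat, test_mat,
                          y_train, y_test, audit) {
  classify <- config$task %in% c("tissue", "provenance")
  best <- gs$best_model
  best$input_ids <- sel$position_ids
  test_metrics <- NULL; test_pred <- NULL; confusion <- NULL; scatter <- NULL
  if (!is.null(test_mat) && nrow(test_mat) > 0) {
    pred <- predict(best, test_mat)
    audit <- audit_entry(audit, "test_prediction_inputs", rownames(test_mat))
    test_metrics <- model_metrics(pred, y_test)
    if (classify) {
      confusion <- confusion_matrix(pred, y_test)
      p_true <- pred[cbind(seq_along(y_test),
                           match(as.character(y_test), colnames(pred)))]
      test_pred <- data.frame(sample_id = rownames(test_mat), truth = y_test,
                              predicted = colnames(pred)[max.col(pred, "first")],
                              p_misclassification = 1 - p_true)
      test_pred <- cbind(test_pred, pred)
    } else {
      test_pred <- data.frame(sample_id = rownames(test_mat),
                              observed = y_test, predicted = pred)
      scatter <- test_pred[, c("observed", "predicted")]
    }
  }
  structure(list(design = design, config = config, selection = sel,
                 leaderboard = gs$leaderboard, best_spec = gs$best_spec,
                 best_model = best, cv = gs$best_cv,
                 cv_confusion = gs$best_cv$confusion,
                 test_metrics = test_metrics, test_predictions = test_pred,
                 confusion = confusion, scatter = scatter,
                 importance = gedeon_importance(best), audit = audit,
                 leakage_note = design$leakage_note),
            class = "task_report")
}

#' Classification workflow (tissue or provenance)
#'
#' Imputes training and test sets separately, selects features on the
#' training data only (differential, random or fixed), runs a
#' hyperparameter grid search under k-fold cross-validation, refits the
#' winner on the full training set, and scores test predictions including
#' per-sample misclassification probabilities (1 - probability of the true
#' class). Every statistic's input sample set is recorded in an audit log.
#'
#' @param mat methylome matrix (all samples).
#' @param metadata sample metadata.
#' @param design a [make_split()] design.
#' @param config a [task_config()] with task "tissue" or "provenance".
#' @return object of class \code{task_report}.
#' @export
run_classification <- function(mat, metadata, design, config) {
  stopifnot(config$task %in% c("tissue", "provenance"))
  rows <- intersect(tissue_rows(metadata, config$tissue_subset), rownames(mat))
  train_ids <- intersect(design$train_ids, rows)
  test_ids <- intersect(design$test_ids, rows)
  label_of <- function(ids) {
    md <- metadata[match(ids, metadata$sample_id), ]
    if (config$task == "tissue") md$tissue else md$provenance
  }
  audit <- list()
  train_mat <- impute_missing(mat[train_ids, , drop = FALSE])
  audit <- audit_entry(audit, "imputation_train", train_ids)
  fs <- select_features(train_mat, label_of(train_ids), NULL, config, audit)
  audit <- fs$audit
  sel <- fs$selection
  if (length(sel$position_ids) == 0L) stop_cfg("feature selection is empty")
  Xtr <- train_mat[, sel$position_ids, drop = FALSE]
  ytr <- label_of(train_ids)
  audit <- audit_entry(audit, "standardization_and_grid", train_ids)
  gs <- do.call(grid_search,
                c(list(X = Xtr, y = ytr, grid = config$grid,
                       task = "classification",
                       n_classes = length(unique(ytr)), k = config$k,
                       seed = config$seed), config$spec_args))
  Xte <- NULL; yte <- NULL
  if (length(test_ids)) {
    test_mat <- impute_missing(mat[test_ids, sel$position_ids, drop = FALSE])
    audit <- audit_entry(audit, "test_imputation", test_ids)
    Xte <- test_mat
    yte <- label_of(test_ids)
  }
  finish_report(design, config, sel, gs, Xtr, Xte, ytr, yte, audit)
}

#' Regression workflow (biomass and wood traits)
#'
#' Training trees are dichotomized at the mean trait value; Welch tests
#' between the high and low methylome groups select the input CpG; the
#' grid search is scored by cross-validated MSE and the winner is scored
#' on the test set by r-squared / adjusted r-squared. The tissue subset is
#' applied to both selection and training.
#'
#' @param mat methylome matrix.
#' @param metadata sample metadata.
#' @param traits trait table, one row per (provenance, genotype, site) tree.
#' @param design a [make_split()] design.
#' @param config a [task_config()] with a quantitative task.
#' @return object of class \code{task_report}.
#' @export
run_regression <- function(mat, metadata, traits, design, config) {
  stopifnot(config$task %in% c("biomass", "density", "soluble_lignin", "mannose"))
  rows <- intersect(tissue_rows(metadata, config$tissue_subset), rownames(mat))
  trait_of <- function(ids) {
    md <- metadata[match(ids, metadata$sample_id), ]
    key <- paste0(md$provenance, md$genotype, md$site)
    tkey <- paste0(traits$provenance, traits$genotype, traits$site)
    stats::setNames(traits[[config$task]][match(key, tkey)], ids)
  }
  train_ids <- intersect(design$train_ids, rows)
  test_ids <- intersect(design$test_ids, rows)
  ytr <- trait_of(train_ids)
  if (anyNA(ytr)) stop_cfg("trait %s missing for some training samples", config$task)
  if (length(unique(ytr)) == 1L) stop_cfg("trait %s is constant", config$task)
  audit <- list()
  train_mat <- impute_missing(mat[train_ids, , drop = FALSE])
  audit <- audit_entry(audit, "imputation_train", train_ids)
  fs <- select_features(train_mat, NULL, ytr, config, audit)
  audit <- fs$audit
  sel <- fs$selection
  if (length(sel$position_ids) == 0L) stop_cfg("feature selection is empty")
  Xtr <- train_mat[, sel$position_ids, drop = FALSE]
  audit <- audit_entry(audit, "standardization_and_grid", train_ids)
  gs <- do.call(grid_search,
                c(list(X = Xtr, y = unname(ytr), grid = config$grid,
                       task = "regression", k = config$k, seed = config$seed),
                  config$spec_args))
  Xte <- NULL; yte <- NULL
  if (length(test_ids)) {
    Xte <- impute_missing(mat[test_ids, sel$position_ids, drop = FALSE])
    audit <- audit_entry(audit, "test_imputation", test_ids)
    yte <- unname(trait_of(test_ids))
  }
  finish_report(design, config, sel, gs, Xtr, Xte, unname(ytr), yte, audit)
}

#' @export
print.task_report <- function(x, ...) {
  cat(sprintf("Task '%s' (%s tissues), %d input CpG (%s)\n", x$config$task,
              x$config$tissue_subset, length(x$selection$position_ids),
              x$selection$origin))
  cat("  CV:  ", paste(names(x$cv$metrics), signif(unlist(x$cv$metrics), 4),
                       sep = " = ", collapse = ", "), "\n")
  if (!is.null(x$test_metrics))
    cat("  test:", paste(names(x$test_metrics), signif(unlist(x$test_metrics), 4),
                         sep = " = ", collapse = ", "), "\n")
  if (!is.null(x$leakage_note)) cat("  NOTE:", x$leakage_note, "\n")
  invisible(x)
}

#' Run a declared suite of tasks
#'
#' Executes tasks across splits from a YAML configuration (or an equivalent
#' list): simulates or loads the study, builds each split, runs each task,
#' writes per-task reports and a summary table. Task failures are recorded
#' and the suite continues.
#'
#' @param config path to a YAML file or a list with elements \code{seed},
#'   \code{study} (arguments for [synthetic_config()], or
#'   \code{matrix}/\code{metadata}/\code{traits} TSV paths),
#'   \code{splits} (list of \code{rule}/\code{seed}) and \code{tasks}
#'   (list of [task_config()] argument lists).
#' @param out_dir report directory (created); default \code{tempdir()}
#'   subdirectory.
#' @return list with \code{summary} (data.frame), \code{reports},
#'   \code{failures}; \code{n_failures} is the suggested exit status.
#' @export
run_suite <- function(config, out_dir = file.path(tempdir(), "epitrait-suite")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(config$study$matrix)) {
    mat <- read_methylome_matrix(config$study$matrix)
    metadata <- as.data.frame(data.table::fread(config$study$metadata))
    traits <- as.data.frame(data.table::fread(config$study$traits))
  } else {
    st_args <- config$study %||% list()
    if (is.null(st_args$seed)) st_args$seed <- seed
    study <- simulate_study(do.call(synthetic_config, st_args))
    mat <- study$matrix
    metadata <- study$metadata
    traits <- study$traits
  }
  splits <- config$splits %||% list(list(rule = "one-genotype-per-provenance",
                                         seed = seed))
  tasks <- config$tasks %||% list()
  rows <- list(); reports <- list(); failures <- list()
  for (sp in splits) {
    design <- make_split(metadata, rule = sp$rule %||% "one-genotype-per-provenance",
                         seed = sp$seed %||% seed)
    for (tk in tasks) {
      tk$seed <- tk$seed %||% seed
      if (!is.null(tk$feature_source)) tk$feature_source <-
          lapply(tk$feature_source, function(v) v)
      cfg <- do.call(task_config, tk)
      tag <- paste0(design$split_id, "_", cfg$task, "_", cfg$tissue_subset)
      res <- tryCatch({
        rep_ <- if (cfg$task %in% c("tissue", "provenance"))
          run_classification(mat, metadata, design, cfg)
        else run_regression(mat, metadata, traits, design, cfg)
        saveRDS_free_report(rep_, file.path(out_dir, paste0(tag, ".json")))
        reports[[tag]] <- rep_
        met <- c(unlist(rep_$cv$metrics),
                 if (!is.null(rep_$test_metrics))
                   stats::setNames(unlist(rep_$test_metrics),
                                   paste0("test_", names(rep_$test_metrics))))
        data.frame(split = design$split_id, task = cfg$task,
                   tissue_subset = cfg$tissue_subset,
                   n_features = length(rep_$selection$position_ids),
                   t(met))
      }, error = function(e) {
        failures[[tag]] <<- conditionMessage(e)
        NULL
      })
      if (!is.null(res)) rows[[tag]] <- res
    }
  }
  summary <- if (length(rows)) data.table::rbindlist(rows, fill = TRUE)
             else data.table::data.table()
  if (nrow(summary))
    data.table::fwrite(summary, file.path(out_dir, "summary.tsv"), sep = "\t")
  list(summary = as.data.frame(summary), reports = reports,
       failures = failures, n_failures = length(failures), out_dir = out_dir)
}

# Text-only report serialization (metrics, selection, leaderboard; weights
# go through write_network alongside).
saveRDS_free_report <- function(report, path) {
  slim <- list(task = report$config$task,
               tissue_subset = report$config$tissue_subset,
               split = report$design$split_id,
               n_features = length(report$selection$position_ids),
               selection = report$selection$position_ids,
               cv_metrics = report$cv$metrics,
               test_metrics = report$test_metrics,
               leaderboard = report$leaderboard,
               leakage_note = report$leakage_note,
               audit = report$audit)
  jsonlite::write_json(slim, path, auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(path)
}
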