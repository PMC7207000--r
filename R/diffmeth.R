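# Per-CpG differential methylation (Welch's t, BH-FDR) and the feature
# selection strategies built on it.

#' Welch's unequal-variance t-test
#'
#' \code{t = (mean(a) - mean(b)) / sqrt(s2a/na + s2b/nb)} with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value from
#' Student's t distribution.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return list with \code{t}, \code{df}, \code{p}.
#' @examples
#' welch_t(c(10, 20, 30), c(40, 50, 60))
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop_cfg("welch_t needs at least 2 values per group")
  va <- var(a); vb <- var(b)
  if (va == 0 && vb == 0)
    stop_cfg("undefined Welch statistic: zero variance in both groups")
  sa <- va / length(a); sb <- vb / length(b)
  tstat <- (mean(a) - mean(b)) / sqrt(sa + sb)
  df <- (sa + sb)^2 / (sa^2 / (length(a) - 1) + sb^2 / (length(b) - 1))
  list(t = tstat, df = df, p = 2 * pt(-abs(tstat), df))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment, clipped at 1, order-preserving
#' with the input.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return adjusted q-values, same order as input.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop_cfg("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Per-CpG Welch tests across a methylome matrix
#'
#' Runs Welch's t-test on every column between two disjoint sample groups
#' and adjusts p-values by Benjamini-Hochberg over the tested family.
#' Columns with zero variance in both groups have an undefined statistic;
#' they are skipped with a warning and excluded from the FDR family
#' (reported with NA statistics).
#'
#' @param mat methylome matrix (samples x positions), complete (imputed) for
#'   the rows used.
#' @param group_a,group_b disjoint vectors of sample ids, each >= 2.
#' @return data.frame with \code{position_id}, \code{t}, \code{df},
#'   \code{p}, \code{q}, one row per column in column order.
#' @export
test_all_cpg <- function(mat, group_a, group_b) {
  if (length(intersect(group_a, group_b)))
    stop_cfg("groups must be disjoint")
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop_cfg("each group needs at least 2 samples")
  miss <- setdiff(c(group_a, group_b), rownames(mat))
  if (length(miss)) stop_cfg("sample(s) not in matrix: %s", paste(miss, collapse = ", "))
  A <- mat[group_a, , drop = FALSE]
  B <- mat[group_b, , drop = FALSE]
  na <- nrow(A); nb <- nrow(B)
  ma <- colMeans(A); mb <- colMeans(B)
  va <- (colSums(A^2) - na * ma^2) / (na - 1)
  vb <- (colSums(B^2) - nb * mb^2) / (nb - 1)
  va <- pmax(va, 0); vb <- pmax(vb, 0)  # guard tiny negative from roundoff
  sa <- va / na; sb <- vb / nb
  degenerate <- va == 0 & vb == 0
  se <- sqrt(sa + sb)
  tstat <- ifelse(degenerate, NA_real_, (ma - mb) / se)
  df <- ifelse(degenerate, NA_real_,
               (sa + sb)^2 / (sa^2 / (na - 1) + sb^2 / (nb - 1)))
  p <- 2 * pt(-abs(tstat), df)
  q <- rep(NA_real_, length(p))
  tested <- !degenerate
  q[tested] <- bh_fdr(p[tested])
  if (any(degenerate))
    warning(sprintf("%d position(s) with zero variance in both groups skipped; FDR family size %d",
                    sum(degenerate), sum(tested)))
  data.frame(position_id = colnames(mat), t = tstat, df = df, p = p, q = q,
             stringsAsFactors = FALSE)
}

new_selection <- function(position_ids, origin, stats = NULL, params = list()) {
  structure(list(position_ids = position_ids, origin = origin,
                 stats = stats, selection_params = params),
            class = "cpg_selection")
}

#' @export
print.cpg_selection <- function(x, ...) {
  cat(sprintf("CpG selection (%s): %d positions\n", x$origin,
              length(x$position_ids)))
  invisible(x)
}

order_results <- function(res) {
  res[order(res$q, res$p, res$position_id), , drop = FALSE]
}

#' Select CpG by significance thresholds
#'
#' Keeps positions with p <= alpha and q <= fdr_cutoff, ordered by ascending
#' q, then p, then position id.
#'
#' @param results data.frame from [test_all_cpg()].
#' @param alpha per-test significance level (default 0.01).
#' @param fdr_cutoff BH q-value cutoff.
#' @return \code{cpg_selection} of origin "differential".
#' @export
select_by_significance <- function(results, alpha = 0.01, fdr_cutoff = 1) {
  if (nrow(results) == 0L) stop_cfg("empty results")
  keep <- !is.na(results$p) & results$p <= alpha & results$q <= fdr_cutoff
  sel <- order_results(results[keep, , drop = FALSE])
  if (nrow(sel) == 0L)
    warning("selection is empty at alpha = ", alpha, ", fdr_cutoff = ", fdr_cutoff)
  new_selection(sel$position_id, "differential", sel,
                list(alpha = alpha, fdr_cutoff = fdr_cutoff))
}

#' Select approximately a target number of CpG by tuning the FDR cutoff
#'
#' Searches the q-value cutoff so the selection holds \code{target +/-
#' tolerance} positions (all with p <= alpha), mirroring selections such as
#' "8000 +/- 100 CpG at an FDR cutoff of approximately 2e-4".
#'
#' @param results data.frame from [test_all_cpg()].
#' @param target desired selection size.
#' @param tolerance acceptable deviation (default 100).
#' @param alpha per-test significance level (default 0.01).
#' @return \code{cpg_selection}; the cutoff used is recorded in
#'   \code{selection_params$fdr_cutoff}.
#' @export
select_to_count <- function(results, target, tolerance = 100L, alpha = 0.01) {
  if (nrow(results) == 0L) stop_cfg("empty results")
  elig <- results[!is.na(results$p) & results$p <= alpha, , drop = FALSE]
  if (target > nrow(elig))
    stop_cfg("target %d exceeds the %d positions with p <= %g", target,
             nrow(elig), alpha)
  elig <- order_results(elig)
  # counts achievable at each distinct q cutoff
  qs <- elig$q
  cut_idx <- which(!duplicated(qs, fromLast = TRUE))  # last index of each q
  counts <- cut_idx
  best <- counts[which.min(abs(counts - target))]
  if (abs(best - target) > tolerance) {
    lower <- max(c(counts[counts <= target], 0))
    upper <- min(c(counts[counts >= target], nrow(elig)))
    stop_cfg("cannot select %d +/- %d positions; nearest achievable counts are %d and %d",
             target, tolerance, lower, upper)
  }
  sel <- elig[seq_len(best), , drop = FALSE]
  new_selection(sel$position_id, "differential", sel,
                list(alpha = alpha, fdr_cutoff = qs[best], target = target,
                     tolerance = tolerance))
}

#' Dichotomize a quantitative trait at its mean
#'
#' High group: strictly above the mean; low group: at or below the mean
#' (values exactly at the mean go to "low", as the high group is defined by
#' exceeding the mean).
#'
#' @param values named numeric vector (names are ids); length >= 4, not all
#'   equal.
#' @return list with \code{high}, \code{low} (ids), and \code{mean}.
#' @export
dichotomize_at_mean <- function(values) {
  if (length(values) < 4L) stop_cfg("need at least 4 trait values")
  if (length(unique(values)) == 1L) stop_cfg("all trait values equal; cannot dichotomize")
  m <- mean(values)
  ids <- names(values) %||% as.character(seq_along(values))
  list(high = ids[values > m], low = ids[values <= m], mean = m)
}

#' Pool top positions from several selections
#'
#' Takes the top \code{counts[i]} positions (by the selection's stored
#' order, ascending q) from each selection and unions them, keeping the
#' first occurrence of duplicates.
#'
#' @param selections list of \code{cpg_selection} objects.
#' @param counts integer vector, one per selection.
#' @return \code{cpg_selection} of origin "pooled".
#' @export
pooled_selection <- function(selections, counts) {
  if (length(selections) != length(counts))
    stop_cfg("need one count per selection")
  tops <- mapply(function(sel, k) {
    if (k > length(sel$position_ids))
      stop_cfg("count %d exceeds selection size %d", k, length(sel$position_ids))
    sel$position_ids[seq_len(k)]
  }, selections, counts, SIMPLIFY = FALSE)
  ids <- unlist(tops, use.names = FALSE)
  new_selection(ids[!duplicated(ids)], "pooled", NULL,
                list(counts = counts, origins = vapply(selections, `[[`,
                                                       "", "origin")))
}

#' Random CpG selection (control features)
#'
#' Uniform sampling without replacement from the position universe,
#' deterministic given the seed; the caller's RNG state is untouched.
#'
#' @param universe character vector of position ids.
#' @param n number to draw.
#' @param seed integer seed.
#' @return \code{cpg_selection} of origin "random".
#' @export
random_selection <- function(universe, n, seed) {
  if (n > length(universe))
    stop_cfg("cannot draw %d positions from a universe of %d", n, length(universe))
  ids <- with_seed(seed, sample(universe, n))
  new_selection(ids, "random", NULL, list(n = n, seed = seed))
}

#' Serialize a selection as TSV (+ JSON parameter sidecar)
#' @param selection \code{cpg_selection}.
#' @param path output TSV path; parameters go to \code{<path>.json}.
#' @export
write_selection <- function(selection, path) {
  st <- selection$stats
  dt <- if (!is.null(st))
    data.table::data.table(st, rank = seq_len(nrow(st)))
  else data.table::data.table(position_id = selection$position_ids,
                              rank = seq_along(selection$position_ids))
  data.table::fwrite(dt, path, sep = "\t")
  jsonlite::write_json(c(list(origin = selection$origin),
                         selection$selection_params),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
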