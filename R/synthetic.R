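# Synthetic methylome generator: beta-mixture baselines, planted tissue /
# provenance / quantitative-trait effects, Poisson coverage with binomial
# read sampling, coverage filtering and uniform missingness.

PROVENANCE_CODES <- c("POR", "WOL", "SOU", "ROS", "LAR", "WHR", "BOY", "LOV", "FRE")

#' Configuration for a synthetic methylome study
#'
#' Defines the statistical structure the analysis assumes: a bimodal
#' beta-mixture baseline per CpG, planted CpG whose latent methylation
#' differs between tissues, is ordered along a fixed provenance sequence, or
#' loads on a per-tree factor driving a quantitative trait, and an
#' observation model of Poisson read coverage with binomial methylation
#' calls, a coverage >= 10 filter and uniform missingness.
#'
#' Effects stated in percentage points are applied on the logit of the
#' latent baseline, as the logit offset equivalent to that shift at 50%
#' methylation, and the result is clipped to [0.001, 0.999] so proportions
#' stay valid near the extremes.
#'
#' @param n_provenances number of provenances (3-letter codes; up to 9 use
#'   the field study's codes, POR, WOL, ...).
#' @param genotypes_per_provenance genotypes sampled per provenance.
#' @param sites common-garden site codes (default IH, PA).
#' @param tissues tissue codes (default X = xylem, L = leaf).
#' @param n_cpg total CpG dyads simulated.
#' @param n_tissue_cpg,n_provenance_cpg,n_trait_cpg planted causal CpG per
#'   effect class (pairwise disjoint).
#' @param tissue_effect latent methylation difference between the two
#'   tissues at planted tissue CpG, percentage points.
#' @param provenance_effect_step separation between consecutive provenances
#'   along the fixed class sequence, percentage points.
#' @param trait_effect trait units per percentage point of mean causal
#'   methylation.
#' @param baseline_mixture numeric(4): low-mode mean, high-mode mean,
#'   dispersion (beta precision), and mixing weight of the low mode.
#' @param mean_coverage expected reads per dyad (Poisson).
#' @param missing_rate fraction of observed cells removed uniformly at
#'   random, on top of the coverage filter (in [0, 1)).
#' @param trait_noise_sd Gaussian noise on the quantitative trait, trait
#'   units.
#' @param latent_noise_sd per-(sample, CpG) biological noise on the logit
#'   scale, emulating between-tree methylation variation.
#' @param trait_baseline trait intercept (default 11.4, a biomass in kg).
#' @param trait_cpg_loading logit-scale loading of the per-tree factor on
#'   trait CpG.
#' @param trait_tissue NULL (trait CpG expressed in all tissues) or a tissue
#'   code: the causal methylation signal appears only in that tissue's
#'   methylomes.
#' @param seed integer seed; the study is bit-identical given the seed.
#' @return object of class \code{epitrait_config}.
#' @export
synthetic_config <- function(n_provenances = 9L,
                             genotypes_per_provenance = 2L,
                             sites = c("IH", "PA"),
                             tissues = c("X", "L"),
                             n_cpg = 20000L,
                             n_tissue_cpg = 200L,
                             n_provenance_cpg = 200L,
                             n_trait_cpg = 200L,
                             tissue_effect = 25,
                             provenance_effect_step = 6,
                             trait_effect = 0.4,
                             baseline_mixture = c(low = 0.05, high = 0.85,
                                                  dispersion = 20, weight = 0.7),
                             mean_coverage = 30,
                             missing_rate = 0.031,
                             trait_noise_sd = 1,
                             latent_noise_sd = 0.3,
                             trait_baseline = 11.4,
                             trait_cpg_loading = 1.0,
                             trait_tissue = NULL,
                             seed = 1L) {
  cfg <- list(n_provenances = as.integer(n_provenances),
              genotypes_per_provenance = as.integer(genotypes_per_provenance),
              sites = sites, tissues = tissues,
              n_cpg = as.integer(n_cpg),
              n_tissue_cpg = as.integer(n_tissue_cpg),
              n_provenance_cpg = as.integer(n_provenance_cpg),
              n_trait_cpg = as.integer(n_trait_cpg),
              tissue_effect = tissue_effect,
              provenance_effect_step = provenance_effect_step,
              trait_effect = trait_effect,
              baseline_mixture = baseline_mixture,
              mean_coverage = mean_coverage,
              missing_rate = missing_rate,
              trait_noise_sd = trait_noise_sd,
              latent_noise_sd = latent_noise_sd,
              trait_baseline = trait_baseline,
              trait_cpg_loading = trait_cpg_loading,
              trait_tissue = trait_tissue,
              seed = as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "epitrait_config")
}

validate_config <- function(cfg) {
  counts <- c(cfg$n_cpg, cfg$n_tissue_cpg, cfg$n_provenance_cpg, cfg$n_trait_cpg,
              cfg$n_provenances, cfg$genotypes_per_provenance)
  if (any(is.na(counts)) || any(counts < 0L))
    stop_cfg("counts must be nonnegative")
  if (cfg$n_tissue_cpg + cfg$n_provenance_cpg + cfg$n_trait_cpg > cfg$n_cpg)
    stop_cfg("planted CpG classes (%d) exceed n_cpg (%d)",
             cfg$n_tissue_cpg + cfg$n_provenance_cpg + cfg$n_trait_cpg, cfg$n_cpg)
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop_cfg("missing_rate must be in [0, 1)")
  if (length(cfg$baseline_mixture) != 4L)
    stop_cfg("baseline_mixture must have 4 components (low, high, dispersion, weight)")
  if (!is.null(cfg$trait_tissue) && !cfg$trait_tissue %in% cfg$tissues)
    stop_cfg("trait_tissue must be one of the configured tissues")
  invisible(cfg)
}

#' Load a synthetic-study configuration from YAML or JSON
#' @param path config file; keys are [synthetic_config()] arguments.
#' @return \code{epitrait_config}.
#' @export
read_synthetic_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  do.call(synthetic_config, raw)
}

provenance_codes <- function(n) {
  if (n <= length(PROVENANCE_CODES)) return(PROVENANCE_CODES[seq_len(n)])
  extra <- apply(expand.grid(LETTERS, LETTERS, LETTERS)[, 3:1], 1, paste0, collapse = "")
  extra <- setdiff(extra, PROVENANCE_CODES)
  c(PROVENANCE_CODES, extra)[seq_len(n)]
}

#' Simulate a methylome study with planted effects
#'
#' Draws a per-CpG latent baseline from the configured two-component beta
#' mixture; applies tissue, provenance-sequence and per-tree trait effects
#' on the logit scale; generates the quantitative trait as a linear
#' combination of trait-CpG latent methylation plus Gaussian noise; and
#' observes every (sample, CpG) cell through Poisson coverage and binomial
#' read sampling, with cells under 10 reads or hit by uniform missingness
#' recorded as missing.
#'
#' @param config an [synthetic_config()] object.
#' @return object of class \code{epitrait_study}: a list with
#'   \code{matrix} (samples x positions, NA = missing), \code{metadata},
#'   \code{traits} (one row per tree: genotype x site), \code{truth}
#'   (planted CpG ids and effect sizes per class), \code{counts}
#'   (dyad-level coverage and methylated-read matrices, NA where a cell was
#'   dropped by the missingness mechanism), and \code{positions}.
#' @export
simulate_study <- function(config) {
  validate_config(config)
  cfg <- config
  set.seed(cfg$seed)

  # -- genome positions: dyads spaced >= 10 bp over up to 10 chromosomes
  n <- cfg$n_cpg
  n_chrom <- max(1L, min(10L, n %/% 100L + 1L))
  chrom_of <- sort(sample.int(n_chrom, n, replace = TRUE))
  chroms <- sprintf("Chr%02d", seq_len(n_chrom))
  pos <- integer(n)
  for (k in seq_len(n_chrom)) {
    idx <- which(chrom_of == k)
    pos[idx] <- cumsum(sample(10:60, length(idx), replace = TRUE))
  }
  positions <- data.table::data.table(chrom = chroms[chrom_of], pos = pos)
  data.table::setorder(positions, chrom, pos)
  positions[, position_id := paste0(chrom, ".", pos)]
  pid <- positions$position_id

  if (n == 0L) {
    meta <- make_metadata(cfg)
    empty <- matrix(numeric(0), nrow = nrow(meta), ncol = 0,
                    dimnames = list(meta$sample_id, character()))
    return(structure(list(matrix = empty, metadata = meta,
                          traits = make_trait_skeleton(cfg, meta),
                          truth = list(tissue = character(),
                                       provenance = character(),
                                       trait = character()),
                          counts = list(coverage = empty, meth = empty),
                          positions = positions, config = cfg),
                     class = "epitrait_study"))
  }

  # -- baseline beta mixture
  mix <- cfg$baseline_mixture
  low <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(mix[4], 1 - mix[4]))
  mu <- ifelse(low, mix[1], mix[2])
  baseline <- clip01(rbeta(n, mu * mix[3], (1 - mu) * mix[3]))

  # -- disjoint causal sets
  planted <- sample.int(n, cfg$n_tissue_cpg + cfg$n_provenance_cpg + cfg$n_trait_cpg)
  idx_tissue <- planted[seq_len(cfg$n_tissue_cpg)]
  idx_prov <- planted[cfg$n_tissue_cpg + seq_len(cfg$n_provenance_cpg)]
  idx_trait <- planted[cfg$n_tissue_cpg + cfg$n_provenance_cpg + seq_len(cfg$n_trait_cpg)]

  meta <- make_metadata(cfg)
  ns <- nrow(meta)
  provs <- provenance_codes(cfg$n_provenances)

  # -- per-tree factor driving trait CpG; trees are genotype x site units
  meta$tree_id <- paste0(meta$provenance, meta$genotype, meta$site)
  trees <- unique(meta[, c("tree_id", "provenance", "genotype", "site")])
  u_tree <- stats::setNames(rnorm(nrow(trees)), trees$tree_id)

  d_tis <- points_to_logit(cfg$tissue_effect)
  d_prov <- points_to_logit(cfg$provenance_effect_step)

  # latent logit per sample x CpG
  L <- matrix(rep(qlogis(baseline), each = ns), nrow = ns)
  if (cfg$n_tissue_cpg > 0) {
    sgn <- ifelse(meta$tissue == cfg$tissues[1], -0.5, 0.5)
    L[, idx_tissue] <- L[, idx_tissue] + sgn * d_tis
  }
  if (cfg$n_provenance_cpg > 0) {
    rank_p <- match(meta$provenance, provs) - (cfg$n_provenances + 1) / 2
    L[, idx_prov] <- L[, idx_prov] + rank_p * d_prov
  }
  if (cfg$n_trait_cpg > 0) {
    load <- u_tree[meta$tree_id] * cfg$trait_cpg_loading
    if (!is.null(cfg$trait_tissue)) load <- load * (meta$tissue == cfg$trait_tissue)
    L[, idx_trait] <- L[, idx_trait] + load
  }
  if (cfg$latent_noise_sd > 0)
    L <- L + matrix(rnorm(ns * n, sd = cfg$latent_noise_sd), nrow = ns)
  latent <- clip01(plogis(L))

  # -- quantitative trait from tree-level causal latent methylation
  traits <- make_trait_skeleton(cfg, meta)
  if (cfg$n_trait_cpg > 0) {
    tree_latent <- clip01(plogis(outer(u_tree[traits$tree_id] * cfg$trait_cpg_loading,
                                       qlogis(baseline[idx_trait]), `+`)))
    score <- rowMeans(100 * tree_latent)
    traits$biomass <- cfg$trait_baseline + cfg$trait_effect * (score - mean(score)) +
      rnorm(nrow(traits), sd = cfg$trait_noise_sd)
  } else {
    traits$biomass <- cfg$trait_baseline + rnorm(nrow(traits), sd = cfg$trait_noise_sd)
  }
  # companion wood traits, non-causal placeholders at realistic scales
  traits$density <- round(rnorm(nrow(traits), 0.36, 0.02), 4)
  traits$soluble_lignin <- round(rnorm(nrow(traits), 4.0, 0.4), 3)
  traits$mannose <- round(rnorm(nrow(traits), 2.1, 0.25), 3)

  # -- observation model
  coverage <- matrix(rpois(ns * n, cfg$mean_coverage), nrow = ns)
  meth <- matrix(rbinom(ns * n, as.vector(coverage), as.vector(latent)), nrow = ns)
  if (cfg$missing_rate > 0) {
    drop <- matrix(runif(ns * n) < cfg$missing_rate, nrow = ns)
    coverage[drop] <- NA_integer_
    meth[drop] <- NA_integer_
  }
  intensity <- ifelse(!is.na(coverage) & coverage >= 10L,
                      100 * meth / coverage, NA_real_)

  # order columns to the sorted position table
  ord <- order(chroms[chrom_of], pos)
  reorder <- function(m) {
    m <- m[, ord, drop = FALSE]
    dimnames(m) <- list(meta$sample_id, pid)
    m
  }
  truth_ids <- function(idx) pid[match(idx, ord)]

  structure(list(
    matrix = reorder(intensity),
    metadata = meta[, setdiff(names(meta), "tree_id")],
    traits = traits,
    truth = list(tissue = truth_ids(idx_tissue),
                 provenance = truth_ids(idx_prov),
                 trait = truth_ids(idx_trait),
                 effects = list(tissue = cfg$tissue_effect,
                                provenance_step = cfg$provenance_effect_step,
                                trait = cfg$trait_effect)),
    counts = list(coverage = reorder(coverage), meth = reorder(meth)),
    positions = positions,
    config = cfg), class = "epitrait_study")
}

make_metadata <- function(cfg) {
  provs <- provenance_codes(cfg$n_provenances)
  grid <- expand.grid(tissue = cfg$tissues, site = cfg$sites,
                      genotype = seq_len(cfg$genotypes_per_provenance),
                      provenance = provs,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("provenance", "genotype", "site", "tissue")]
  grid$sample_id <- paste0(grid$provenance, grid$genotype, grid$site, grid$tissue)
  grid$mature_leaf <- FALSE
  grid$technical_rep <- FALSE
  grid[, c("sample_id", "provenance", "genotype", "site", "tissue",
           "mature_leaf", "technical_rep")]
}

make_trait_skeleton <- function(cfg, meta) {
  meta$tree_id <- paste0(meta$provenance, meta$genotype, meta$site)
  trees <- unique(meta[, c("tree_id", "provenance", "genotype", "site")])
  rownames(trees) <- NULL
  trees
}

#' Write one Bismark-dialect CpG report per sample
#'
#' Each dyad is emitted as its two strand records: the plus-strand cytosine
#' at position p and the minus-strand cytosine at p+1, with the dyad's read
#' counts split deterministically between strands; reading the files back
#' through [import_cytosine_reports()] reproduces the study matrix exactly.
#' Cells dropped by the missingness mechanism are absent from their file.
#'
#' @param study an [simulate_study()] result with count-level data.
#' @param directory output directory (created if needed).
#' @return invisibly, the vector of files written. Also writes the planted
#'   ground truth as \code{truth.tsv}.
#' @export
write_cytosine_reports <- function(study, directory) {
  if (is.null(study$counts)) stop_cfg("study has no count-level data")
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) stop_cfg("cannot create directory %s", directory)
  pos_tab <- study$positions
  files <- character(nrow(study$metadata))
  for (i in seq_len(nrow(study$metadata))) {
    sid <- study$metadata$sample_id[i]
    cov <- study$counts$coverage[i, ]
    m <- study$counts$meth[i, ]
    keep <- which(!is.na(cov))
    u <- cov[keep] - m[keep]
    m_plus <- m[keep] %/% 2L
    u_plus <- u %/% 2L
    dt <- data.table::data.table(
      chrom = rep(pos_tab$chrom[keep], each = 2L),
      pos = as.vector(rbind(pos_tab$pos[keep], pos_tab$pos[keep] + 1L)),
      strand = rep(c("+", "-"), length(keep)),
      count_meth = as.vector(rbind(m_plus, m[keep] - m_plus)),
      count_unmeth = as.vector(rbind(u_plus, u - u_plus)),
      context = "CpG",
      trinucleotide = rep(c("CGA", "CGT"), length(keep)))
    data.table::setorder(dt, chrom, pos)
    files[i] <- file.path(directory, paste0(sid, ".CpG_report.txt"))
    data.table::fwrite(dt, files[i], sep = "\t", col.names = FALSE, quote = FALSE)
  }
  truth_dt <- data.table::rbindlist(lapply(
    c("tissue", "provenance", "trait"),
    function(cl) if (length(study$truth[[cl]]))
      data.table::data.table(class = cl, position_id = study$truth[[cl]])))
  if (!is.null(truth_dt) && nrow(truth_dt))
    data.table::fwrite(truth_dt, file.path(directory, "truth.tsv"), sep = "\t")
  invisible(files)
}

#' @export
print.epitrait_study <- function(x, ...) {
  cat(sprintf("Synthetic methylome study: %d samples x %d CpG dyads\n",
              nrow(x$matrix), ncol(x$matrix)))
  cat(sprintf("  planted CpG: %d tissue, %d provenance, %d trait; %.1f%% missing\n",
              length(x$truth$tissue), length(x$truth$provenance),
              length(x$truth$trait), 100 * mean(is.na(x$matrix))))
  invisible(x)
}
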