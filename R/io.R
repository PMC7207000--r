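# Reading per-cytosine methylation calls, strand merging, coverage
# filtering and assembly of the sample x CpG intensity matrix.

#' Parse a methylome sample name
#'
#' Sample names encode provenance (three capital letters), genotype number,
#' common-garden site (\code{IH} or \code{PA}) and tissue (\code{X} xylem,
#' \code{L} leaf), optionally followed by \code{M} (mature leaf) and/or
#' \code{Rep} (technical replicate), e.g. \code{"POR12IHX"}.
#'
#' @param name character vector of sample names.
#' @return A data.frame with columns \code{sample_id}, \code{provenance},
#'   \code{genotype}, \code{site}, \code{tissue}, \code{mature_leaf},
#'   \code{technical_rep}.
#' @examples
#' parse_sample_name("POR12IHX")
#' parse_sample_name("ROS1PAL")
#' @export
parse_sample_name <- function(name) {
  if (length(name) == 0L || any(!nzchar(name)))
    stop_cfg("sample name must be a nonempty string")
  pat <- "^([A-Z]{3})([0-9]+)(IH|PA)(X|L)(M?)(Rep)?$"
  ok <- grepl(pat, name)
  if (any(!ok)) {
    bad <- name[!ok][1L]
    # locate the first token that fails to parse, for the error message
    if (!grepl("^[A-Z]{3}", bad))
      stop_cfg("cannot parse sample name '%s': expected 3-letter provenance code", bad)
    if (!grepl("^[A-Z]{3}[0-9]+", bad))
      stop_cfg("cannot parse sample name '%s': expected genotype number after provenance", bad)
    if (!grepl("^[A-Z]{3}[0-9]+(IH|PA)", bad))
      stop_cfg("cannot parse sample name '%s': expected site code IH or PA", bad)
    stop_cfg("cannot parse sample name '%s': expected tissue code X or L (optionally M, Rep)", bad)
  }
  data.frame(
    sample_id     = name,
    provenance    = sub(pat, "\\1", name),
    genotype      = as.integer(sub(pat, "\\2", name)),
    site          = sub(pat, "\\3", name),
    tissue        = sub(pat, "\\4", name),
    mature_leaf   = sub(pat, "\\5", name) == "M",
    technical_rep = !is.na(sub(pat, "\\6", name)) & sub(pat, "\\6", name) == "Rep",
    stringsAsFactors = FALSE
  )
}

#' Serialize sample metadata back to a sample name
#' @param meta one-row data.frame as returned by [parse_sample_name()].
#' @return character sample name.
#' @export
format_sample_name <- function(meta) {
  paste0(meta$provenance, meta$genotype, meta$site, meta$tissue,
         ifelse(meta$mature_leaf, "M", ""),
         ifelse(meta$technical_rep, "Rep", ""))
}

#' Read a per-cytosine CpG report
#'
#' Reads the Bismark-style cytosine report dialect: a headerless TSV with
#' columns chromosome, 1-based position, strand, methylated read count,
#' unmethylated read count, context (CpG/CHG/CHH) and trinucleotide.
#' Non-CpG rows are retained but flagged via the \code{is_cpg} column.
#'
#' @param path path to the report file.
#' @return A data.table with columns \code{chrom}, \code{pos}, \code{strand},
#'   \code{count_meth}, \code{count_unmeth}, \code{context},
#'   \code{trinucleotide}, \code{is_cpg}, in file order.
#' @export
read_cytosine_report <- function(path) {
  if (!file.exists(path)) stop_cfg("cytosine report not found: %s", path)
  if (file.size(path) == 0L) {
    dt <- data.table::data.table()
  } else {
    dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                            colClasses = list(character = c(1, 3, 6, 7)))
  }
  if (nrow(dt) == 0L) {
    return(data.table::data.table(
      chrom = character(), pos = integer(), strand = character(),
      count_meth = integer(), count_unmeth = integer(),
      context = character(), trinucleotide = character(), is_cpg = logical()))
  }
  if (ncol(dt) != 7L)
    stop_cfg("malformed cytosine report %s: expected 7 tab-separated columns, found %d",
             path, ncol(dt))
  data.table::setnames(dt, c("chrom", "pos", "strand", "count_meth",
                             "count_unmeth", "context", "trinucleotide"))
  pos <- suppressWarnings(as.integer(dt$pos))
  cm <- suppressWarnings(as.integer(dt$count_meth))
  cu <- suppressWarnings(as.integer(dt$count_unmeth))
  bad <- which(is.na(pos) | is.na(cm) | is.na(cu) | pos < 1L | cm < 0L | cu < 0L |
                 !(dt$strand %in% c("+", "-")))
  if (length(bad))
    stop_cfg("malformed row at line %d of %s", bad[1L], path)
  data.table::set(dt, j = "pos", value = pos)
  data.table::set(dt, j = "count_meth", value = cm)
  data.table::set(dt, j = "count_unmeth", value = cu)
  dt[, is_cpg := context == "CpG"]
  dt[]
}

#' Merge strand-symmetric CpG dyads
#'
#' A CpG is palindromic: the cytosine on the plus strand at position p and
#' the cytosine on the minus strand at p+1 interrogate the same dyad. Their
#' read counts are summed into a single record addressed by the plus-strand
#' coordinate. Non-CpG contexts are dropped. Minus-strand cytosines without
#' a plus partner are re-addressed to their dyad coordinate (pos - 1).
#'
#' @param records data.table from [read_cytosine_report()], sorted by
#'   (chrom, pos).
#' @return data.table with columns \code{chrom}, \code{pos}, \code{strand}
#'   (always "+"), \code{count_meth}, \code{count_unmeth}, \code{context}.
#' @export
merge_strand_symmetric <- function(records) {
  cpg <- records[records$is_cpg %||% (records$context == "CpG")]
  if (nrow(cpg) == 0L)
    return(data.table::data.table(chrom = character(), pos = integer(),
                                  strand = character(), count_meth = integer(),
                                  count_unmeth = integer(), context = character()))
  if (!identical(order(cpg$chrom, cpg$pos), seq_len(nrow(cpg))))
    stop_cfg("merge_strand_symmetric requires records sorted by (chrom, pos)")
  dyad <- data.table::copy(cpg)
  dyad[, dyad_pos := ifelse(strand == "-", pos - 1L, pos)]
  out <- dyad[, .(count_meth = sum(count_meth),
                  count_unmeth = sum(count_unmeth)),
              by = .(chrom, pos = dyad_pos)]
  out[, `:=`(strand = "+", context = "CpG")]
  data.table::setorder(out, chrom, pos)
  out[, .(chrom, pos, strand, count_meth, count_unmeth, context)]
}

#' Compute methylation intensities with a coverage prefilter
#'
#' Intensity is the percentage of reads calling methylated,
#' \code{100 * meth / (meth + unmeth)}. Dyads covered by fewer than
#' \code{min_coverage} reads are excluded (treated as missing downstream).
#'
#' @param records merged dyad records from [merge_strand_symmetric()].
#' @param min_coverage minimum total read count to retain a site (default 10;
#'   sites with exactly \code{min_coverage} reads are kept).
#' @return data.table with \code{chrom}, \code{pos}, \code{position_id}
#'   ("Chrom.pos"), \code{intensity} in [0, 100].
#' @export
compute_intensities <- function(records, min_coverage = 10L) {
  cov <- records$count_meth + records$count_unmeth
  keep <- cov >= min_coverage
  out <- records[keep, .(chrom, pos)]
  out[, position_id := paste0(chrom, ".", pos)]
  out[, intensity := 100 * records$count_meth[keep] / cov[keep]]
  out[]
}

#' Assemble the sample x CpG intensity matrix
#'
#' Columns are the union of positions across samples, sorted by
#' (chromosome, position); a (sample, position) pair absent from a sample's
#' intensity map is missing (NA).
#'
#' @param intensity_maps named list of per-sample data.tables from
#'   [compute_intensities()]; names are sample ids.
#' @return numeric matrix, rows = samples, columns = position ids.
#' @export
assemble_matrix <- function(intensity_maps) {
  if (length(intensity_maps) < 1L) stop_cfg("need at least one sample")
  ids <- names(intensity_maps)
  if (is.null(ids) || anyDuplicated(ids))
    stop_cfg("duplicate or missing sample id in intensity maps")
  all_pos <- data.table::rbindlist(
    lapply(intensity_maps, function(m) m[, .(chrom, pos)]))
  all_pos <- unique(all_pos)
  data.table::setorder(all_pos, chrom, pos)
  pid <- paste0(all_pos$chrom, ".", all_pos$pos)
  mat <- matrix(NA_real_, nrow = length(ids), ncol = length(pid),
                dimnames = list(ids, pid))
  for (s in ids) {
    m <- intensity_maps[[s]]
    mat[s, m$position_id] <- m$intensity
  }
  mat
}

#' Impute missing intensities by the per-position mean
#'
#' Each missing value is replaced by the mean of the observed values at that
#' position across the samples present in \code{mat}. Train and test sets
#' must be imputed by separate calls to preserve their independence.
#'
#' @param mat methylome matrix (samples x positions) with NAs for missing.
#' @return matrix with no missing values; observed cells untouched.
#' @export
impute_missing <- function(mat) {
  nmiss <- colSums(is.na(mat))
  if (any(nmiss == nrow(mat)))
    stop_cfg("position %s has no observed values to impute from",
             colnames(mat)[which(nmiss == nrow(mat))[1L]])
  needs <- which(nmiss > 0L)
  if (length(needs) == 0L) return(mat)
  means <- colMeans(mat[, needs, drop = FALSE], na.rm = TRUE)
  for (j in seq_along(needs)) {
    col <- needs[j]
    mat[is.na(mat[, col]), col] <- means[j]
  }
  mat
}

#' Import a directory of cytosine reports into a methylome matrix
#'
#' Convenience wrapper: read each report, merge strand-symmetric dyads,
#' apply the coverage prefilter, assemble the union matrix.
#'
#' @param files character vector of report paths, or a directory containing
#'   files named \code{<sample>.CpG_report.txt}.
#' @param min_coverage coverage prefilter (default 10).
#' @return methylome matrix as from [assemble_matrix()].
#' @export
import_cytosine_reports <- function(files, min_coverage = 10L) {
  if (length(files) == 1L && dir.exists(files))
    files <- list.files(files, pattern = "\\.CpG_report\\.txt$", full.names = TRUE)
  if (length(files) == 0L) stop_cfg("no cytosine reports found")
  ids <- sub("\\.CpG_report\\.txt$", "", basename(files))
  maps <- lapply(files, function(f)
    compute_intensities(merge_strand_symmetric(read_cytosine_report(f)),
                        min_coverage = min_coverage))
  names(maps) <- ids
  assemble_matrix(maps)
}

#' Write / read a methylome matrix as TSV
#'
#' Samples x positions, header row of position ids, first column
#' \code{sample_id}. Missing values are empty fields.
#' @param mat methylome matrix.
#' @param path output path.
#' @return \code{read_methylome_matrix} returns the matrix.
#' @export
write_methylome_matrix <- function(mat, path) {
  dt <- data.table::as.data.table(mat, keep.rownames = "sample_id")
  data.table::fwrite(dt, path, sep = "\t", na = "", quote = FALSE)
  invisible(path)
}

#' @rdname write_methylome_matrix
#' @export
read_methylome_matrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  ids <- dt$sample_id
  dt[, sample_id := NULL]
  mat <- as.matrix(dt)
  rownames(mat) <- ids
  mat
}
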