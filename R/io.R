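#' Read a read-count table from TSV
#'
#' Expects tab-separated columns `sample_id`, `replicate`, `amplicon_id`,
#' `cpg_id`, `chrom`, `pos` (1-based CpG position), `meth_reads`,
#' `total_reads`. Validation errors name the offending row.
#'
#' @param path TSV file.
#' @return A validated `count_table`.
#' @export
read_count_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_count_table(d)
}

#' Write a read-count table as TSV
#' @param counts a `count_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path) {
  cols <- c("sample_id", "replicate", "amplicon_id", "cpg_id", "chrom",
            "pos", "meth_reads", "total_reads")
  utils::write.table(counts[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a methylation matrix as long-format TSV
#' @param m a `meth_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_meth_matrix <- function(m, path) {
  long <- data.frame(
    sample_id = rep(m$samples$sample_id, times = ncol(m$beta)),
    replicate = rep(m$samples$replicate, times = ncol(m$beta)),
    cpg_id = rep(colnames(m$beta), each = nrow(m$beta)),
    beta = as.numeric(m$beta))
  i <- match(long$cpg_id, m$cpgs$cpg_id)
  long$amplicon_id <- m$cpgs$amplicon_id[i]
  long$chrom <- m$cpgs$chrom[i]
  long$pos <- m$cpgs$pos[i]
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a long-format methylation TSV back into a `meth_matrix`
#' @param path TSV written by [write_meth_matrix()].
#' @return A `meth_matrix`.
#' @export
read_meth_matrix <- function(path) {
  long <- utils::read.delim(path, stringsAsFactors = FALSE)
  cpgs <- unique(long[, c("cpg_id", "amplicon_id", "chrom", "pos")])
  cpgs <- cpgs[order(cpgs$chrom, cpgs$pos), ]
  rownames(cpgs) <- NULL
  samples <- unique(long[, c("sample_id", "replicate")])
  rownames(samples) <- NULL
  rn <- paste(samples$sample_id, samples$replicate, sep = ".")
  beta <- matrix(NA_real_, nrow(samples), nrow(cpgs),
                 dimnames = list(rn, cpgs$cpg_id))
  ri <- match(paste(long$sample_id, long$replicate, sep = "."), rn)
  ci <- match(long$cpg_id, cpgs$cpg_id)
  beta[cbind(ri, ci)] <- long$beta
  if (all(is.na(samples$replicate))) rownames(beta) <- samples$sample_id
  structure(list(beta = beta, samples = samples, cpgs = cpgs,
                 exclusions = data.frame()), class = "meth_matrix")
}

#' Serialize a reference panel
#'
#' Writes `<prefix>_means.tsv`, `<prefix>_vars.tsv` (cell types x CpGs),
#' `<prefix>_markers.tsv` and a `<prefix>_panel.json` sidecar with
#' provenance (cell types, individuals per type).
#'
#' @param panel a `ref_panel`.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_panel <- function(panel, prefix) {
  wt <- function(m, suffix) {
    d <- data.frame(cell_type = rownames(m), m, check.names = FALSE)
    utils::write.table(d, paste0(prefix, suffix), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(panel$means, "_means.tsv")
  wt(panel$vars, "_vars.tsv")
  utils::write.table(panel$markers, paste0(prefix, "_markers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(celltypes = panel$celltypes,
         n_individuals = panel$n_individuals,
         n_cpgs = ncol(panel$means),
         n_amplicons = length(unique(panel$markers$amplicon_id))),
    paste0(prefix, "_panel.json"), auto_unbox = TRUE)
  invisible(prefix)
}

#' Read a serialized reference panel
#' @param prefix path prefix used by [write_panel()].
#' @return A `ref_panel` (diagonal dispersion).
#' @export
read_panel <- function(prefix) {
  rd <- function(suffix) {
    d <- utils::read.delim(paste0(prefix, suffix), check.names = FALSE,
                           stringsAsFactors = FALSE)
    m <- as.matrix(d[, -1, drop = FALSE])
    rownames(m) <- d$cell_type
    m
  }
  means <- rd("_means.tsv")
  vars <- rd("_vars.tsv")
  markers <- utils::read.delim(paste0(prefix, "_markers.tsv"),
                               stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(prefix, "_panel.json"),
                              simplifyVector = TRUE)
  structure(list(means = means, vars = vars, cov = NULL,
                 n_individuals = meta$n_individuals,
                 markers = markers, celltypes = rownames(means)),
            class = "ref_panel")
}

#' Write estimated proportions as TSV
#' @param estimates a [deconvolve_cohort()] data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_proportions <- function(estimates, path) {
  utils::write.table(estimates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a proportions TSV (e.g. known mixture truth)
#' @param path TSV with `sample_id` plus one numeric column per cell type.
#' @return Numeric matrix, rows named by sample.
#' @export
read_proportions <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  as_prop_matrix(d)
}

#' Write an evaluation report as TSV + JSON
#' @param report an `eval_report`.
#' @param prefix output path prefix (`<prefix>_evaluation.{tsv,json}`).
#' @return `prefix`, invisibly.
#' @export
write_eval_report <- function(report, prefix) {
  utils::write.table(report$per_type, paste0(prefix, "_evaluation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(mean_correlation = report$mean_correlation,
         mean_rmse = report$mean_rmse,
         bias_p_value = report$bias$p_value,
         bias_mean_difference = report$bias$mean_difference,
         n_samples = report$n_samples),
    paste0(prefix, "_evaluation.json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
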