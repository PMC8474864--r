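# Shared fixture builders; everything is generated in code.

# A reference panel assembled directly from known means/variances
# (bypasses build_panel; used to test estimators against hand-picked numbers).
manual_panel <- function(means, vars = NULL, amplicon = NULL) {
  if (is.null(vars)) vars <- means * 0
  mk <- data.frame(
    cpg_id = colnames(means),
    amplicon_id = if (is.null(amplicon)) colnames(means) else amplicon,
    chrom = "chr1", pos = 100L * seq_len(ncol(means)),
    stringsAsFactors = FALSE)
  structure(list(means = means, vars = vars, cov = NULL,
                 n_individuals = rep(2L, nrow(means)),
                 markers = mk, celltypes = rownames(means)),
            class = "ref_panel")
}

# meth_matrix assembled directly from a beta matrix (rows = merged samples)
manual_meth <- function(beta, amplicon = NULL) {
  cpgs <- data.frame(cpg_id = colnames(beta),
                     amplicon_id = if (is.null(amplicon)) colnames(beta) else amplicon,
                     chrom = "chr1", pos = 100L * seq_len(ncol(beta)),
                     stringsAsFactors = FALSE)
  structure(list(beta = beta,
                 samples = data.frame(sample_id = rownames(beta),
                                      replicate = NA_integer_),
                 cpgs = cpgs, exclusions = data.frame()),
            class = "meth_matrix")
}

# clamp to [0,1] preserving matrix shape (pmin/pmax with scalars drop dims)
clamp01 <- function(m) {
  m[m < 0] <- 0
  m[m > 1] <- 1
  m
}

# one count-table row set built from vectors (recycled)
make_counts <- function(sample_id, replicate = 1L, amplicon_id, cpg_id,
                        meth, total, pos = NULL) {
  n <- max(lengths(list(sample_id, amplicon_id, cpg_id, meth, total)))
  if (is.null(pos)) pos <- 100L * as.integer(factor(rep_len(cpg_id, n)))
  d <- data.frame(sample_id = rep_len(sample_id, n),
                  replicate = rep_len(replicate, n),
                  amplicon_id = rep_len(amplicon_id, n),
                  cpg_id = rep_len(cpg_id, n),
                  chrom = "chr1", pos = rep_len(pos, n),
                  meth_reads = rep_len(meth, n),
                  total_reads = rep_len(total, n),
                  stringsAsFactors = FALSE)
  class(d) <- c("count_table", "data.frame")
  d
}

# full synthetic study -> merged bulk/reference methylation, panel, estimates
run_synth_study <- function(cfg, methods = c("wnnls", "ols")) {
  ref <- simulate_reference(cfg)
  bulk <- simulate_mixtures(ref$truth, cfg)
  blanks <- simulate_blanks(cfg)
  mb <- merge_replicates(call_methylation(background_filter(bulk, blanks)))
  mr <- merge_replicates(call_methylation(background_filter(ref$counts, blanks)))
  panel <- build_panel(mr, ref$sample_sheet)
  out <- list(truth = ref$truth, panel = panel, bulk_meth = mb)
  for (m in methods) {
    est <- deconvolve_cohort(mb, panel, method = m)
    out[[paste0("est_", m)]] <- est
    out[[paste0("report_", m)]] <- evaluate_estimates(est, ref$truth$proportions)
  }
  out
}
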