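#' Validate a read-count table
#'
#' Checks the column contract of a targeted-sequencing count table and
#' reports offending rows by number.
#'
#' @param counts data frame with columns `sample_id`, `replicate`,
#'   `amplicon_id`, `cpg_id`, `chrom`, `pos`, `meth_reads`, `total_reads`.
#' @return The validated table with class `count_table`.
#' @export
validate_count_table <- function(counts) {
  req <- c("sample_id", "replicate", "amplicon_id", "cpg_id", "chrom", "pos",
           "meth_reads", "total_reads")
  miss <- setdiff(req, names(counts))
  if (length(miss))
    stop("count table is missing column(s): ", paste(miss, collapse = ", "))
  for (col in c("meth_reads", "total_reads", "pos", "replicate")) {
    v <- counts[[col]]
    if (!is.numeric(v) || anyNA(v) || any(v != round(v)))
      stop("column '", col, "' must be integer-valued (row ",
           which(!is.numeric(v) | is.na(v) | v != round(v))[1], ")")
  }
  if (any(counts$meth_reads < 0) || any(counts$total_reads < 0))
    stop("negative read counts at row ",
         which(counts$meth_reads < 0 | counts$total_reads < 0)[1])
  bad <- which(counts$meth_reads > counts$total_reads)
  if (length(bad))
    stop("meth_reads > total_reads at row ", bad[1], " (sample ",
         counts$sample_id[bad[1]], ", CpG ", counts$cpg_id[bad[1]], ")")
  if (!inherits(counts, "count_table"))
    class(counts) <- c("count_table", class(counts))
  counts
}

# per-(sample, replicate, amplicon) read level: mean per-CpG total depth
amplicon_levels <- function(counts) {
  agg <- stats::aggregate(total_reads ~ sample_id + replicate + amplicon_id,
                          data = counts, FUN = mean)
  names(agg)[names(agg) == "total_reads"] <- "level"
  agg
}

#' Exclude amplicons that do not clear the blank background
#'
#' For every (sample, replicate, amplicon), the amplicon's read level (mean
#' per-CpG total depth) must strictly exceed `factor` times the background
#' level of that amplicon — the average read level observed in the blank
#' (no-DNA) libraries. Amplicons at or below the bar are flagged; their CpGs
#' become missing at methylation calling. Ties are excluded ("exceed" is
#' strict). Amplicons without any blank measurement get background 0, with a
#' message.
#'
#' @param counts sample `count_table`.
#' @param blanks blank `count_table` covering the same amplicons.
#' @param factor background multiplier (default 5).
#' @return `counts` with added logical column `excluded` and character column
#'   `exclusion_reason` (`"background"` or `NA`). The per-amplicon decisions
#'   are attached as attribute `"exclusions"`.
#' @export
#' @examples
#' # a blank background of 10 reads means amplicons need > 50 reads to survive
background_filter <- function(counts, blanks, factor = 5) {
  counts <- validate_count_table(counts)
  blanks <- validate_count_table(blanks)
  if (factor <= 0) stop("factor must be > 0")

  blank_lev <- amplicon_levels(blanks)
  bg <- tapply(blank_lev$level, blank_lev$amplicon_id, mean)
  missing_bg <- setdiff(unique(counts$amplicon_id), names(bg))
  if (length(missing_bg)) {
    message("no blank measurements for amplicon(s) ",
            paste(missing_bg, collapse = ", "), "; background set to 0")
    bg <- c(bg, stats::setNames(rep(0, length(missing_bg)), missing_bg))
  }

  lev <- amplicon_levels(counts)
  lev$background <- as.numeric(bg[lev$amplicon_id])
  lev$excluded <- !(lev$level > factor * lev$background)

  key <- function(d) paste(d$sample_id, d$replicate, d$amplicon_id, sep = "\r")
  excl <- stats::setNames(lev$excluded, key(lev))
  counts$excluded <- as.logical(excl[key(counts)])
  counts$exclusion_reason <- ifelse(counts$excluded, "background",
                                    NA_character_)
  attr(counts, "exclusions") <- lev[lev$excluded,
                                    c("sample_id", "replicate", "amplicon_id",
                                      "level", "background")]
  counts
}

#' Call methylation levels from read counts
#'
#' The methylation level (beta) of a CpG in a sample-replicate is the number
#' of methylated reads divided by the total reads at that site. Sites with
#' zero total reads, and all sites of amplicons flagged by
#' [background_filter()], are missing.
#'
#' @param counts a `count_table`, optionally carrying the `excluded` column
#'   from [background_filter()].
#' @return A `meth_matrix`: list with `beta` (rows = sample-replicates,
#'   columns = CpGs, `NA` = missing), `samples` (`sample_id`, `replicate`),
#'   `cpgs` (`cpg_id`, `amplicon_id`, `chrom`, `pos`) and `exclusions`.
#' @export
call_methylation <- function(counts) {
  counts <- validate_count_table(counts)
  if (!"excluded" %in% names(counts)) counts$excluded <- FALSE

  cpgs <- unique(counts[, c("cpg_id", "amplicon_id", "chrom", "pos")])
  cpgs <- cpgs[order(cpgs$chrom, cpgs$pos), ]
  rownames(cpgs) <- NULL
  samples <- unique(counts[, c("sample_id", "replicate")])
  rownames(samples) <- NULL

  beta <- matrix(NA_real_, nrow(samples), nrow(cpgs),
                 dimnames = list(paste(samples$sample_id, samples$replicate,
                                       sep = "."),
                                 cpgs$cpg_id))
  ok <- !counts$excluded & counts$total_reads > 0
  ri <- match(paste(counts$sample_id, counts$replicate, sep = "."),
              rownames(beta))
  ci <- match(counts$cpg_id, cpgs$cpg_id)
  beta[cbind(ri[ok], ci[ok])] <-
    counts$meth_reads[ok] / counts$total_reads[ok]

  excl <- attr(counts, "exclusions")
  if (is.null(excl))
    excl <- data.frame(sample_id = character(), replicate = integer(),
                       amplicon_id = character())
  structure(list(beta = beta, samples = samples, cpgs = cpgs,
                 exclusions = excl),
            class = "meth_matrix")
}

#' @export
print.meth_matrix <- function(x, ...) {
  cat("meth_matrix:", nrow(x$beta), "sample rows x", ncol(x$beta), "CpGs (",
      sum(is.na(x$beta)), "missing )\n")
  invisible(x)
}

#' Merge duplicate assays of the same sample
#'
#' Collapses replicate rows of a `meth_matrix` to one row per sample.
#' The default policy averages the available (non-missing) replicate betas
#' per CpG; `"weighted"` recomputes the beta from pooled raw counts,
#' `(meth1 + meth2) / (total1 + total2)`, over replicates that survived
#' filtering (requires `counts`). A CpG missing in every replicate stays
#' missing.
#'
#' @param m a `meth_matrix` from [call_methylation()].
#' @param policy `"mean"` or `"weighted"`.
#' @param counts the (filtered) `count_table` behind `m`; required for the
#'   weighted policy.
#' @return A `meth_matrix` with one row per sample (`replicate` = NA).
#' @export
merge_replicates <- function(m, policy = c("mean", "weighted"),
                             counts = NULL) {
  policy <- match.arg(policy)
  stopifnot(inherits(m, "meth_matrix"))
  ids <- unique(m$samples$sample_id)
  beta <- matrix(NA_real_, length(ids), ncol(m$beta),
                 dimnames = list(ids, colnames(m$beta)))
  if (policy == "mean") {
    for (id in ids) {
      rows <- m$beta[m$samples$sample_id == id, , drop = FALSE]
      v <- colMeans(rows, na.rm = TRUE)
      v[is.nan(v)] <- NA_real_
      beta[id, ] <- v
    }
  } else {
    if (is.null(counts))
      stop("the weighted policy needs the raw count table")
    counts <- validate_count_table(counts)
    if (!"excluded" %in% names(counts)) counts$excluded <- FALSE
    use <- counts[!counts$excluded & counts$total_reads > 0, ]
    met <- stats::aggregate(meth_reads ~ sample_id + cpg_id, use, sum)
    tot <- stats::aggregate(total_reads ~ sample_id + cpg_id, use, sum)
    stopifnot(identical(met[1:2], tot[1:2]))
    ri <- match(met$sample_id, ids)
    ci <- match(met$cpg_id, colnames(beta))
    keep <- !is.na(ri) & !is.na(ci)
    beta[cbind(ri[keep], ci[keep])] <-
      met$meth_reads[keep] / tot$total_reads[keep]
  }
  structure(list(beta = beta,
                 samples = data.frame(sample_id = ids, replicate = NA_integer_),
                 cpgs = m$cpgs, exclusions = m$exclusions),
            class = "meth_matrix")
}
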