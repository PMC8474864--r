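#' Priority score of a CpG for one target cell type
#'
#' Counts conforming sorted-cell samples at one CpG: samples of the target
#' cell type with fragment coverage strictly above `threshold`, plus samples
#' of every other cell type with coverage strictly below it. A perfectly
#' cell-type-specific CpG therefore scores the total number of sorted
#' samples (individuals x cell types). Samples at exactly the threshold
#' conform to neither condition.
#'
#' @param coverage numeric matrix of fragment coverage, rows = sorted-cell
#'   samples (rownames = sample ids), columns = CpG ids.
#' @param samples sample sheet data frame with columns `sample_id`,
#'   `individual_id`, `cell_type`; one row per coverage row.
#' @param cpg CpG id (column of `coverage`).
#' @param target target cell type.
#' @param threshold coverage cutoff separating "covered" from "uncovered";
#'   must be > 0.
#' @return Integer score in `[0, nrow(coverage)]`.
#' @seealso [priority_scores()] for all CpGs x cell types at once.
#' @export
#' @examples
#' cov <- matrix(c(0.8, 0.05, 0.9, 0.1), 2, 2,
#'               dimnames = list(c("s1", "s2"), c("g1", "g2")))
#' sheet <- data.frame(sample_id = c("s1", "s2"),
#'                     individual_id = "i1", cell_type = c("A", "B"))
#' priority_score(cov, sheet, "g1", "A")  # 2: s1 above, s2 below
priority_score <- function(coverage, samples, cpg, target, threshold = 0.3) {
  tab <- priority_scores(coverage, samples, threshold = threshold)
  if (!cpg %in% tab$cpg_id) stop("CpG '", cpg, "' absent from coverage matrix")
  col <- paste0("score_", target)
  if (!col %in% names(tab)) stop("unknown cell type '", target, "'")
  tab[[col]][tab$cpg_id == cpg]
}

#' Priority scores for every CpG and target cell type
#'
#' @inheritParams priority_score
#' @return A `priority_score_table` data frame: `cpg_id`, one `score_<type>`
#'   column per cell type, `best_type` (argmax, ties broken by lexicographic
#'   cell-type order) and `best_score`.
#' @export
priority_scores <- function(coverage, samples, threshold = 0.3) {
  if (!is.matrix(coverage) || !is.numeric(coverage))
    stop("coverage must be a numeric matrix (samples x CpGs)")
  if (threshold <= 0) stop("threshold must be > 0")
  if (any(coverage < 0)) stop("fragment coverage must be non-negative")
  req <- c("sample_id", "individual_id", "cell_type")
  if (!all(req %in% names(samples)))
    stop("sample sheet needs columns: ", paste(req, collapse = ", "))
  if (is.null(rownames(coverage))) {
    if (nrow(coverage) != nrow(samples))
      stop("coverage rows do not match the sample sheet")
    rownames(coverage) <- samples$sample_id
  }
  if (!all(samples$sample_id %in% rownames(coverage)))
    stop("sample sheet contains samples absent from the coverage matrix")
  coverage <- coverage[samples$sample_id, , drop = FALSE]

  types <- sort(unique(samples$cell_type))
  above <- coverage > threshold
  below <- coverage < threshold
  score <- sapply(types, function(ct) {
    in_t <- samples$cell_type == ct
    colSums(above[in_t, , drop = FALSE]) + colSums(below[!in_t, , drop = FALSE])
  })
  score <- matrix(as.integer(score), ncol = length(types),
                  dimnames = list(colnames(coverage), types))
  best <- apply(score, 1, which.max)  # first max = lexicographic tie-break
  out <- data.frame(cpg_id = colnames(coverage), score,
                    best_type = types[best],
                    best_score = score[cbind(seq_len(nrow(score)), best)],
                    row.names = NULL, stringsAsFactors = FALSE)
  names(out)[1 + seq_along(types)] <- paste0("score_", types)
  class(out) <- c("priority_score_table", "data.frame")
  out
}

#' Select marker CpGs from a priority-score table
#'
#' Keeps CpGs whose best score reaches `min_score`, groups them by best target
#' type, sorts within type by score (descending) then genomic position
#' (ascending), and caps each type at `per_type_quota`.
#'
#' @param scores a [priority_scores()] table.
#' @param min_score minimum best score to retain a CpG. The default intent is
#'   "specific in every individual": pass the total sample count.
#' @param per_type_quota maximum markers kept per cell type (default
#'   unlimited).
#' @param coords optional data frame `cpg_id`, `chrom`, `pos` (1-based CpG
#'   position) used for coordinate output and positional tie-breaking.
#' @return A `marker_set` data frame: `cpg_id`, `target_type`, `score`,
#'   `chrom`, `pos`.
#' @export
rank_markers <- function(scores, min_score, per_type_quota = Inf,
                         coords = NULL) {
  stopifnot(inherits(scores, "data.frame"))
  score_cols <- grep("^score_", names(scores), value = TRUE)
  max_possible <- NA_integer_
  if (min_score < 0) stop("min_score must be non-negative")
  keep <- scores[scores$best_score >= min_score, , drop = FALSE]
  if (nrow(keep) == 0) {
    warning("no CpG reached min_score = ", min_score)
    out <- data.frame(cpg_id = character(), target_type = character(),
                      score = integer(), chrom = character(), pos = integer())
    class(out) <- c("marker_set", "data.frame")
    return(out)
  }
  if (!is.null(coords)) {
    i <- match(keep$cpg_id, coords$cpg_id)
    keep$chrom <- coords$chrom[i]
    keep$pos <- coords$pos[i]
  } else {
    keep$chrom <- NA_character_
    keep$pos <- seq_len(nrow(scores))[scores$best_score >= min_score]
  }
  keep <- keep[order(keep$best_type, -keep$best_score, keep$pos), ]
  pieces <- lapply(split(keep, keep$best_type), function(d)
    utils::head(d, per_type_quota))
  out <- do.call(rbind, pieces)
  out <- data.frame(cpg_id = out$cpg_id, target_type = out$best_type,
                    score = out$best_score, chrom = out$chrom, pos = out$pos,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("marker_set", "data.frame")
  out
}

#' Write a marker set as BED-like TSV
#'
#' Columns: chrom, 0-based start, 1-based end, cpg_id, score, target_type.
#'
#' @param markers a [rank_markers()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_marker_bed <- function(markers, path) {
  bed <- data.frame(chrom = markers$chrom, start = markers$pos - 1L,
                    end = markers$pos, name = markers$cpg_id,
                    score = markers$score, target_type = markers$target_type)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
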