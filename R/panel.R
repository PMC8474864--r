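#' Build a cell-type reference panel from sorted-cell methylation
#'
#' For each marker CpG and cell type, computes the mean methylation across the
#' reference individuals of that type and the cross-subject dispersion. The
#' dispersion is what the weighted estimator uses to down-weight CpGs whose
#' methylation is inconsistent across subjects.
#'
#' By default the cross-subject dispersion at each CpG is stored as one
#' variance per cell type (diagonal covariance), which is always defined when
#' reference individuals differ between cell types. When the same individuals
#' were sorted into every cell type (a matched design), `covariance = "full"`
#' additionally estimates the full cell-type x cell-type covariance per CpG
#' from the matched per-individual deviations.
#'
#' @param sorted_meth a replicate-merged `meth_matrix` of sorted-cell samples
#'   (one row per sample).
#' @param sample_sheet data frame `sample_id`, `individual_id`, `cell_type`.
#' @param covariance `"diagonal"` (default) or `"full"`.
#' @return A `ref_panel`: list with `means` (cell type x CpG), `vars`
#'   (cell type x CpG sample variances), `cov` (`NULL`, or per-CpG list of
#'   cell-type covariance matrices), `n_individuals` (per cell type),
#'   `markers` (CpG map with amplicon ids) and `celltypes`.
#' @details CpGs observed in fewer than two individuals for any cell type are
#'   dropped with a warning (their mean or variance would be undefined or
#'   degenerate). Missing betas (background-filtered) are excluded
#'   complete-case per CpG per type.
#' @export
build_panel <- function(sorted_meth, sample_sheet,
                        covariance = c("diagonal", "full")) {
  covariance <- match.arg(covariance)
  stopifnot(inherits(sorted_meth, "meth_matrix"))
  req <- c("sample_id", "individual_id", "cell_type")
  if (!all(req %in% names(sample_sheet)))
    stop("sample sheet needs columns: ", paste(req, collapse = ", "))
  ids <- sorted_meth$samples$sample_id
  if (!all(ids %in% sample_sheet$sample_id))
    stop("sample sheet does not cover all methylation samples")
  sheet <- sample_sheet[match(ids, sample_sheet$sample_id), ]
  types <- sort(unique(sheet$cell_type))
  n_ind <- table(sheet$cell_type)
  if (any(n_ind < 2))
    stop("cell type(s) with fewer than 2 individuals: ",
         paste(names(n_ind)[n_ind < 2], collapse = ", "))

  beta <- sorted_meth$beta
  m <- ncol(beta)
  means <- vars <- matrix(NA_real_, length(types), m,
                          dimnames = list(types, colnames(beta)))
  nobs <- matrix(0L, length(types), m, dimnames = dimnames(means))
  for (ct in types) {
    rows <- beta[sheet$cell_type == ct, , drop = FALSE]
    nobs[ct, ] <- colSums(!is.na(rows))
    means[ct, ] <- colMeans(rows, na.rm = TRUE)
    vars[ct, ] <- apply(rows, 2, stats::var, na.rm = TRUE)
  }
  drop <- colSums(nobs < 2) > 0
  if (any(drop)) {
    warning("dropping ", sum(drop),
            " CpG(s) observed in < 2 individuals for some cell type: ",
            paste(colnames(beta)[drop], collapse = ", "))
    means <- means[, !drop, drop = FALSE]
    vars <- vars[, !drop, drop = FALSE]
  }
  if (ncol(means) == 0) stop("empty panel: no CpG usable in every cell type")

  covs <- NULL
  if (covariance == "full") {
    # matched design: per individual, one row per cell type
    by_ind <- split(seq_len(nrow(sheet)), sheet$individual_id)
    if (!all(vapply(by_ind, function(i)
      setequal(sheet$cell_type[i], types), logical(1))))
      stop("full covariance requires every individual sorted into every cell type")
    covs <- lapply(colnames(means), function(g) {
      dev <- t(vapply(by_ind, function(i) {
        v <- beta[i, g][match(types, sheet$cell_type[i])]
        v
      }, numeric(length(types))))
      colnames(dev) <- types
      stats::cov(dev, use = "pairwise.complete.obs")
    })
    names(covs) <- colnames(means)
  }

  markers <- sorted_meth$cpgs[match(colnames(means), sorted_meth$cpgs$cpg_id), ]
  rownames(markers) <- NULL
  structure(list(means = means, vars = vars, cov = covs,
                 n_individuals = as.integer(n_ind[types]),
                 markers = markers, celltypes = types),
            class = "ref_panel")
}

#' @export
print.ref_panel <- function(x, ...) {
  cat("ref_panel:", length(x$celltypes), "cell types (",
      paste(x$celltypes, collapse = ", "), ") x", ncol(x$means), "CpGs over",
      length(unique(x$markers$amplicon_id)), "amplicons\n")
  invisible(x)
}

#' Remove amplicons from a reference panel
#'
#' Drops every CpG belonging to the named amplicons from the panel means and
#' dispersions, e.g. to exclude an unreliable amplicon or to run a
#' leave-one-amplicon-out analysis.
#'
#' @param panel a `ref_panel`.
#' @param amplicon_ids character vector of amplicon ids to remove.
#' @return The reduced `ref_panel`.
#' @export
drop_markers <- function(panel, amplicon_ids) {
  stopifnot(inherits(panel, "ref_panel"))
  if (length(amplicon_ids) == 0) return(panel)
  unknown <- setdiff(amplicon_ids, panel$markers$amplicon_id)
  if (length(unknown))
    stop("unknown amplicon id(s): ", paste(unknown, collapse = ", "))
  keep <- !(panel$markers$amplicon_id %in% amplicon_ids)
  if (!any(keep)) stop("empty panel: all amplicons dropped")
  panel$means <- panel$means[, keep, drop = FALSE]
  panel$vars <- panel$vars[, keep, drop = FALSE]
  if (!is.null(panel$cov)) panel$cov <- panel$cov[keep]
  panel$markers <- panel$markers[keep, ]
  rownames(panel$markers) <- NULL
  panel
}
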