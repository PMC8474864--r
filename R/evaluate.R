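#' Evaluate proportion estimates against known mixtures
#'
#' Computes, per cell type, the Pearson correlation between estimated and
#' true proportions across samples, the mean and (n-1) standard deviation of
#' the estimates, and the RMSE against truth (1/n inside the mean). Overall
#' summaries are unweighted averages over cell types. A pooled paired t-test
#' of (estimate - truth) over all sample x cell-type pairs probes for bias.
#'
#' Samples whose estimates are missing (e.g. critical-marker violations) are
#' excluded pairwise. Correlations based on fewer than 3 pairs, or on a
#' constant vector, are flagged undefined (`NA`).
#'
#' @param estimates data frame from [deconvolve_cohort()] (`sample_id` plus
#'   one column per cell type), or a numeric matrix with sample rownames.
#' @param truth numeric matrix of true proportions (rows = samples, columns =
#'   cell types) or an equivalent data frame with `sample_id`.
#' @return An `eval_report`: list with `per_type` (data frame: `cell_type`,
#'   `correlation`, `mean_estimate`, `sd_estimate`, `mean_true`, `sd_true`,
#'   `rmse`, `n`), `mean_correlation`, `mean_rmse`, `bias` (list `p_value`,
#'   `mean_difference`, `note`) and `n_samples`.
#' @export
evaluate_estimates <- function(estimates, truth) {
  est <- as_prop_matrix(estimates)
  tru <- as_prop_matrix(truth)
  types <- intersect(colnames(tru), colnames(est))
  if (length(types) == 0) stop("no shared cell types")
  common <- intersect(rownames(est), rownames(tru))
  if (length(common) == 0) stop("no shared samples")
  est <- est[common, types, drop = FALSE]
  tru <- tru[common, types, drop = FALSE]

  per <- lapply(types, function(ct) {
    ok <- !is.na(est[, ct]) & !is.na(tru[, ct])
    e <- est[ok, ct]; t_ <- tru[ok, ct]
    r <- if (sum(ok) >= 3 && stats::sd(e) > 0 && stats::sd(t_) > 0)
      stats::cor(e, t_) else NA_real_
    data.frame(cell_type = ct, correlation = r,
               mean_estimate = mean(e), sd_estimate = stats::sd(e),
               mean_true = mean(t_), sd_true = stats::sd(t_),
               rmse = sqrt(mean((e - t_)^2)), n = sum(ok),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  bias <- bias_test(est, tru)
  structure(list(per_type = per,
                 mean_correlation = mean(per$correlation, na.rm = TRUE),
                 mean_rmse = mean(per$rmse),
                 bias = bias, n_samples = length(common)),
            class = "eval_report")
}

as_prop_matrix <- function(x) {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) stop("proportion matrix needs sample rownames")
    return(x)
  }
  x <- as.data.frame(x)
  if (!"sample_id" %in% names(x))
    stop("proportion data frame needs a sample_id column")
  num <- vapply(x, is.numeric, logical(1))
  num[names(x) %in% c("n_markers_used", "replicate")] <- FALSE
  num[names(x) %in% c("converged", "critical_marker_violation")] <- FALSE
  m <- as.matrix(x[, num, drop = FALSE])
  rownames(m) <- x$sample_id
  m
}

#' @export
print.eval_report <- function(x, digits = 3, ...) {
  cat("eval_report over", x$n_samples, "samples\n")
  print(cbind(x$per_type[1], round(x$per_type[-1], digits)))
  cat(sprintf("mean correlation %.3f | mean RMSE %.3f | bias P = %.3g\n",
              x$mean_correlation, x$mean_rmse, x$bias$p_value))
  invisible(x)
}

#' Pooled bias test of proportion estimates
#'
#' Paired two-sided t-test on the pooled differences (estimate - truth)
#' across all sample x cell-type pairs; a large p-value is consistent with an
#' unbiased estimator. Per-cell-type paired t-tests are also reported.
#'
#' @param estimates,truth numeric matrices (samples x cell types) with
#'   matching dimnames, or data frames with `sample_id`.
#' @return A list: `p_value`, `mean_difference`, `per_type` (named p-value
#'   vector) and `note` (degenerate-case annotation, or `NA`).
#' @export
bias_test <- function(estimates, truth) {
  est <- as_prop_matrix(estimates)
  tru <- as_prop_matrix(truth)
  types <- intersect(colnames(tru), colnames(est))
  common <- intersect(rownames(est), rownames(tru))
  d <- as.numeric(est[common, types] - tru[common, types])
  d <- d[!is.na(d)]
  if (length(d) < 2) stop("need at least 2 paired observations")
  note <- NA_character_
  # differences that are constant to machine precision carry no evidence of
  # bias beyond their mean; t.test refuses them, we report p = 1 with a note
  near_const <- function(x) stats::sd(x) <= 1e-10 * max(1, abs(mean(x)))
  if (near_const(d)) {
    if (abs(mean(d)) <= 1e-10) {
      p <- 1
      note <- "zero variance of differences; p set to 1"
    } else {
      p <- 0
      note <- "constant non-zero offset; p set to 0"
    }
  } else {
    p <- stats::t.test(d)$p.value
  }
  per_type <- vapply(types, function(ct) {
    dd <- est[common, ct] - tru[common, ct]
    dd <- dd[!is.na(dd)]
    if (length(dd) < 2 || near_const(dd)) return(NA_real_)
    stats::t.test(dd)$p.value
  }, numeric(1))
  list(p_value = p, mean_difference = mean(d), per_type = per_type,
       note = note)
}

#' Leave-one-amplicon-out robustness analysis
#'
#' Re-estimates the cell-type proportions with each amplicon excluded in
#' turn and evaluates against the known truth, quantifying how much each
#' marker contributes: a baseline row (full panel) is followed by one row
#' per excluded amplicon with the per-cell-type RMSE, correlation, mean and
#' SD plus the overall means.
#'
#' @param bulks replicate-merged bulk `meth_matrix` or beta matrix.
#' @param panel a `ref_panel`.
#' @param truth true proportions (matrix or data frame with `sample_id`).
#' @param method `"wnnls"` or `"ols"`.
#' @param ... passed to [deconvolve_cohort()].
#' @return A data frame with `nrow = n_amplicons + 1`; column
#'   `excluded_amplicon` is `"none"` for the baseline. Per cell type `ct`,
#'   columns `rmse_<ct>`, `cor_<ct>`, `mean_<ct>`, `sd_<ct>`; plus
#'   `mean_correlation` and `mean_rmse`. The full `eval_report`s are
#'   attached as attribute `"reports"`.
#' @export
leave_one_out <- function(bulks, panel, truth, method = c("wnnls", "ols"),
                          ...) {
  method <- match.arg(method)
  amps <- unique(panel$markers$amplicon_id)
  if (length(amps) < 2) stop("need at least 2 amplicons in the panel")

  eval_one <- function(p) {
    est <- deconvolve_cohort(bulks, p, method = method, ...)
    evaluate_estimates(est, truth)
  }
  reports <- c(list(none = eval_one(panel)),
               stats::setNames(lapply(amps, function(a)
                 eval_one(drop_markers(panel, a))), amps))

  rows <- lapply(names(reports), function(nm) {
    rep_ <- reports[[nm]]
    pt <- rep_$per_type
    row <- data.frame(excluded_amplicon = nm, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(pt))) {
      ct <- pt$cell_type[i]
      row[[paste0("rmse_", ct)]] <- pt$rmse[i]
      row[[paste0("cor_", ct)]] <- pt$correlation[i]
      row[[paste0("mean_", ct)]] <- pt$mean_estimate[i]
      row[[paste0("sd_", ct)]] <- pt$sd_estimate[i]
    }
    row$mean_correlation <- rep_$mean_correlation
    row$mean_rmse <- rep_$mean_rmse
    row
  })
  out <- do.call(rbind, rows)
  attr(out, "reports") <- reports
  out
}
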