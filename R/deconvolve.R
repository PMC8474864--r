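#' Cell-type proportion estimation
#'
#' The bulk methylation vector of a subject is modelled as a weighted sum of
#' the reference-panel mean profiles, with weights equal to the cell-type
#' proportions: `Y = sum_c p_c R_c + E`, fitted without an intercept,
#' separately for each subject. [estimate_ols()] is the unweighted
#' least-squares estimator (negative coefficients truncated to zero, then
#' renormalized to the simplex). [estimate_wnnls()] is an iterative weighted
#' non-negative least-squares estimator: starting from the NNLS fit, each CpG
#' `g` receives weight `w_g = 1 / (nu + p' S_g p)` where `S_g` is the
#' cross-subject dispersion of the reference profiles at `g`, and the NNLS is
#' refitted on rows scaled by `sqrt(w_g)` until the proportions stabilise.
#' CpGs with consistent methylation across reference subjects therefore pull
#' the fit hardest.
#'
#' Markers missing in the bulk profile (background-filtered or unobserved)
#' are dropped from that subject's regression.
#'
#' @param bulk named numeric vector of bulk methylation betas (names = CpG
#'   ids; `NA` = missing), or a single-row `meth_matrix`.
#' @param panel a [build_panel()] reference panel.
#' @return A `deconv_result`: list with `proportions` (simplex, named by cell
#'   type), `raw` (pre-normalization coefficients), `residuals` (observed
#'   minus fitted, on the used markers), `weights` (final per-CpG weights;
#'   all 1 for OLS), `n_markers_used`, `iterations`, `converged` and
#'   `markers_used`.
#' @name deconvolution
NULL

as_bulk_vector <- function(bulk) {
  if (inherits(bulk, "meth_matrix")) {
    if (nrow(bulk$beta) != 1)
      stop("expected a single-sample profile; use deconvolve_cohort() for many")
    return(bulk$beta[1, ])
  }
  if (!is.numeric(bulk) || is.null(names(bulk)))
    stop("bulk must be a named numeric vector of betas")
  bulk
}

# design matrix (markers x cell types) restricted to observed markers
design_for <- function(bulk, panel) {
  y <- as_bulk_vector(bulk)
  use <- intersect(names(y)[!is.na(y)], colnames(panel$means))
  n_c <- nrow(panel$means)
  if (length(use) < n_c)
    stop("fewer observed markers (", length(use), ") than cell types (",
         n_c, ")")
  X <- t(panel$means[, use, drop = FALSE])
  qrX <- qr(X)
  if (qrX$rank < n_c) {
    dep <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("reference profiles are collinear on the used markers ",
         "(cell type(s): ", paste(dep, collapse = ", "), ")")
  }
  list(X = X, y = y[use], use = use)
}

new_deconv_result <- function(raw, p, resid, w, use, iter, conv) {
  structure(list(proportions = p, raw = raw, residuals = resid,
                 weights = w, n_markers_used = length(use),
                 iterations = iter, converged = conv, markers_used = use),
            class = "deconv_result")
}

#' @export
print.deconv_result <- function(x, digits = 3, ...) {
  cat("deconv_result (", x$n_markers_used, "markers):\n")
  print(round(x$proportions, digits))
  invisible(x)
}

#' @rdname deconvolution
#' @export
estimate_ols <- function(bulk, panel) {
  stopifnot(inherits(panel, "ref_panel"))
  d <- design_for(bulk, panel)
  fit <- stats::lm.fit(d$X, d$y)
  raw <- stats::setNames(fit$coefficients, colnames(d$X))
  p <- pmax(raw, 0)
  if (sum(p) == 0)
    stop("all truncated coefficients are zero; cannot normalize")
  p <- p / sum(p)
  new_deconv_result(raw, p, stats::setNames(fit$residuals, d$use),
                    stats::setNames(rep(1, length(d$use)), d$use),
                    d$use, 1L, TRUE)
}

# p' S_g p for every used CpG; diagonal panels use the per-type variances
cross_subject_var <- function(panel, use, p) {
  if (!is.null(panel$cov)) {
    vapply(panel$cov[use], function(S) drop(t(p) %*% S %*% p), numeric(1))
  } else {
    as.numeric(p^2 %*% panel$vars[, use, drop = FALSE])
  }
}

#' @rdname deconvolution
#' @param nu variance floor added to the cross-subject variance in the weight
#'   denominator; keeps weights finite for zero-variance CpGs.
#' @param max_iter maximum weight-refit iterations.
#' @param tol convergence tolerance on the maximum absolute change of the
#'   normalized proportions.
#' @export
estimate_wnnls <- function(bulk, panel, nu = 1e-4, max_iter = 100,
                           tol = 1e-6) {
  stopifnot(inherits(panel, "ref_panel"))
  if (nu <= 0) stop("nu must be > 0")
  d <- design_for(bulk, panel)
  n_c <- ncol(d$X)

  nnls_fit <- function(X, y) {
    f <- pracma::lsqnonneg(X, y)
    stats::setNames(f$x, colnames(X))
  }
  raw <- nnls_fit(d$X, d$y)
  p <- if (sum(raw) > 0) raw / sum(raw) else rep(1 / n_c, n_c)
  w <- stats::setNames(rep(1, length(d$use)), d$use)
  conv <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    w <- 1 / (nu + cross_subject_var(panel, d$use, p))
    sw <- sqrt(w)
    raw <- nnls_fit(d$X * sw, d$y * sw)
    p_new <- if (sum(raw) > 0) raw / sum(raw) else rep(1 / n_c, n_c)
    if (max(abs(p_new - p)) < tol) {
      p <- p_new
      conv <- TRUE
      break
    }
    p <- p_new
  }
  if (!conv)
    warning("weighted NNLS did not converge in ", max_iter, " iterations")
  resid <- stats::setNames(d$y - as.numeric(d$X %*% raw), d$use)
  new_deconv_result(raw, stats::setNames(p, colnames(d$X)), resid,
                    stats::setNames(w, d$use), d$use, iter, conv)
}

#' Deconvolve a cohort of bulk samples
#'
#' Runs one regression per subject on the intersection of that subject's
#' observed CpGs with the panel. Subjects with no data for any
#' critical-marker amplicon get their proportions set to missing and are
#' flagged, rather than estimated from an unreliable reduced panel.
#'
#' @param bulks a replicate-merged `meth_matrix` of bulk samples, or a
#'   numeric matrix (rows = samples, columns = CpG ids).
#' @param panel a `ref_panel`.
#' @param method `"wnnls"` (default) or `"ols"`.
#' @param critical_markers amplicon ids whose absence invalidates a
#'   subject's estimate (e.g. `c("P14", "P17")`).
#' @param ... passed to the estimator (`nu`, `max_iter`, `tol`).
#' @return A data frame with one row per sample: `sample_id`, one proportion
#'   column per cell type, `n_markers_used`, `converged`,
#'   `critical_marker_violation`. The full per-sample `deconv_result`
#'   objects are attached as attribute `"results"`.
#' @export
deconvolve_cohort <- function(bulks, panel, method = c("wnnls", "ols"),
                              critical_markers = NULL, ...) {
  method <- match.arg(method)
  stopifnot(inherits(panel, "ref_panel"))
  beta <- if (inherits(bulks, "meth_matrix")) bulks$beta else as.matrix(bulks)
  if (is.null(rownames(beta)))
    rownames(beta) <- paste0("sample", seq_len(nrow(beta)))
  est_fun <- if (method == "ols") {
    function(y, panel, ...) estimate_ols(y, panel)  # ols has no tuning knobs
  } else {
    estimate_wnnls
  }

  types <- rownames(panel$means)
  amp_of <- stats::setNames(panel$markers$amplicon_id, panel$markers$cpg_id)
  res_list <- vector("list", nrow(beta))
  out <- data.frame(sample_id = rownames(beta), stringsAsFactors = FALSE)
  for (ct in types) out[[ct]] <- NA_real_
  out$n_markers_used <- NA_integer_
  out$converged <- NA
  out$critical_marker_violation <- FALSE

  for (i in seq_len(nrow(beta))) {
    y <- beta[i, ]
    if (length(critical_markers)) {
      obs_amps <- unique(amp_of[names(y)[!is.na(y)]])
      missing_crit <- setdiff(critical_markers, obs_amps)
      if (length(missing_crit)) {
        out$critical_marker_violation[i] <- TRUE
        res_list[i] <- list(NULL)
        next
      }
    }
    r <- est_fun(y, panel, ...)
    res_list[[i]] <- r
    out[i, types] <- r$proportions[types]
    out$n_markers_used[i] <- r$n_markers_used
    out$converged[i] <- r$converged
  }
  names(res_list) <- rownames(beta)
  attr(out, "results") <- res_list
  out
}
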