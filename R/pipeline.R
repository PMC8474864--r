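#' Pipeline configuration
#'
#' Builds (and validates) the configuration driving [run_pipeline()]. All
#' fields mirror the CLI flags; a YAML file with the same keys can be loaded
#' with [read_run_config()].
#'
#' @param reference_counts path to the sorted-cell count TSV.
#' @param bulk_counts path to the bulk count TSV.
#' @param blank_counts path to the blank count TSV (optional; no background
#'   filtering when absent).
#' @param sample_sheet path to the reference sample sheet TSV.
#' @param truth optional path to a known-proportions TSV; enables the
#'   evaluation stage.
#' @param outdir output directory (created if needed).
#' @param background_factor background multiplier for [background_filter()].
#' @param merge replicate-merging policy, `"mean"` or `"weighted"`.
#' @param method estimator, `"wnnls"` or `"ols"`.
#' @param nu,tol,max_iter weighted-estimator controls.
#' @param critical_markers amplicon ids that must be present per subject.
#' @param drop_amplicons amplicon ids removed from the panel before
#'   deconvolution.
#' @param seed integer seed recorded in the provenance log.
#' @return A validated `run_config` list.
#' @export
run_config <- function(reference_counts, bulk_counts, blank_counts = NULL,
                       sample_sheet, truth = NULL, outdir = ".",
                       background_factor = 5,
                       merge = c("mean", "weighted"),
                       method = c("wnnls", "ols"),
                       nu = 1e-4, tol = 1e-6, max_iter = 100,
                       critical_markers = NULL, drop_amplicons = NULL,
                       seed = 1L) {
  merge <- match.arg(merge)
  method <- match.arg(method)
  if (background_factor <= 0) stop("background_factor must be > 0")
  if (nu <= 0 || tol <= 0 || max_iter < 1)
    stop("nu and tol must be > 0, max_iter >= 1")
  structure(list(reference_counts = reference_counts,
                 bulk_counts = bulk_counts, blank_counts = blank_counts,
                 sample_sheet = sample_sheet, truth = truth, outdir = outdir,
                 background_factor = background_factor, merge = merge,
                 method = method, nu = nu, tol = tol, max_iter = max_iter,
                 critical_markers = critical_markers,
                 drop_amplicons = drop_amplicons,
                 seed = as.integer(seed)), class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected to catch typos.
#'
#' @param path YAML file whose keys mirror the [run_config()] arguments.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

#' Run the full targeted-deconvolution pipeline
#'
#' Chains the stages on files: methylation calling with background filtering
#' and replicate merging (for both the sorted-cell and bulk tables), panel
#' construction, per-subject deconvolution and — when a truth table is given
#' — evaluation. All intermediate artifacts are written under
#' `config$outdir` together with a `provenance.json` log of the parameters.
#'
#' @param config a [run_config()] (or path to its YAML).
#' @return Invisibly, a list with `panel`, `estimates` and (optionally)
#'   `report`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  blanks <- NULL
  if (!is.null(config$blank_counts))
    blanks <- stage("read-blanks", read_count_table(config$blank_counts))

  prep <- function(path, label) {
    counts <- stage(paste0("read-", label), read_count_table(path))
    if (!is.null(blanks))
      counts <- stage("background-filter",
                      background_filter(counts, blanks,
                                        factor = config$background_factor))
    m <- stage("call", call_methylation(counts))
    stage("merge", merge_replicates(m, policy = config$merge,
                                    counts = counts))
  }

  ref_m <- prep(config$reference_counts, "reference")
  bulk_m <- prep(config$bulk_counts, "bulk")
  write_meth_matrix(ref_m, file.path(config$outdir, "reference_methylation.tsv"))
  write_meth_matrix(bulk_m, file.path(config$outdir, "bulk_methylation.tsv"))

  sheet <- stage("read-sample-sheet",
                 utils::read.delim(config$sample_sheet,
                                   stringsAsFactors = FALSE))
  panel <- stage("build-panel", build_panel(ref_m, sheet))
  if (length(config$drop_amplicons))
    panel <- stage("drop-markers", drop_markers(panel, config$drop_amplicons))
  write_panel(panel, file.path(config$outdir, "panel"))

  estimates <- stage("deconvolve",
                     deconvolve_cohort(bulk_m, panel, method = config$method,
                                       critical_markers = config$critical_markers,
                                       nu = config$nu, tol = config$tol,
                                       max_iter = config$max_iter))
  write_proportions(estimates, file.path(config$outdir, "proportions.tsv"))

  report <- NULL
  if (!is.null(config$truth)) {
    truth <- stage("read-truth", read_proportions(config$truth))
    report <- stage("evaluate", evaluate_estimates(estimates, truth))
    write_eval_report(report, file.path(config$outdir, "report"))
  }

  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("targetDeconv")),
         parameters = config[c("background_factor", "merge", "method", "nu",
                               "tol", "max_iter", "critical_markers",
                               "drop_amplicons", "seed")],
         inputs = config[c("reference_counts", "bulk_counts", "blank_counts",
                           "sample_sheet", "truth")]),
    file.path(config$outdir, "provenance.json"), auto_unbox = TRUE,
    null = "null")
  invisible(list(panel = panel, estimates = estimates, report = report))
}

#' Reproduce the known-mixture evaluation from published supplementary tables
#'
#' Runs panel construction, deconvolution (with the unreliable amplicon P5
#' excluded by default) and evaluation from TSV exports of the published
#' supplementary tables: the reference-panel methylation of sorted cells,
#' the methylation estimates of the known-mixture samples, and the known
#' mixing proportions. The files are user-supplied (exported from the
#' article's additional files); this package does not bundle them.
#'
#' @param mixture_meth_tsv TSV of bulk methylation for the known mixtures
#'   (readable by [read_meth_matrix()]).
#' @param reference_meth_tsv TSV of sorted-cell methylation (same format).
#' @param reference_sheet_tsv reference sample sheet TSV.
#' @param truth_tsv TSV of the known mixing proportions.
#' @param drop_amplicons amplicons excluded before estimation (default
#'   `"P5"`).
#' @param method estimator (default `"wnnls"`).
#' @return The `eval_report` for the requested estimator.
#' @export
reproduce_known_mixture_evaluation <- function(mixture_meth_tsv,
                                               reference_meth_tsv,
                                               reference_sheet_tsv,
                                               truth_tsv,
                                               drop_amplicons = "P5",
                                               method = "wnnls") {
  for (f in c(mixture_meth_tsv, reference_meth_tsv, reference_sheet_tsv,
              truth_tsv))
    if (!file.exists(f))
      stop("required input file not found: ", f)
  ref_m <- read_meth_matrix(reference_meth_tsv)
  bulk_m <- read_meth_matrix(mixture_meth_tsv)
  sheet <- utils::read.delim(reference_sheet_tsv, stringsAsFactors = FALSE)
  truth <- read_proportions(truth_tsv)
  panel <- build_panel(ref_m, sheet)
  if (length(drop_amplicons)) panel <- drop_markers(panel, drop_amplicons)
  est <- deconvolve_cohort(bulk_m, panel, method = method)
  evaluate_estimates(est, truth)
}
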