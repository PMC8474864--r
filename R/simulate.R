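#' Configuration for the synthetic targeted-methylation study
#'
#' Bundles every knob of the simulator: the marker panel layout (cell types,
#' amplicons per type, CpGs per amplicon), the reference design (individuals),
#' the bulk mixture design (samples, replicates, proportions), sequencing depth,
#' subject-level biological variation and the blank background rate.
#'
#' The defaults describe a blood-leukocyte study: 4 cell types (CD3+ T cells,
#' CD14+ monocytes, CD15+ granulocytes, CD19+ B cells), a 17-amplicon / 34-CpG
#' marker panel with per-type amplicon counts 4/7/3/3, a reference panel of 7
#' individuals sorted into all 4 types, 10 bulk mixtures assayed in duplicate
#' at a mean per-CpG depth of 3000 reads, and a mixture design whose per-type
#' means and spreads include a dominant type (granulocytes) and a rare one
#' (B cells).
#'
#' @param n_celltypes number of cell types (>= 2).
#' @param n_markers_per_type amplicons per cell type; a scalar (recycled) or a
#'   vector of length `n_celltypes`.
#' @param cpgs_per_amplicon CpG sites per amplicon.
#' @param n_ref_individuals individuals in the sorted-cell reference panel.
#' @param n_discovery_individuals individuals in the fragment-coverage
#'   discovery data set (marker selection).
#' @param n_bulk_samples number of bulk mixture samples.
#' @param n_replicates assay replicates per bulk sample.
#' @param depth mean total reads per CpG per sample (Poisson mean).
#' @param subject_sd SD of subject-level methylation deviation on the beta
#'   scale (Gaussian, truncated to `[0,1]`) for a typical CpG.
#' @param var_cpg_fraction fraction of CpGs with elevated cross-subject
#'   variability (their subject SD is `var_cpg_factor * subject_sd`). Real
#'   marker panels are heterogeneous in how consistent a CpG is across
#'   subjects; this is the feature the weighted estimator exploits.
#' @param var_cpg_factor subject-SD multiplier for the variable CpGs.
#' @param high_level,low_level target methylation of a marker CpG in its
#'   target cell type / in all other types, fractions in `[0,1]`.
#' @param blank_rate mean background reads per CpG site in a blank (no-DNA)
#'   library; Poisson mean.
#' @param proportions_mode `"fixed"` (use `proportions`, recycled row-wise to
#'   `n_bulk_samples`) or `"dirichlet"` (draw rows from a Dirichlet with
#'   concentration `dirichlet_alpha`).
#' @param proportions matrix of mixture proportions (rows on the simplex),
#'   columns in cell-type order; `NULL` uses the built-in 5-mixture design.
#' @param dirichlet_alpha Dirichlet concentration vector, length
#'   `n_celltypes`.
#' @param celltypes character vector of cell-type labels.
#' @param seed integer seed fixing the full simulated output bit-for-bit.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- simulation_config(n_bulk_samples = 4, depth = 500, seed = 1)
#' ref <- simulate_reference(cfg)
#' dim(ref$truth$profiles)
simulation_config <- function(n_celltypes = 4,
                              n_markers_per_type = c(4, 7, 3, 3),
                              cpgs_per_amplicon = 2,
                              n_ref_individuals = 7,
                              n_discovery_individuals = 9,
                              n_bulk_samples = 10,
                              n_replicates = 2,
                              depth = 3000,
                              subject_sd = 0.03,
                              var_cpg_fraction = 0.25,
                              var_cpg_factor = 5,
                              high_level = 0.9,
                              low_level = 0.1,
                              blank_rate = 10,
                              proportions_mode = c("fixed", "dirichlet"),
                              proportions = NULL,
                              dirichlet_alpha = NULL,
                              celltypes = NULL,
                              seed = 1L) {
  proportions_mode <- match.arg(proportions_mode)
  counts <- c(n_celltypes = n_celltypes, n_ref_individuals = n_ref_individuals,
              n_discovery_individuals = n_discovery_individuals,
              n_bulk_samples = n_bulk_samples, n_replicates = n_replicates,
              cpgs_per_amplicon = cpgs_per_amplicon)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("all design counts must be integers >= 1")
  if (length(n_markers_per_type) == 1)
    n_markers_per_type <- rep(n_markers_per_type, n_celltypes)
  if (length(n_markers_per_type) != n_celltypes)
    stop("n_markers_per_type must have length 1 or n_celltypes")
  if (any(n_markers_per_type < 1))
    stop("need at least one amplicon per cell type")
  if (!(low_level >= 0 && low_level < high_level && high_level <= 1))
    stop("need 0 <= low_level < high_level <= 1")
  if (depth < 1) stop("depth must be >= 1")
  if (subject_sd < 0) stop("subject_sd must be >= 0")
  if (var_cpg_fraction < 0 || var_cpg_fraction > 1)
    stop("var_cpg_fraction must be in [0,1]")
  if (var_cpg_factor < 1) stop("var_cpg_factor must be >= 1")
  if (blank_rate < 0) stop("blank_rate must be >= 0")
  if (is.null(celltypes)) {
    celltypes <- if (n_celltypes == 4) c("CD3", "CD14", "CD15", "CD19")
                 else paste0("CT", seq_len(n_celltypes))
  }
  if (length(celltypes) != n_celltypes || anyDuplicated(celltypes))
    stop("celltypes must be ", n_celltypes, " distinct labels")

  if (proportions_mode == "fixed") {
    if (is.null(proportions)) {
      if (n_celltypes == 4) {
        # 5-mixture design: column means (0.26, 0.12, 0.54, 0.08), spreads
        # large for CD3/CD15 and small for CD14/CD19, echoing a blood study
        # with a dominant granulocyte fraction and a rare B-cell fraction
        proportions <- matrix(c(
          0.05, 0.10, 0.80, 0.05,
          0.15, 0.12, 0.63, 0.10,
          0.30, 0.16, 0.46, 0.08,
          0.50, 0.14, 0.30, 0.06,
          0.30, 0.08, 0.51, 0.11), ncol = 4, byrow = TRUE)
      } else {
        proportions <- matrix(1 / n_celltypes, nrow = 1, ncol = n_celltypes)
      }
    }
    proportions <- as.matrix(proportions)
    if (ncol(proportions) != n_celltypes)
      stop("proportions must have n_celltypes columns")
    if (any(proportions < 0) || any(abs(rowSums(proportions) - 1) > 1e-8))
      stop("proportion rows must be non-negative and sum to 1")
    # recycle the design row-wise up to the requested number of bulk samples
    idx <- rep_len(seq_len(nrow(proportions)), n_bulk_samples)
    proportions <- proportions[idx, , drop = FALSE]
  } else {
    if (is.null(dirichlet_alpha)) dirichlet_alpha <- rep(1, n_celltypes)
    if (length(dirichlet_alpha) != n_celltypes || any(dirichlet_alpha <= 0))
      stop("dirichlet_alpha must be ", n_celltypes, " positive values")
    proportions <- NULL
  }
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer")

  structure(list(
    n_celltypes = as.integer(n_celltypes),
    n_markers_per_type = as.integer(n_markers_per_type),
    cpgs_per_amplicon = as.integer(cpgs_per_amplicon),
    n_ref_individuals = as.integer(n_ref_individuals),
    n_discovery_individuals = as.integer(n_discovery_individuals),
    n_bulk_samples = as.integer(n_bulk_samples),
    n_replicates = as.integer(n_replicates),
    depth = depth, subject_sd = subject_sd,
    var_cpg_fraction = var_cpg_fraction, var_cpg_factor = var_cpg_factor,
    high_level = high_level, low_level = low_level,
    blank_rate = blank_rate,
    proportions_mode = proportions_mode,
    proportions = proportions,
    dirichlet_alpha = dirichlet_alpha,
    celltypes = celltypes,
    seed = seed), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_celltypes, "cell types,",
      sum(x$n_markers_per_type), "amplicons,",
      sum(x$n_markers_per_type) * x$cpgs_per_amplicon, "CpGs\n")
  cat("  reference:", x$n_ref_individuals, "individuals; bulks:",
      x$n_bulk_samples, "x", x$n_replicates, "replicates; depth",
      x$depth, "; subject_sd", x$subject_sd, "; seed", x$seed, "\n")
  invisible(x)
}

# Marker map for a config: one row per CpG with amplicon grouping,
# target cell type and genomic coordinates (1-based CpG positions).
marker_map <- function(config) {
  n_amp <- sum(config$n_markers_per_type)
  amp_type <- rep(config$celltypes, config$n_markers_per_type)
  amp_id <- paste0("P", seq_len(n_amp))
  data.frame(
    cpg_id = paste0(rep(amp_id, each = config$cpgs_per_amplicon), "_",
                    seq_len(config$cpgs_per_amplicon)),
    amplicon_id = rep(amp_id, each = config$cpgs_per_amplicon),
    target_type = rep(amp_type, each = config$cpgs_per_amplicon),
    chrom = "chr1",
    pos = rep(10000L * seq_len(n_amp), each = config$cpgs_per_amplicon) +
      100L * seq_len(config$cpgs_per_amplicon),
    stringsAsFactors = FALSE)
}

# truth + truncated Gaussian subject deviation, clipped to [0,1]
perturb_beta <- function(beta, sd) {
  if (all(sd == 0)) return(beta)
  out <- pmin(1, pmax(0, beta + stats::rnorm(length(beta), 0, sd)))
  attributes(out) <- attributes(beta)
  out
}

rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  g / rowSums(g)
}

#' Simulate the sorted-cell reference experiment
#'
#' Builds the ground truth for a synthetic study (cell-type methylation
#' profiles, mixture proportions, per-sample expected bulk methylation) and
#' draws the sorted-cell read-count table: each reference individual's profile
#' is the truth plus truncated Gaussian noise (`subject_sd`), per-CpG total
#' reads are Poisson around `depth`, and methylated reads are binomial.
#'
#' Each marker CpG is methylated at `high_level` in its target cell type and
#' at `low_level` in all others, giving every cell type a block of markers
#' that are "on" only in that type.
#'
#' @param config a [simulation_config()] object.
#' @return A list with elements
#'   \describe{
#'     \item{truth}{`ground_truth` object: `profiles` (cell type x CpG),
#'       `proportions` (sample x cell type, simplex rows),
#'       `expected_bulk` (sample x CpG), `markers` (marker map),
#'       `cpg_sd` (per-CpG subject-level SD).}
#'     \item{counts}{sorted-cell `count_table` (one replicate per sorted
#'       sample).}
#'     \item{sample_sheet}{data frame `sample_id`, `individual_id`,
#'       `cell_type`.}
#'   }
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  mk <- marker_map(config)
  m <- nrow(mk)
  profiles <- matrix(config$low_level, config$n_celltypes, m,
                     dimnames = list(config$celltypes, mk$cpg_id))
  for (ct in config$celltypes)
    profiles[ct, mk$target_type == ct] <- config$high_level

  # cross-subject variability is a property of the CpG: a seeded subset of
  # sites is "variable" (elevated subject SD); the rest are consistent
  cpg_sd <- rep(config$subject_sd, m)
  variable <- stats::runif(m) < config$var_cpg_fraction
  cpg_sd[variable] <- config$subject_sd * config$var_cpg_factor
  names(cpg_sd) <- mk$cpg_id

  # mixture proportions (fixed design or Dirichlet draw)
  if (config$proportions_mode == "dirichlet") {
    prop <- rdirichlet(config$n_bulk_samples, config$dirichlet_alpha)
  } else {
    prop <- config$proportions
  }
  dimnames(prop) <- list(sprintf("mix%02d", seq_len(config$n_bulk_samples)),
                         config$celltypes)

  # each bulk mixture is pooled from one (synthetic) donor per run: its
  # cell-type profiles deviate from the truth by subject-level noise, so the
  # reference panel does not perfectly match the bulk donors
  expected_bulk <- matrix(NA_real_, config$n_bulk_samples, m,
                          dimnames = list(rownames(prop), mk$cpg_id))
  for (s in seq_len(config$n_bulk_samples)) {
    donor <- perturb_beta(profiles, rep(cpg_sd, each = nrow(profiles)))
    expected_bulk[s, ] <- as.numeric(prop[s, , drop = FALSE] %*% donor)
  }

  truth <- structure(list(profiles = profiles, proportions = prop,
                          expected_bulk = expected_bulk, markers = mk,
                          cpg_sd = cpg_sd),
                     class = "ground_truth")

  # sorted-cell counts: n_ref_individuals x n_celltypes samples
  sheet <- expand.grid(individual_id = sprintf("ind%d", seq_len(config$n_ref_individuals)),
                       cell_type = config$celltypes,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sheet$sample_id <- paste0("ref_", sheet$individual_id, "_", sheet$cell_type)
  sheet <- sheet[, c("sample_id", "individual_id", "cell_type")]

  rows <- vector("list", nrow(sheet))
  for (i in seq_len(nrow(sheet))) {
    beta <- perturb_beta(profiles[sheet$cell_type[i], ], cpg_sd)
    tot <- stats::rpois(m, config$depth)
    met <- stats::rbinom(m, tot, beta)
    rows[[i]] <- data.frame(sample_id = sheet$sample_id[i], replicate = 1L,
                            amplicon_id = mk$amplicon_id, cpg_id = mk$cpg_id,
                            chrom = mk$chrom, pos = mk$pos,
                            meth_reads = met, total_reads = tot,
                            stringsAsFactors = FALSE)
  }
  counts <- do.call(rbind, rows)
  class(counts) <- c("count_table", "data.frame")
  list(truth = truth, counts = counts, sample_sheet = sheet)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("ground_truth:", nrow(x$profiles), "cell types x", ncol(x$profiles),
      "CpGs;", nrow(x$proportions), "mixture samples\n")
  invisible(x)
}

#' Simulate bulk mixture read counts
#'
#' Draws the targeted-sequencing count table for the known mixtures in
#' `truth`: for each sample, replicate and CpG, total reads are Poisson around
#' `config$depth` and methylated reads are binomial with the sample's expected
#' bulk methylation (the proportion-weighted sum of that sample's donor
#' cell-type profiles). Replicates are independent draws from the same
#' expected methylation.
#'
#' @param truth `ground_truth` from [simulate_reference()].
#' @param config the same [simulation_config()] used to build `truth`.
#' @return A bulk `count_table` with `n_replicates` replicates per sample.
#' @export
simulate_mixtures <- function(truth, config) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "sim_config"))
  mk <- truth$markers
  if (nrow(truth$proportions) != config$n_bulk_samples ||
      ncol(truth$expected_bulk) != nrow(mk))
    stop("truth and config dimensions do not match")
  set.seed(config$seed + 1L)
  m <- nrow(mk)
  rows <- vector("list", config$n_bulk_samples * config$n_replicates)
  k <- 0
  for (s in seq_len(config$n_bulk_samples)) {
    beta <- truth$expected_bulk[s, ]
    for (r in seq_len(config$n_replicates)) {
      tot <- stats::rpois(m, config$depth)
      met <- stats::rbinom(m, tot, beta)
      k <- k + 1
      rows[[k]] <- data.frame(sample_id = rownames(truth$proportions)[s],
                              replicate = r,
                              amplicon_id = mk$amplicon_id, cpg_id = mk$cpg_id,
                              chrom = mk$chrom, pos = mk$pos,
                              meth_reads = met, total_reads = tot,
                              stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(rbind, rows)
  class(counts) <- c("count_table", "data.frame")
  counts
}

#' Simulate blank (no-DNA) control libraries
#'
#' Two blank replicates are produced, mirroring the usual pair of negative
#' controls on a targeted run. Per CpG site, background reads are Poisson with
#' mean `blank_rate`; the distribution of blank reads is an assumption of the
#' simulator (negative controls carry no signal model), documented in the
#' package vignette.
#'
#' @param config a [simulation_config()].
#' @return A blank `count_table` with sample ids `blank1`, `blank2`.
#' @export
simulate_blanks <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  mk <- marker_map(config)
  m <- nrow(mk)
  rows <- lapply(1:2, function(b) {
    tot <- stats::rpois(m, config$blank_rate)
    met <- stats::rbinom(m, tot, 0.5)
    data.frame(sample_id = paste0("blank", b), replicate = 1L,
               amplicon_id = mk$amplicon_id, cpg_id = mk$cpg_id,
               chrom = mk$chrom, pos = mk$pos,
               meth_reads = met, total_reads = tot, stringsAsFactors = FALSE)
  })
  counts <- do.call(rbind, rows)
  class(counts) <- c("count_table", "data.frame")
  counts
}

#' Simulate a fragment-coverage matrix for marker discovery
#'
#' Emulates an enrichment-based methylome screen over the marker CpGs:
#' fragment coverage tracks the methylation level of each sorted-cell sample
#' (coverage around `high_level` where the CpG is methylated, around
#' `low_level` elsewhere) with Gaussian measurement noise, floored at 0.
#' Uses `n_discovery_individuals` individuals per cell type.
#'
#' @param config a [simulation_config()].
#' @param noise_sd SD of the coverage measurement noise.
#' @return A list with `coverage` (matrix, sorted samples x CpGs) and
#'   `sample_sheet` (`sample_id`, `individual_id`, `cell_type`).
#' @export
simulate_coverage <- function(config, noise_sd = 0.05) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  mk <- marker_map(config)
  profiles <- matrix(config$low_level, config$n_celltypes, nrow(mk),
                     dimnames = list(config$celltypes, mk$cpg_id))
  for (ct in config$celltypes)
    profiles[ct, mk$target_type == ct] <- config$high_level
  sheet <- expand.grid(individual_id = sprintf("d%d", seq_len(config$n_discovery_individuals)),
                       cell_type = config$celltypes,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sheet$sample_id <- paste0("mwas_", sheet$individual_id, "_", sheet$cell_type)
  sheet <- sheet[, c("sample_id", "individual_id", "cell_type")]
  cov <- t(vapply(seq_len(nrow(sheet)), function(i) {
    mu <- perturb_beta(profiles[sheet$cell_type[i], ], config$subject_sd)
    pmax(0, mu + stats::rnorm(nrow(mk), 0, noise_sd))
  }, numeric(nrow(mk))))
  dimnames(cov) <- list(sheet$sample_id, mk$cpg_id)
  list(coverage = cov, sample_sheet = sheet)
}
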