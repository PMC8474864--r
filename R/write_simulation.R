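#' Write a complete synthetic study to disk
#'
#' Materializes everything [run_pipeline()] needs: sorted-cell, bulk and
#' blank count tables, the reference sample sheet, and the ground truth
#' (cell-type profiles and mixture proportions) for evaluation.
#'
#' @param config a [simulation_config()].
#' @param outdir output directory (created if needed).
#' @return Invisibly, a named list of the written file paths.
#' @export
write_simulation <- function(config, outdir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ref <- simulate_reference(config)
  bulk <- simulate_mixtures(ref$truth, config)
  blanks <- simulate_blanks(config)

  paths <- list(
    reference_counts = file.path(outdir, "reference_counts.tsv"),
    bulk_counts = file.path(outdir, "bulk_counts.tsv"),
    blank_counts = file.path(outdir, "blank_counts.tsv"),
    sample_sheet = file.path(outdir, "reference_samples.tsv"),
    truth_profiles = file.path(outdir, "truth_profiles.tsv"),
    truth_proportions = file.path(outdir, "truth_proportions.tsv"))

  write_count_table(ref$counts, paths$reference_counts)
  write_count_table(bulk, paths$bulk_counts)
  write_count_table(blanks, paths$blank_counts)
  utils::write.table(ref$sample_sheet, paths$sample_sheet, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  prof <- data.frame(cell_type = rownames(ref$truth$profiles),
                     ref$truth$profiles, check.names = FALSE)
  utils::write.table(prof, paths$truth_profiles, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  prop <- data.frame(sample_id = rownames(ref$truth$proportions),
                     ref$truth$proportions, check.names = FALSE)
  utils::write.table(prop, paths$truth_proportions, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
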