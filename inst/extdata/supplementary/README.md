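# User-supplied supplementary data

To reproduce the published known-mixture evaluation with
`reproduce_known_mixture_evaluation()`, place TSV exports of the published
supplementary tables in this directory (they are not redistributable with
the package):

- `reference_methylation.tsv` — sorted-cell methylation of the marker CpGs
  (long format: sample_id, replicate, cpg_id, beta, amplicon_id, chrom, pos)
- `mixture_methylation.tsv` — methylation of the known-mixture samples,
  same format
- `reference_samples.tsv` — sample_id, individual_id, cell_type
- `mixture_proportions.tsv` — sample_id plus one column per cell type with
  the known mixing proportions
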