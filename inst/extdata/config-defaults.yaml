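# Real-data template with the study-scale default thresholds: 2 s.d.
# log10-UMI window, at least 1000 detected genes per cell, genes detected
# in at least 10 cells, mitochondrial exclusion, q <= 0.05 for markers and
# DEGs, variable-gene bounds 0.01-3 on the mean log TPM-like value with
# dispersion > 1, 60% condition purity for enriched trajectory states,
# p < 0.05 for GO enrichment, top 1000 trajectory DEGs.
counts_dir: path/to/mtx_dir        # matrix.mtx + genes.tsv + barcodes.tsv
lrdb_dir: path/to/lrdb_dir         # secreted.tsv + receptors.tsv + pairs.tsv
annotation_file: path/to/go.tsv    # two columns: gene, term
receiver_cluster: SMC
# trajectory_tsv: path/to/external_trajectory.tsv   # optional override
thresholds:
  sd_window: 2
  min_genes: 1000
  min_cells: 10
  q_max: 0.05
  min_log_fc: 0
  mean_low: 0.01
  mean_high: 3
  min_dispersion: 1
  enrich_threshold: 0.6
  p_max: 0.05
  state_top_n: 1000
  min_group_cells: 10
seed: 1
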