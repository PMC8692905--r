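# Reference synthetic run: four clusters x two conditions x 100 cells,
# 1000 genes with a 37-gene mitochondrial panel, planted markers, six
# ligand-receptor pairs from the fibroblast-like sender (C2) to the
# SMC-like receiver (C4), and a three-state severity trajectory in the
# receiver. Thresholds mirror the real-data defaults except for the
# detected-gene floor and the trajectory DEG count, which are scaled to
# the 1000-gene panel.
simulation:
  nClusters: 4
  cellsPerClusterPerCondition: 100
  nGenes: 1000
  nMitoGenes: 37
  nSecreted: 40
  nReceptors: 30
  nPlantedPairs: 6
  nMarkersPerCluster: 10
  nStateGenes: 20
  markerFoldChange: 4
  stateFoldChange: 4
  librarySizeMean: 10000
  librarySizeSdLog: 0.3
  dispersion: 0.5
  nDonorsPerCondition: 3
  senderCluster: 2
  receiverCluster: 4
  seed: 1
thresholds:
  sd_window: 2
  min_genes: 100
  min_cells: 10
  q_max: 0.05
  min_log_fc: 0
  mean_low: 0.01
  mean_high: 3
  min_dispersion: 1
  enrich_threshold: 0.6
  p_max: 0.05
  state_top_n: 200
  min_group_cells: 10
seed: 1
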