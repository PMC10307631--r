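# Small end-to-end pipeline configuration over bundled synthetic data.
seed: 7
outdir: flscape_out
thresholds:
  signature_alpha: 0.05
  sc_de_bonferroni: 0.05
  gsea_bh: 0.25
  mito_max: 0.20
  libsize_min: 1024
  tf_gate: 0.20
  gene_min_spots: 10
  gene_max_frac: 0.95
  anchor_quantile: 0.9
sizes:
  bulk:
    n_genes: 1200
    n_replicates: 3
    dispersion: 0.05
    genes_per_program: 40
    log2fc: 2
  sc:
    n_genes: 1000
    cells_per_state: 250
    low_depth_frac: 0.05
    high_mito_frac: 0.05
  spatial:
    n_spots: 400
    depth: 500
    n_genes: 400
    n_markers: 20
    K: 3
  atac:
    n_peaks: 300
    n_cells: 200
    n_motifs: 10
    n_background: 30
    planted_activity: 1.5
topics:
  n_iter: 200
  n_top: 30
gsea:
  n_perm: 500
masks:
  prefixes: ["MT-", "RPS", "RPL"]
  genes: ["MALAT1"]
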