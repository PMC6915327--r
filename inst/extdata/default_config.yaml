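# ribote end-to-end run configuration (synthetic study design)
seed: 1
stages: [simulate, qc, quant, diffte, utr]
simulate:
  n_genes: 2000
  n_replicates: 3
  conditions: [WT, 2D]
  utr5_length_mean: 150
  utr5_length_sd: 50
  utr5_length_min: 25
  utr5_gc_target: 0.6
  top_fraction: 0.10
  uorf_fraction: 0.15
  cds_codons_min: 100
  cds_codons_max: 500
  utr3_length_mean: 300
  utr3_length_sd: 100
  utr3_length_min: 40
  expression_logmean: 3.0
  expression_logsd: 1.0
  te_logsd: 0.25
  dispersion: 0.02
  depth: 1000000
  dtg_up_fraction: 0.10
  dtg_down_fraction: 0.10
  te_effect_fold: 2.5
  frame_probs: [0.85, 0.10, 0.05]
  footprint_length_probs:
    "28": 0.15
    "29": 0.35
    "30": 0.25
    "31": 0.15
    "32": 0.10
  psite_offset: 12
qc:
  psite_offset: 12
  canonical_min: 28
  canonical_max: 32
  min_canonical_fraction: 0.8
  min_in_frame: 0.6
  min_r2: 0.9
  metagene_upstream: 50
  metagene_downstream: 150
  max_reads_per_sample: 100000
quant:
  min_reads: 40
  region: transcript
diffte:
  lower_ratio: 0.667
  upper_ratio: 1.5
  alpha: 0.05
  standardization: trimmed
utr:
  min_tract: 4
  min_codons: 2
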