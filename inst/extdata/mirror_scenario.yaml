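# Default synthetic scenario: five bulk datasets and one single-cell
# dataset, structured like the cross-dataset microglia GPCRome analysis.
# 15 core receptor genes are planted at high percentiles in every dataset,
# 2 white-matter-enriched genes at medium percentiles in grey-matter
# datasets and high in the white-matter dataset, and all remaining catalog
# receptor genes strictly below the medium tier with a >= 0.05 percentile
# margin. The single-cell component plants a 10% disease-associated cluster
# with six homeostatic markers shifted down and CXCR4 shifted up.
name: core_signature_mirror
species: human
unit: FPKM
bulk:
  n_genes: 2000
  n_samples: 8
  meanlog: 1.0
  sdlog: 1.5
  noise_sd: 0.05
  datasets:
    - {id: ds_gm_a, region: GM}
    - {id: ds_gm_b, region: GM}
    - {id: ds_gm_c, region: GM}
    - {id: ds_gm_d, region: GM}
    - {id: ds_wm, region: WM}
  core_genes: [CX3CR1, GPR34, GPR183, P2RY12, P2RY13, ADGRG1, ADORA3,
               ADRB2, CCR1, C3AR1, C5AR1, LPAR5, LPAR6, PTAFR, FPR1]
  core_targets_low: 0.87
  core_targets_high: 0.99
  rescue_genes: [CXCR4, PTGER4]
  rescue_gm_targets: [0.70, 0.80]
  rescue_wm_targets: [0.862, 0.866]
  background_targets_low: 0.05
  background_targets_high: 0.60
single_cell:
  n_cells: 1602
  proportions: {homeostatic: 0.75, disease: 0.10, monocyte: 0.10, lymphocyte: 0.05}
  dispersion: 2.0
  depth_sdlog: 0.3
  down_markers: [CX3CR1, GPR34, GPR183, P2RY12, P2RY13, ADGRG1]
  down_fold: 0.25
  up_markers: [CXCR4]
  up_fold: 3.0
  up_also_in_monocyte: true
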