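# Demo configuration for run_pipeline(); paths are resolved by the caller.
panel: toy_panel.bed
hotspots: hotspots.tsv
seed: 7
n_snv: 200
n_indel: 50
depth: 1000
error_rate: 0.001
maf_model: cellline_pool
purity: 0.5
coverage_depth: 2000
depth_grid: [100, 200, 300, 400, 500, 600, 700, 800]
replicates: 5
purity_grid: [0.5, 0.4, 0.3, 0.2, 0.1]
thresholds:
  min_depth: 30
  max_normal_maf: 0.03
  maf_min: 0.01
  maf_min_hotspot: 0.005
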