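# Demonstration pipeline configuration: three ecotypes along the
# temperature x depth gradient of a hot-spring mat, sequenced with nominal
# homopolymer error rates. Structure mirrors pipelineConfig().
reference:
  length: 324
ecotypes:
  - id: E1
    niche_center: [60, 250]
    niche_breadth: [2.5, 220]
    weight: 1
    n_hfs: 3
    n_lfs: 2
  - id: E2
    niche_center: [63, 400]
    niche_breadth: [2.5, 220]
    weight: 1
    n_hfs: 3
    n_lfs: 2
  - id: E3
    niche_center: [65, 600]
    niche_breadth: [2.5, 220]
    weight: 1
    n_hfs: 3
    n_lfs: 2
haplotypes:
  within_distance: 2
  separation: 5
grid:
  temperatures: [60, 63, 65]
  depths: [200, 400, 600]
reads:
  depth_per_sample: 600
  p_ins: 0.01
  p_del: 0.005
  run_length_exponent: 0
hfs_threshold: 50
demarc:
  n_replicates: 150
  slack: 0
  npop_max: 6
ordtest:
  n_perm: 999
modes: [conservative, fine]
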