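# Default EPN/LPP component definitions for 256-net (257-channel) data.
# Cluster sensor ids live in the cluster_*.json files next to this one.
EPN:
  cluster_file: cluster_epn_hcgsn256.json
  fixed_window: [240, 300]
  search_range: [150, 350]
  span: 60
  direction: -1
LPP:
  cluster_file: cluster_lpp_hcgsn256.json
  fixed_window: [380, 480]
  search_range: [350, 750]
  span: 100
  direction: 1
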