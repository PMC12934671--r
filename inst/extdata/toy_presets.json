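{
  "all_pass_nonTYR": {"group": "nonTYR"},
  "all_pass_TYR": {"group": "TYR"},
  "all_pass_noAPE": {"group": "noAPE"},
  "violate_spatial": {"group": "nonTYR", "violate": "spatial"},
  "violate_dihedral": {"group": "nonTYR", "violate": "dihedral"},
  "violate_saltbr": {"group": "nonTYR", "violate": "saltbr"},
  "violate_hrd": {"group": "nonTYR", "violate": "hrd"},
  "violate_actloopNT": {"group": "nonTYR", "violate": "actloopNT"},
  "violate_actloopCT": {"group": "nonTYR", "violate": "actloopCT"}
}
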