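{
  "_comment": "SYNTHETIC stand-in sequences for testing and demos. The repeat, priming flanks, overhangs and screen anchors of a real cloning design are experiment-specific supplementary material and must be supplied by the user.",
  "pam": {
    "core": "TTA",
    "permissive_set": ["TTA", "CTA", "TCA", "TTG", "TTT"]
  },
  "design": {
    "repression_len": 20,
    "cleavage_len": 30,
    "mode_boundary": 26,
    "guides_per_gene": 3,
    "strand_mode": "template",
    "bins": 3,
    "max_homopolymer": 6,
    "arm_len": 600
  },
  "repeat_seq": "GTCGCACCCTTCATGGGTGCGACAAGAATC",
  "flanks": {
    "prime5": "ACACTCTTTCCCTACACGAC",
    "prime3": "GTTCAGACGTGTGCTCTTCC",
    "enzyme": "BsaI",
    "overhang5": "TAGT",
    "overhang3": "CGCA"
  },
  "screen": {
    "anchor5": "ACACTCTTTCCCTACACGAC",
    "anchor3": "GTTCAGACGTGTGCTCTTCC",
    "max_mm_spacer": 0
  },
  "offtarget": {
    "max_mm_reject": 1,
    "pam_scope": "permissive_set"
  }
}
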