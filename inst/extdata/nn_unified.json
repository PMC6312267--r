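{
  "name": "unified-oligonucleotide-nn",
  "description": "Unified nearest-neighbor stacking parameters for DNA/DNA duplexes in 1 M NaCl. dH in kcal/mol, dS in cal/(mol K). Stacks are keyed by the 5'->3' top-strand doublet; the ten unique entries cover all sixteen doublets via reverse-complement equivalence.",
  "units": {"dH": "kcal/mol", "dS": "cal/(mol*K)"},
  "stacks": {
    "AA": {"dH": -7.9,  "dS": -22.2},
    "AT": {"dH": -7.2,  "dS": -20.4},
    "TA": {"dH": -7.2,  "dS": -21.3},
    "CA": {"dH": -8.5,  "dS": -22.7},
    "GT": {"dH": -8.4,  "dS": -22.4},
    "CT": {"dH": -7.8,  "dS": -21.0},
    "GA": {"dH": -8.2,  "dS": -22.2},
    "CG": {"dH": -10.6, "dS": -27.2},
    "GC": {"dH": -9.8,  "dS": -24.4},
    "GG": {"dH": -8.0,  "dS": -19.9}
  },
  "initiation": {
    "GC": {"dH": 0.1, "dS": -2.8},
    "AT": {"dH": 2.3, "dS": 4.1}
  },
  "symmetry": {"dH": 0.0, "dS": -1.4},
  "salt_dS_per_phosphate_pair": 0.368,
  "gas_constant": 1.9872
}
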