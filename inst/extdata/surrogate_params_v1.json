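{
  "version": "1.0",
  "description": "Deterministic position-weight surrogate splice-site scorer. Donor: log2-odds over a 9-mer spanning [-3,+6] around the exon|intron boundary, hard GT gate at +1,+2, logistic squash. Acceptor: pyrimidine fraction of an 18-nt polypyrimidine tract plus log2-odds at two consensus positions over a 23-mer ending on the first exonic base, hard AG gate, logistic squash. Base order in frequency rows: A, C, G, T. Background frequency 0.25.",
  "background": 0.25,
  "donor": {
    "window": 9,
    "offsets": [-3, -2, -1, 3, 4, 5, 6],
    "freq": {
      "-3": [0.33, 0.37, 0.18, 0.12],
      "-2": [0.56, 0.14, 0.15, 0.15],
      "-1": [0.42, 0.06, 0.42, 0.10],
      "3":  [0.55, 0.03, 0.39, 0.03],
      "4":  [0.71, 0.08, 0.12, 0.09],
      "5":  [0.07, 0.06, 0.81, 0.06],
      "6":  [0.16, 0.17, 0.22, 0.45]
    },
    "gate": { "1": "G", "2": "T" },
    "logistic": { "k": 1.0, "s0": 4.2 }
  },
  "acceptor": {
    "window": 23,
    "ppt_positions": [1, 18],
    "ppt_weight": 9.0,
    "freq": {
      "20": [0.10, 0.35, 0.10, 0.45],
      "23": [0.25, 0.12, 0.50, 0.13]
    },
    "gate": { "21": "A", "22": "G" },
    "logistic": { "k": 1.4, "s0": 8.5 }
  }
}
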