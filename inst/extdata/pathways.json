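[
  {
    "name": "WL",
    "genes": ["fwdB", "ftr", "mch", "mtd", "cdhA", "cdhB", "cdhC", "cdhD", "cdhE"],
    "key_genes": ["cdhA", "cdhB", "cdhC", "cdhD", "cdhE"],
    "partial_min_key": 2,
    "note": "Wood-Ljungdahl (reductive acetyl-CoA) pathway. The non-key gene list is a configurable placeholder; the key cluster is the archaeal-type CODH/ACS cdhABCDE."
  },
  {
    "name": "methane_key",
    "genes": ["mcrA", "mcrB", "mcrC", "mcrD", "mcrG"],
    "key_genes": ["mcrA", "mcrB", "mcrC", "mcrD", "mcrG"],
    "partial_min_key": 2,
    "note": "Methyl-coenzyme M reductase key cluster."
  },
  {
    "name": "mtr",
    "genes": ["mtrA", "mtrB", "mtrC", "mtrD", "mtrE", "mtrF", "mtrG", "mtrH"],
    "partial_min_key": 2,
    "note": "Tetrahydromethanopterin S-methyltransferase subunits; no key cluster, so a single subunit (e.g. mtrH alone) is called absent under the majority rule."
  }
]
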