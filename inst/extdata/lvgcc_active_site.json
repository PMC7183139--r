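{
  "residues": [
    {
      "chain": "A",
      "resname": "ILE",
      "resno": 51
    },
    {
      "chain": "A",
      "resname": "THR",
      "resno": 52
    },
    {
      "chain": "A",
      "resname": "MET",
      "resno": 53
    },
    {
      "chain": "A",
      "resname": "SER",
      "resno": 78
    },
    {
      "chain": "A",
      "resname": "PHE",
      "resno": 79
    },
    {
      "chain": "A",
      "resname": "LEU",
      "resno": 82
    },
    {
      "chain": "A",
      "resname": "ASN",
      "resno": 83
    },
    {
      "chain": "A",
      "resname": "LEU",
      "resno": 86
    },
    {
      "chain": "B",
      "resname": "LEU",
      "resno": 148
    },
    {
      "chain": "B",
      "resname": "THR",
      "resno": 149
    },
    {
      "chain": "B",
      "resname": "GLY",
      "resno": 150
    },
    {
      "chain": "B",
      "resname": "LEU",
      "resno": 170
    },
    {
      "chain": "B",
      "resname": "PHE",
      "resno": 171
    },
    {
      "chain": "B",
      "resname": "GLY",
      "resno": 174
    },
    {
      "chain": "B",
      "resname": "ASN",
      "resno": 175
    },
    {
      "chain": "B",
      "resname": "LEU",
      "resno": 178
    },
    {
      "chain": "B",
      "resname": "LEU",
      "resno": 179
    },
    {
      "chain": "B",
      "resname": "PHE",
      "resno": 182
    },
    {
      "chain": "C",
      "resname": "THR",
      "resno": 246
    },
    {
      "chain": "C",
      "resname": "PHE",
      "resno": 247
    },
    {
      "chain": "C",
      "resname": "PHE",
      "resno": 274
    },
    {
      "chain": "C",
      "resname": "PHE",
      "resno": 275
    },
    {
      "chain": "C",
      "resname": "ASN",
      "resno": 278
    },
    {
      "chain": "C",
      "resname": "ILE",
      "resno": 279
    },
    {
      "chain": "D",
      "resname": "ALA",
      "resno": 342
    },
    {
      "chain": "D",
      "resname": "THR",
      "resno": 343
    },
    {
      "chain": "D",
      "resname": "GLY",
      "resno": 345
    },
    {
      "chain": "D",
      "resname": "ALA",
      "resno": 369
    },
    {
      "chain": "D",
      "resname": "PHE",
      "resno": 370
    },
    {
      "chain": "D",
      "resname": "ILE",
      "resno": 373
    },
    {
      "chain": "D",
      "resname": "ASN",
      "resno": 374
    },
    {
      "chain": "D",
      "resname": "VAL",
      "resno": 377
    }
  ]
}
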