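{
  "_comment": [
    "Template profile for PDB entry 8WB4 (cryptophyte PSII-ACPII supercomplex).",
    "Only the universal chlorophyll and lipid component codes are filled in.",
    "The codes used by this deposition for alloxanthin, alpha-carotene,",
    "crocoxanthin and monadoxanthin are entry-specific and must be read from",
    "the downloaded file's chemical components, then added below (value =",
    "ALX, ACAR, CRO or MON). Likewise fill naming_map with the entry's",
    "chain ids mapped to subunit labels (ACPII-1..6, CCPII-S, CP43, CP47,",
    "D1, D2, Unk1..3, ...) for both monomers; values starting with '_' are",
    "ignored as placeholders."
  ],
  "code_map": {
    "CLA": "CHL_A",
    "KC1": "CHL_C",
    "KC2": "CHL_C",
    "LMG": "LMG",
    "SQD": "SQD",
    "LHG": "LHG"
  },
  "naming_map": {}
}
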