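{
  "_comment": "Profile for synthetic fixtures written by make_fixture(). Chlorophylls reuse the real component codes; the carotenoid codes ALX/ACA/CRX/MND are synthetic stand-ins (no universal codes exist for alloxanthin, crocoxanthin, monadoxanthin).",
  "code_map": {
    "CLA": "CHL_A",
    "KC1": "CHL_C",
    "KC2": "CHL_C",
    "ALX": "ALX",
    "ACA": "ACAR",
    "CRX": "CRO",
    "MND": "MON",
    "LMG": "LMG",
    "SQD": "SQD",
    "LHG": "LHG"
  },
  "naming_map": {}
}
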