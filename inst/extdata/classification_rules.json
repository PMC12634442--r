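{
  "version": "1.0",
  "note": "Editable molecular classification rule content. Fusion patterns are 'A::B' gene pairs (partner order ignored), 'GENE::*' wildcards, or 'GENE-r' rearrangement patterns that also cover validated enhancer-hijack events targeting the gene. Tier membership of proposed versus rare/novel patterns is intentionally editable so new diagnostic markers can be adopted by a rules update alone.",
  "who_fusions": [
    "RUNX1::RUNX1T1",
    "CBFB::MYH11",
    "KMT2A::*",
    "PML::RARA",
    "NUP98::*",
    "MECOM-r",
    "DEK::NUP214",
    "RBM15::MRTFA",
    "KAT6A::CREBBP",
    "FUS::ERG",
    "PICALM::MLLT10"
  ],
  "who_mutations": [
    "NPM1",
    "CEBPA",
    "TP53:biallelic"
  ],
  "proposed_class_fusions": [
    "CBFA2T3::GLIS2",
    "MYB::GATA1",
    "CDK6::HOXA13",
    "TBL1XR1::RARB",
    "BCL11B-r",
    "HOXA13-r",
    "HOXA10-r",
    "RUNX1::CBFA2T3"
  ],
  "proposed_class_mutations": [
    "CBFB",
    "UBTF"
  ],
  "aml_mr_genes": [
    "ASXL1",
    "BCOR",
    "EZH2",
    "RUNX1",
    "SF3B1",
    "SRSF2",
    "STAG2",
    "U2AF1",
    "ZRSR2"
  ],
  "aml_mr_cyto": [
    "5q-",
    "mono7",
    "7q-",
    "11q-",
    "12p-",
    "17p-",
    "i17q",
    "complex"
  ]
}
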