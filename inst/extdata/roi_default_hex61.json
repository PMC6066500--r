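{
  "rois": {
    "iM1": ["C3", "E002", "E003", "E004", "E005", "E006", "E007"],
    "iPAR": ["E032", "E016", "E033", "E031", "E055", "E017", "E053", "E015", "E054", "E056", "E034", "E052", "E030", "E018", "E014", "E057", "E051", "E035", "E029", "E019", "E013"],
    "cM1": ["E020", "E038", "E039", "E061", "E021", "E037", "E008"],
    "cPAR": ["E060", "E059", "E061", "E036", "E037", "E058", "E020", "E038", "E008", "E039", "E021", "E009", "E040", "E022", "E010", "E041", "E023", "E011", "E024", "E042", "E012"],
    "iPMd": ["E012", "E011", "E025", "E027", "E026", "E024", "E010"],
    "iPf": ["E026", "E045", "E046", "E025", "E047", "E012", "E027"],
    "iMedPr": ["E058", "E036", "E059", "E060", "E037", "E008", "E061"],
    "iV1": ["E058", "E059", "E036", "E060", "E037", "E061", "E008"]
  },
  "primary_pair": ["iM1", "iPAR"],
  "control_pairs": [
    ["iM1", "cPAR"],
    ["iM1", "cM1"],
    ["iM1", "iPMd"],
    ["iM1", "iPf"],
    ["iM1", "iMedPr"],
    ["iM1", "iV1"]
  ]
}
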