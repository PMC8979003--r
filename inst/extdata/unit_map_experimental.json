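{
  "description": "Experimentally determined polycistronic transcription-unit map of the M. brunneum ARSEF 3297 and B. bassiana mitogenomes (RT-PCR and Northern hybridization evidence). Gene lists are ordered in transcription direction; 'nested' genes lie within a listed gene's span; sizes are approximate transcript sizes in kb per species. The unit VI tRNA reported ambiguously as trnV(trnL) is stored as trnV with an alias.",
  "units": [
    {
      "label": "I",
      "genes": ["rnl"],
      "nested": ["rps3"],
      "size_kb_bb": 5.0,
      "size_kb_mb": 4.7
    },
    {
      "label": "II",
      "genes": ["trnT", "trnE", "trnM1", "trnM2", "trnL1", "trnA", "trnF", "trnK", "trnL2", "trnQ", "trnH", "trnM3", "nad2", "nad3", "atp9"],
      "size_kb_bb": 4.5,
      "size_kb_mb": 3.5
    },
    {
      "label": "III",
      "genes": ["cox2", "trnR1", "nad4L", "nad5", "cob", "trnC"],
      "size_kb_bb": 6.0,
      "size_kb_mb": 5.0
    },
    {
      "label": "IV",
      "genes": ["cox1", "trnR2"],
      "size_kb_bb": 4.5,
      "size_kb_mb": 2.0
    },
    {
      "label": "V",
      "genes": ["nad1", "nad4", "atp8", "atp6"],
      "size_kb_bb": 6.0,
      "size_kb_mb": 4.0
    },
    {
      "label": "VI",
      "genes": ["rns", "trnY", "trnD", "trnS", "trnN", "cox3", "trnG", "nad6", "trnV", "trnI", "trnS2", "trnW", "trnP"],
      "alias": {"trnV": "trnL"},
      "size_kb_bb": 5.0,
      "size_kb_mb": 5.5
    }
  ]
}
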