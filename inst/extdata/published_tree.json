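{
  "description": "Reference severity tree encoding the published shape/weight overvaluation cutpoints; thresholds only, no fitted node parameters.",
  "covariate": "overvaluation",
  "thresholds": [1.25, 3.75, 4.75, 5.75],
  "group_definitions": [
    "overvaluation < 1.25",
    "overvaluation 1.25-3.74",
    "overvaluation 3.75-4.74",
    "overvaluation 4.75-5.74",
    "overvaluation >= 5.75"
  ]
}
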