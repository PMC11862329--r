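{
  "species": "Calathea crotalifera",
  "source": "PADRINO IPM database entry (Westerband & Horvitz model); vital-rate coefficients require transcription and are not shipped",
  "drivers": [
    {"name": "canopy_openness"},
    {"name": "photosynthetic_rate"}
  ],
  "expected_lambda_regime": "<1"
}
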