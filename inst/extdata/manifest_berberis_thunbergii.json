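{
  "species": "Berberis thunbergii",
  "source": "PADRINO IPM database entry (Merow et al. model); vital-rate coefficients require transcription and are not shipped",
  "drivers": [
    {"name": "temp_warmest_month"},
    {"name": "may_precipitation"},
    {"name": "par"},
    {"name": "soil_nitrogen"},
    {"name": "soil_ph"}
  ],
  "expected_lambda_regime": ">1"
}
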