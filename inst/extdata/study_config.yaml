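# Example two-window study configuration (synthetic demo values).
windows:
  w1_start: 2003-01-01
  w1_end: 2004-12-31
  w2_start: 2006-01-01
  w2_end: 2007-12-31
anchor_codes: [bp_measurement]
alpha: 0.05
min_discordant: 0
strict: false
cutoffs:
  sbp:
    - event_code: sbp_ge_140
      lower: 140
  bmi:
    - event_code: bmi_25_30
      lower: 25
      upper: 30
    - event_code: bmi_ge_30
      lower: 30
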