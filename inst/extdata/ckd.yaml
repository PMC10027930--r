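# CKD stage definitions and pathophysiology deltas.
egfr_normal: 106.78        # mL/min/1.73 m2, reference adult male
stages:
  "3": {egfr_min: 31, egfr_max: 60, dpep1_factor: 0.69}
  "4": {egfr_min: 16, egfr_max: 30, dpep1_factor: 0.64}
  "5": {egfr_min: 1,  egfr_max: 15, dpep1_factor: 0.64}
# Minimal documented pathophysiology delta set: kidney volume and renal
# blood flow scale with the eGFR ratio; everything else inherits healthy
# values.
deltas:
  kidney_volume_propto_egfr: true
  renal_flow_propto_egfr: true
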