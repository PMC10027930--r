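# Simulated meropenem dosing regimens per CKD stage: conventional (30 min)
# and prolonged (3 h) infusions.
stage3:
  - {dose_mg: 1000, interval_h: 6,  infusion_h: 0.5, label: "1000 mg q6h / 30 min"}
  - {dose_mg: 1000, interval_h: 6,  infusion_h: 3,   label: "1000 mg q6h / 3 h"}
  - {dose_mg: 1000, interval_h: 8,  infusion_h: 0.5, label: "1000 mg q8h / 30 min"}
  - {dose_mg: 1000, interval_h: 8,  infusion_h: 3,   label: "1000 mg q8h / 3 h"}
  - {dose_mg: 500,  interval_h: 8,  infusion_h: 0.5, label: "500 mg q8h / 30 min"}
  - {dose_mg: 500,  interval_h: 8,  infusion_h: 3,   label: "500 mg q8h / 3 h"}
stage4:
  - {dose_mg: 1000, interval_h: 8,  infusion_h: 0.5, label: "1000 mg q8h / 30 min"}
  - {dose_mg: 1000, interval_h: 8,  infusion_h: 3,   label: "1000 mg q8h / 3 h"}
  - {dose_mg: 500,  interval_h: 8,  infusion_h: 0.5, label: "500 mg q8h / 30 min"}
  - {dose_mg: 500,  interval_h: 8,  infusion_h: 3,   label: "500 mg q8h / 3 h"}
stage5:
  - {dose_mg: 1000, interval_h: 8,  infusion_h: 0.5, label: "1000 mg q8h / 30 min"}
  - {dose_mg: 1000, interval_h: 8,  infusion_h: 3,   label: "1000 mg q8h / 3 h"}
  - {dose_mg: 500,  interval_h: 8,  infusion_h: 0.5, label: "500 mg q8h / 30 min"}
  - {dose_mg: 500,  interval_h: 8,  infusion_h: 3,   label: "500 mg q8h / 3 h"}
  - {dose_mg: 500,  interval_h: 12, infusion_h: 0.5, label: "500 mg q12h / 30 min"}
  - {dose_mg: 500,  interval_h: 12, infusion_h: 3,   label: "500 mg q12h / 3 h"}
  - {dose_mg: 1000, interval_h: 24, infusion_h: 0.5, label: "1000 mg q24h / 30 min"}
  - {dose_mg: 1000, interval_h: 24, infusion_h: 3,   label: "1000 mg q24h / 3 h"}
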