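# Meropenem dosing regimens evaluated in the intermittent-hemodialysis
# population (one-week horizon, 40% fT>MIC target).
regimens:
  - {dose_mg: 250,  interval_h: 24, infusion_h: 0.5, label: "0.25 g once daily"}
  - {dose_mg: 250,  interval_h: 12, infusion_h: 0.5, label: "0.25 g q12h"}
  - {dose_mg: 500,  interval_h: 24, infusion_h: 0.5, label: "0.5 g once daily"}
  - {dose_mg: 500,  interval_h: 12, infusion_h: 0.5, label: "0.5 g q12h"}
  - {dose_mg: 1000, interval_h: 24, infusion_h: 0.5, label: "1 g once daily"}
mics_mg_L: [1, 2, 4, 8]
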