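# Intermittent hemodialysis settings (high-flux dialyzer, thrice weekly).
bfr_mL_min: 200          # blood flow rate
dfr_mL_min: 500          # dialysate flow rate
koa_mL_min: 188          # mass-transfer coefficient x membrane area
session_duration_h: 4
weekly_pattern: [0, 2, 4]     # session days within a 7-day week (Mon/Wed/Fri)
session_start_h: 0            # clock hour of session start on session days
dose_to_session_offset_h: 0   # dose start relative to session start on
                              # dialysis days (0 = infusion begins with the
                              # session; influential, kept explicit)
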