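# Meropenem PBPK input parameters (literature/optimized compilation).
# Kinetic constants are converted to internal units (umol/L, L, min) on load.
drug:
  name: meropenem
  molecular_weight: {value: 383.46, unit: g/mol}
  pka_acid: 3.47
  pka_base: 9.39
  logP: 1.25
  water_solubility: {value: 5.63, unit: mg/mL}
  binding_partner: albumin
  fu: {value: 98, unit: percent}
  gfr_fraction: 1.00
processes:
  - name: DPEP1
    direction: metabolism_intracellular
    km: {value: 3.56, unit: mM}
    vmax: {value: 79.34, unit: umol/L/min}
  - name: OAT3
    direction: uptake_basolateral
    km: {value: 847, unit: uM}
    vmax: {value: 18156.72, unit: umol/L/min}
  - name: NPT1
    direction: efflux_apical
    km: {value: 755.89, unit: uM}
    vmax: {value: 57.64, unit: umol/L/min}
conventions:
  # Effective secretory reference volume: Vmax (umol/L/min) entries are
  # multiplied by this volume to obtain total transport capacity (umol/min).
  # Calibrated so the OAT3 entry reproduces adult meropenem tubular-secretion
  # clearance; scaled with kidney volume in disease states.
  vmax_reference_volume_L: 0.0059
  # First-order tubular-lumen -> urine drain rate (1/min).
  lumen_drain_per_min: 0.12
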