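# Imposed xylem water boundaries: sink 2 constant uptake 2e-8 m^3/s, sink 1
# swept between -1e-8 (evaporation) and 2e-8 m^3/s by the driver; source
# evaporation balances the net sink water flow.
name: xylem_sweep
hydraulic_mode: xylem_coupled
source:
  v0: 1.25e-8
  evaporation_mode: balance_sinks
sinks:
- v_max: 1.25e-8
  K_m: 75.0
  pathway_length: 0.25
  water_boundary: {type: imposed_flux, q: 2.0e-8}
- v_max: 1.25e-8
  K_m: 75.0
  pathway_length: 0.25
  water_boundary: {type: imposed_flux, q: 2.0e-8}
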