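# Tuber vs root: tuber water uptake permeability reduced by 90%.
name: tuber_root
hydraulic_mode: xylem_coupled
source:
  v0: 1.25e-8
sinks:
- v_max: 1.25e-8
  K_m: 75.0
  pathway_length: 0.25
  water_boundary: {type: soil_coupled, permeability_factor: 0.1}
- v_max: 1.25e-8
  K_m: 75.0
  pathway_length: 0.25
  water_boundary: {type: soil_coupled, permeability_factor: 1.0}
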