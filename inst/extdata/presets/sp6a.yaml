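# As efflux_factorial, with SWEET v_max reduced by 40% (SP6A mitigation).
name: sp6a
hydraulic_mode: xylem_coupled
source:
  v0: 2.0e-9
sinks:
- v_max: 5.0e-9
  K_m: 75.0
  pathway_length: 0.1
  water_boundary: {type: evaporating, fraction: 0.1}
- v_max: 5.0e-9
  K_m: 75.0
  pathway_length: 0.3
  water_boundary: {type: soil_coupled, permeability_factor: 1.0}
radial_sucrose:
  sweet_efflux: {v_max: 0.148, K_m: 70.0}
  sweet_retrieval: {v_max: 0.148, K_m: 10.0}
  sut_retrieval: {v_max: 0.117, K_m: 1.0}
  sp6a_factor: 0.6
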