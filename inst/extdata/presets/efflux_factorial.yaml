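# Young leaf (0.1 m, evaporating) vs root/tuber (0.3 m, soil-coupled) with
# equal baseline sink kinetics and SWEET/SUT radial sucrose exchange along
# both long-distance pathways. The apoplast removal rate is the calibrated
# package value (maximum net efflux fraction about 23% of loading over the
# standard loading scan).
name: efflux_factorial
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
  sp6a_factor: 1.0
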