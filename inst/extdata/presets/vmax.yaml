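# Sink-strength scenario: two sinks differing only in v_max (22.5 vs 2.5 nmol/s).
name: vmax
hydraulic_mode: phloem_only
source:
  v0: 1.25e-8
sinks:
- v_max: 2.25e-8
  K_m: 75.0
  pathway_length: 0.25
  r_ref: 7.5e+12
- v_max: 2.5e-9
  K_m: 75.0
  pathway_length: 0.25
  r_ref: 7.5e+12
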