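# Sink-affinity scenario: equal v_max (12.5 nmol/s), K_m 75 vs 750 mM.
name: km
hydraulic_mode: phloem_only
source:
  v0: 1.25e-8
sinks:
- v_max: 1.25e-8
  K_m: 75.0
  pathway_length: 0.25
  r_ref: 7.5e+12
- v_max: 1.25e-8
  K_m: 750.0
  pathway_length: 0.25
  r_ref: 7.5e+12
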