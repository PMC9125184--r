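# Pathway-resistance scenario: lengths 0.25 vs 5 m (lumped 7.5e12 vs 1.5e14
# mol s m^-6). The viscosity polynomial is clamped at its 1.5 M validity
# edge so the lumped system keeps a root near total sink capacity.
name: resistance
hydraulic_mode: phloem_only
out_of_validity: clamp
source:
  v0: 1.25e-8
sinks:
- v_max: 1.25e-8
  K_m: 75.0
  pathway_length: 0.25
  r_ref: 7.5e+12
- v_max: 1.25e-8
  K_m: 75.0
  pathway_length: 5.0
  r_ref: 1.5e+14
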