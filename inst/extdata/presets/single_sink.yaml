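# Single source, single 0.25 m pathway, single sink; used for the
# concentration-gradient and mean-resistance studies.
name: single_sink
hydraulic_mode: phloem_only
source:
  v0: 1.0e-9
sinks:
- v_max: 2.5e-8
  K_m: 75.0
  pathway_length: 0.25
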