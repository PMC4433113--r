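# Example scenario: the thin-membrane overlimiting case with a coarser mesh
# and a reduced sweep. Any omitted key falls back to the named preset.
scenario: overlimiting_thin
geometry:
  membrane_thickness_nm: 5
charges:
  sigma_mC_m2: -100
bias:
  V_left: 0.5
  V_right: 0
numerics:
  mesh_profile: coarse
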