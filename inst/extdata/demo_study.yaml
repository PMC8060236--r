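# Demo study: three synthetic branched phantoms plus a simulated cohort.
# Phantom geometry is in millimetres.
seed: 7
spacing_mm: 0.5
section_spacing_mm: 1
si_definition: feret
out_dir: demo_study_out
phantoms:
  - name: straight_90
    parent: {length: 80, radius: 8}
    branch:
      takeoff_angle_deg: 90
      origin_arclength: 40
      length: 40
      radius: 3
      cuff_end_arclength: 10
      vessel_origin_arclength: 28
      nominal_stent_length: 44
  - name: oblique_120
    parent: {length: 80, radius: 8}
    branch:
      takeoff_angle_deg: 120
      origin_arclength: 40
      length: 45
      radius: 3
      cuff_end_arclength: 12
      vessel_origin_arclength: 30
      nominal_stent_length: 50
  - name: acute_60_eccentric
    parent: {length: 80, radius: 8}
    branch:
      takeoff_angle_deg: 60
      origin_arclength: 40
      length: 40
      radius: 3
      si: 0.85
      cuff_end_arclength: 10
      vessel_origin_arclength: 26
      nominal_stent_length: 42
cohort:
  reference_cells: yes
  seed: 7
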