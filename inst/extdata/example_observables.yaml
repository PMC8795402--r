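# Observables for `ntcsim optics calibrate --observables ...`:
# the default anchor set of the reference design.
- name: axial_fwhm_um
  value: 3.15
  preset: DL
- name: square_fov_mm
  value: 0.5
  preset: DL
- name: etl_shift_um
  value: 600
  current_mA: 50
  preset: nTC1
  lens_distance_mm: 5
- name: field_sagitta_um
  value: 20
  fov_mm: 1.2
- name: field_sagitta_um
  value: 87
  fov_mm: 2.5
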