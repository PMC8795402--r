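# Example end-to-end run: small activity-scan raster of a bead phantom
# under the maximal-field nTC2 configuration.
optics:
  preset: nTC2
  lens_distance_mm: 5
  wavelength_nm: 927
scan:
  n_lines: 64
  pixels_per_line: 64
  line_period_ms: 1
  extent_um: 200
phantom:
  preset: beads
  n_emitters: 10
  volume_um: [150, 150, 30]
seed: 1
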