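# Bundled fixture provenance

- `nrel5mw_planform.tsv` — 17 aerodynamic span stations of the open 5-MW
  reference turbine blade (span position, chord, twist, airfoil family,
  thickness ratio), transcribed from the public reference definition.
- `polars/polar_*_synthetic.tsv` — SYNTHETIC lift/drag polars generated by
  `reference_polar()` from a calibrated lift-curve model (zero-lift angle,
  slope, stall onset and drag bucket per airfoil family); they are not the
  original wind-tunnel tables.
- `airfoils/naca64_90span_synthetic.dat` — SYNTHETIC stand-in for the
  64-series 90%-span profile: generated 17%-thick cambered 4-digit shape.
- `thresholds/decompression_rodent_synthetic.tsv` — SYNTHETIC rodent rapid-
  decompression records honouring the published constraints (exposures
  -45.5..-86.5 kPa, durations 0.0021..1.9 s, no mortality below 58 kPa,
  first mortality at 58.6 kPa below ambient; rat mean body mass 168 g).
- `thresholds/blast_ld50.tsv` — blast LD50 overpressures; the mouse row
  (20.7 g, 184 kPa) is the published value, the remaining rows are
  SYNTHETIC plausible fill-in for the allometric-fit helper.
- `reference_exposure_table.tsv` — published blade-surface and tip-vortex
  exposure extrema used as the comparison anchor for threshold ratios.
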