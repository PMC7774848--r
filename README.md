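# batbaro

Can the pressure transients around a utility-scale wind-turbine blade
plausibly cause fatal barotrauma in bats? `batbaro` is an R package for
wildlife–wind-energy researchers that answers this quantitatively: it
computes the pressure fields a 5-MW reference turbine creates at its blade
surface and in its blade-tip vortex, tracks bat-sized particles along grazing
flight paths through those fields, extracts the magnitude and duration of the
pressure exposure, and compares both against the rapid-decompression and
blast-overpressure levels known to kill small mammals.

## The model in brief

For a blade section at 90% span with relative wind speed `u_rel` and angle of
attack `α` (from the turbine's operating schedule at wind speeds 5, 7.5 and
10 m/s):

- **Blade field** — Hess–Smith panel method (sources + vortex sheet, Kutta
  condition); pressure from Bernoulli,
  `Cp = (p − p∞) / (½ ρ u_rel²)`.
- **Tip vortex** — Vatistas (n = 2) vortex,
  `v_θ(r̄) = Γ/(2π r_c) · r̄/√(1 + r̄⁴)`, whose radial momentum balance
  integrates to
  `p(r) − p∞ = ρΓ²/(8π² r_c²) · [atan(r̄²) − π/2]`,
  with core radius `r_c = 0.05 c̄` (0.17 m here) and strength Γ equal to the
  maximum bound circulation along the span, obtained from a blade-element
  momentum solver via the Kutta–Joukowski relation `Γ = L′/(ρ v)`.
- **Exposure** — straight (ballistic) flight paths grazing the surface to
  under 1 mm, pressure–time traces centred on their extreme, and durations
  measured against the ±5%-of-atmospheric band.
- **Thresholds** — smallest mortal rapid-decompression exposure in rodents
  (58.6 kPa below ambient) and the mouse blast LD50 (184 kPa); safety ratio
  = |threshold| / |predicted exposure|.

Everything runs offline from bundled fixtures: a transcription of the public
17-station reference planform, synthetic calibrated polars, a generated
17%-thick section shape, and threshold tables honouring the published
constraints (see `inst/extdata/MANIFEST.md`).

## Worked example

```r
library(batbaro)
fx <- reference_fixture_set()

core_radius(mean_chord(fx$planform))
#> [1] 0.1708882            # m — the 0.17 m tip-vortex core radius

exposure_summary(10, fx)
#>   u_inf_mps p_min_close_Pa p_min_far_Pa p_vortex_min_Pa p_max_close_Pa p_max_far_Pa ...
#> 1        10        -7972.4      -5712.1         -4323.5         2599.3       2081.1
```

At 10 m/s wind a bat skimming the suction side within 1 mm experiences a
~8 kPa pressure drop for under 0.01 s; 100 mm away the drop is ~5.7 kPa; the
vortex core sits ~4.3 kPa below ambient. Comparing the published exposure
table against the threshold fixtures:

```r
build_report(fx$exposure_reference, fx$decompression, fx$blast)
#> (10 m/s rows)
#>    mechanism predicted_Pa threshold_Pa ratio rounded
#>    blade_low        -7077        58600  8.28       8
#>   blade_high         2304       184000 79.86      80
#>   vortex_low        -4556        58600 12.86      13
```

The worst-case low pressure a bat can physically encounter is ~8× smaller
than the smallest exposure that kills rats, the high pressure ~80× below the
mouse LD50, and the vortex core ~13× below the rodent threshold — and the
worst cases require skimming the moving blade within a millimetre.

The full pipeline (three wind speeds, both pressure sides, both approach
directions, CSV/JSON artifacts):

```r
run_pipeline(run_config(output_dir = "run_out"))
```

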