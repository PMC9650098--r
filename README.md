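# nmtf

Simulation and analysis of diaphragm **neuromuscular transmission failure
(NMTF)** and **neuromuscular junction (NMJ) morphometry**, built around the
superimposed-stimulation technique used with the ex vivo phrenic
nerve–diaphragm (Bulbring) preparation.

During repetitive nerve stimulation, force declines both because muscle
fibres fatigue and because some fibres stop receiving nerve input
(transmission failure). The superimposition technique separates the two:
the phrenic nerve is stimulated in 40 Hz, 330-ms trains repeated each
second (33% duty cycle) for 120 s, and every 15 s the muscle is also
stimulated directly, so the force of *all* fibres — including those failing
transmission — is measured in the same train. With muscle-evoked force `MF`
and nerve-evoked force `NF` (each normalised to its initial value), the
failure statistic at each assessed epoch is

```
NMTF = − [ MF/MF_init − NF/NF_init ] / (MF/MF_init) × 100
```

reported negative (more negative = more failure), 0 when nerve- and
muscle-evoked forces decline in parallel. The package also computes
**intratrain fatigue** (post-peak force droop within a train,
`−100·(max − min)/max`), **specific force** (plateau force over the strip
cross-sectional area `weight / (Lo × 1.056 g/cm³)`), and, on the imaging
side, NMJ **apposition** (`100·|pre ∩ post|/|post|` of thresholded
projection masks), endplate/terminal **CSA**, **relative planar area**
(endplate area over its bounding rectangle) and fibre-type classification
by the joint <500 µm² / <50 µm size criteria.

Because no raw recordings are deposited for studies of this kind, the
package ships first-class synthetic generators with analytic ground truth:

- `simulate_recording()` / `simulate_cohort()` — isometric force traces
  under a parametric transmission-failure model, with stimulus marker
  channels and closed-form per-train truth;
- `render_nmj_stack()` / `generate_nmj_cohort()` — two-channel
  (α-bungarotoxin / synaptophysin) confocal z-stacks with known masks,
  areas and overlap.

Every analyzer is validated by round-trip recovery of the generator's
closed forms.

## Worked example

```r
library(nmtf)

# a preparation calibrated to the vehicle group: initial NMTF −12.6%,
# final NMTF −65.4%, end-of-run intratrain fatigue −1.9%
model <- group_calibrations()$vehicle
rec   <- simulate_recording(stim_protocol(), prep_metadata(), model, seed = 1)
a     <- analyze_recording(rec)
a
#> <nmtf_analysis> A1 (vehicle): specific force 22.4 N/cm^2,
#>   initial NMTF -12.6%, final NMTF -65.1%, intratrain -6.1%
tidy(a)
#> # A tibble: 4 × 5
#>   animal_id group   sex    statistic                 value
#>   <chr>     <chr>   <chr>  <chr>                     <dbl>
#> 1 A1        vehicle female specific_force            22.4
#> 2 A1        vehicle female initial_nmtf             -12.6
#> 3 A1        vehicle female final_nmtf               -65.1
#> 4 A1        vehicle female final_intratrain_fatigue  -6.05
```

The recovered statistics land within a fraction of a point of the
calibration's closed-form truths (specific force 22.3 N/cm², initial NMTF
−12.6%, final NMTF −65.4%) — the residuals come from the 0.5% force noise;
the
noisy intratrain value overshoots its −1.9% truth because a within-train
minimum is a min statistic — on a noise-free trace it is exact.

On the imaging side:

```r
r <- render_nmj_stack(nmj_shape_params(seed = 1))   # 417 µm², 60.7%, 48.7%
measure_nmj(r$stack)[, 1:5]
#> # A tibble: 1 × 5
#>   apposition endplate_csa terminal_csa orthogonal_area relative_planar_area
#>        <dbl>        <dbl>        <dbl>           <dbl>                <dbl>
#> 1       60.2         418.         265.            869.                 48.1
```

`run_end_to_end(run_config(), "out/")` chains
simulate → analyze → report and writes tidy CSV tables plus a provenance
manifest; reruns with the same config and seed are bit-identical.

## Vignette

`vignettes/nmtf-methods.Rmd` documents the failure model and its closed
forms, the NMJ renderer, the numerical choices (smoothing, settling
windows, thresholds, tie-breaks), what the generators do and do not emulate
about real recordings, and known limitations.
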