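---
title: "Models and methods: simulated NMTF assays and NMJ morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: simulated NMTF assays and NMJ morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmtf)
```

## The measurement problem

When a muscle is driven through its nerve at tetanic rates, force falls for
two reasons that a single force trace cannot separate: the fibres fatigue,
and some fibres stop being activated at all because neuromuscular
transmission fails. The superimposed-stimulation assay separates them by
periodically driving the muscle directly — direct stimulation activates
every fibre, failed transmission or not, so the directly evoked force
tracks pure muscle fatigue while the nerve-evoked force tracks fatigue
*plus* transmission failure. With both normalised to their initial values,

$$\mathrm{NMTF}(t) = -\,\frac{MF(t)/MF_{init} - NF(t)/NF_{init}}
{MF(t)/MF_{init}} \times 100,$$

which is 0 whenever the two normalised forces decline in parallel (any
amount of pure muscle fatigue) and grows in magnitude only with
nerve-specific loss. We store the negated magnitude so that failure is
negative, matching how these results are conventionally reported; the
epoch-0 value is identically zero because both normalised forces are 1
there.

The package implements the full assay — protocol description, train
detection, plateau measurement, the NMTF time course, intratrain fatigue,
and specific-force normalisation — together with a generator of synthetic
recordings whose ground truth is known in closed form, so every stage of
the analysis is testable without access to laboratory data.

## The force generator

`simulate_recording()` renders the standard protocol (40 Hz trains of
330 ms once per second, 33% duty cycle, 120 s, direct muscle stimulation
superimposed on the second half of a train every 15 s) over a
`failure_model()` with two processes indexed by protocol progress
$s \in [0,1]$ (0 at the first train, 1 at the last):

- transmission failure $f(s) = f_0 + (f_{end}-f_0)\,s^{\gamma}$, removing
  force from nerve-evoked contractions only;
- muscle fatigue $m(s) = 1 - (1-m_{end})\,s^{\phi}$, scaling everything.

The nerve-evoked plateau of the train at progress $s$ is
$P\,m(s)\,(1-f(s))$ and the superimposed whole-muscle plateau is
$P\,m(s)$, with $P$ the initial tetanic force
(`peak_specific_force` × strip CSA). A within-train droop of the
nerve-driven component ramps linearly from 0 to $d_{end}$ across the run.
These closed forms make the ground truth exact: final NMTF is
$-100\,(1-(1-f_{end})/(1-f_0))$, initial NMTF is $-100 f_0$, intratrain
fatigue at the end is $-100\,d_{end}$, and
`calibrate_failure_model()` inverts the first relation so a target
normalised nerve force (hence a target printed group mean) can be dialled
in directly.

Key parameters and defaults:

| parameter | default | meaning |
|---|---|---|
| `peak_specific_force` | 22.3 N/cm² | initial 40 Hz tetanic specific force |
| `rise_tau` | 25 ms | tetanic rise time constant |
| `relax_tau` | 30 ms | post-train relaxation |
| `noise_sd` | 0.005 | force noise, fraction of initial force |
| `gamma`, `fatigue_shape` | 1.5 | ramp exponents (accelerating time courses) |
| sampling rate | 1 kHz | transducer rate (unreported in such studies; configurable) |

Three deliberate idealisations matter for exact recoverability:

1. **Fused tetanus.** The 40 Hz ripple is not rendered; the envelope is a
   normalised mono-exponential that reaches its plateau *exactly* at
   $5\tau$ and holds it. All analysed statistics are plateau peaks, so
   per-pulse structure would add cost without changing any estimate.
2. **Settling windows.** The plateau is held flat for 8 ms before droop
   begins, and droop reaches its floor 8 ms before the end of each
   assessed window. A peak extractor that smooths with a 5-ms moving
   average therefore reads plateau maxima and droop minima exactly on
   noise-free input — the generator never hides its ground truth inside a
   transient shorter than the analyzer's smoother.
3. **End-anchored ramps.** With one train per second for 120 s there are
   train onsets at 0..119 s, and only eight of them are multiples of 15 s.
   The generator therefore always superimposes the final train as well, and
   anchors $s=1$ there, so the nine assessed epochs span the full run and
   the "120-s" statistics are read from a train whose parameters equal the
   model's end-of-run values exactly.

Group calibrations (`group_calibrations()`) set $f_0$, $f_{end}$ and
$d_{end}$ so each group's closed-form initial NMTF, final NMTF and
end-of-run intratrain fatigue equal the published group means of the
four-arm chemogenetic TrkB-inhibition design (vehicle, vehicle + acute
1NMPP1, chronic TKI, TKI + acute BDNF); muscle capacity at the end of the
run is 0.700 of initial in every group, since direct-muscle fatigue is
treatment-independent in this preparation. Cohort dispersion
(`draw_cohort_models()`) is multiplicative Gaussian jitter per animal with
CVs chosen once from the reported 95% confidence intervals mapped through
the closed forms (f0 0.6, f_end 0.05, m_end 0.05, d_end 0.4), clamped to
the physical ranges.

## Trace analysis

`detect_trains()` groups nerve-marker pulses into trains (the primary path;
the stimulator's grid is authoritative in a real rig too) and classifies a
train as superimposed when muscle-marker pulses fall inside it, splitting
it into the nerve-only window and the muscle window. A marker-free
fallback segments the force trace at 5% of its maximum and refines each
onset against the early-train local maximum; on noise-free input it agrees
with the marker path to ±2 samples.

`measure_trains()` smooths the trace with a 5-ms moving average
(configurable) before reading window maxima, and keeps every search half a
smoother width away from window boundaries so smoothed samples never mix
adjacent stimulation segments — without this, the nerve peak near the
muscle-stimulation onset is biased upward by a few tenths of a percent,
which is exactly the size of effect the assay is meant to resolve.
Intratrain fatigue takes the window minimum *after* the within-train
maximum and *before* the window end, so neither the rise phase nor
post-train relaxation counts as droop; the within-train minimum of a noisy
trace is still a min statistic, so on noisy input the measured droop
overshoots its truth by a few points even though peaks (maxima of smoothed
plateaus) are nearly unbiased. Deterministic droop checks therefore use
noise-free traces.

## The NMJ generator and morphometry

`render_nmj_stack()` builds a post-synaptic endplate as a "pretzel": a
wobbly closed loop plus curvilinear arms, rasterised, and thickened to the
distance-transform level set whose pixel count matches the target area.
Because the level-set threshold is chosen by order statistics, the area
target is met within pixel-tie resolution (well under the 2% contract);
an outer loop rescales the skeleton's bounding box until the
bounding-rectangle fill ratio (relative planar area) is within tolerance,
and unreachable target combinations abort with achieved-vs-requested
values rather than returning silently degraded geometry. The pre-synaptic
terminal is the top `apposition`% of endplate pixels under a smooth random
field (spatially coherent blobs, not salt-and-pepper), plus a 5% fringe
outside the endplate so that apposition (normalised to the *post* area)
differs from overlap normalised to the pre area, as in the real
measurement. Both channels share a smooth depth field that distributes the
masks across z-slices; intensities get a Gaussian PSF (default σ 0.15 µm,
a diffraction-limited value for a high-NA water objective at the default
0.176 µm/px), a background of 20 and Gaussian noise of 5% of the signal
amplitude. Ground truth (masks, areas, apposition, fill ratio) is recorded
before blur and noise.

The morphometry chain mirrors a standard projection workflow:
maximum-intensity projection over automatically selected signal-bearing
slices (a slice is kept when its 99.9th-percentile intensity clearly
exceeds the channel's background estimate — both twice the median and five
robust SDs above it, the two guards covering bright-background and
dark-background regimes); Otsu thresholding per channel (the historical
acquisition software's threshold settings are unreported, so a
parameter-free method with a logged threshold and a fixed-value override is
the reproducible choice); cleanup that removes sub-2-µm² specks and, for
the endplate channel, keeps the largest connected component; then pixel
arithmetic for areas, the bounding rectangle for orthogonal area, and
$100\,|pre \cap post|/|post|$ for apposition. Fibre diameter is supplied
metadata — measuring it from these single-junction crops is out of scope —
and classification applies the joint size criteria (<500 µm² and <50 µm →
type I/IIa; >500 µm² and >50 µm → type IIx/IIb), with boundary equality and
mixed cases flagged `excluded`: excluded junctions stay in per-animal
overall means and leave only the type-specific tables.

## Statistical layer

`stats_report()` applies, per outcome: a Shapiro-Wilk normality check; the
**single-pass** two-SD screen (mean and sample SD computed once on all
points; the rule is deliberately not iterated, and the tests pin exactly
one pass); then the ANOVA. One- and two-factor between designs use ordinary
least squares; time courses use a repeated-measures layout with the subject
stratum carrying the within-factor error, which is what degrees of freedom
like (3, 93) for 32 animals × 9 epochs imply. Tukey HSD serves
between-subject post-tests; Bonferroni pairwise comparisons are run at each
within-factor level for time-resolved group contrasts. All of this
delegates to base R's `aov`/`TukeyHSD`/`pairwise.t.test`/`shapiro.test`;
the test suite checks the F statistic against an explicit sums-of-squares
oracle to 1e-6.

`power_n_per_group()` iterates the noncentral-t power of a two-sided
two-sample t-test. For the published design assumptions (reference mean
59.0, SD 8.5, 20% detectable difference, α = 0.05, power 0.80) it returns
**10** per group, not the 8 used in the original design; the assumptions
that would produce 8 (a one-sided test, or a paired structure) are not
stated, so the function reports the computed value and this note records
the discrepancy rather than guessing.

## Problem sizes, determinism, degenerate inputs

The validation suite runs at desk scale chosen as representative rather
than exhaustive: 120-s recordings at 1 kHz (120k samples), cohorts of 8
preparations per calibration for the stochastic round trips, 20 rendered
stacks (256² × 8 × 2 voxels) for the morphometry round trips, 50
replicates for the Monte-Carlo power check. Every random draw flows from
an explicit seed (per-animal and per-stack seeds derived from a master
seed), and repeated runs are bit-identical — this is asserted, not assumed.
Degenerate inputs fail loudly with named causes: non-positive sampling
rates, geometry, weights or lengths; truncated recordings (the error names
the missing final epoch); empty masks; constant images under Otsu;
mismatched TIFF page counts or channel counts.

## What the generators do not emulate

The force model is phenomenological: no quantal release, vesicle pools,
axonal branch-point conduction, EMG or per-pulse force ripple, and droop is
a smooth ramp rather than stochastic per-fibre dropout. The stack renderer
has no optical sectioning physics beyond a Gaussian PSF, no fluorophore
spectra or bleed-through, and targets mask-level truth rather than
intensity-level realism. Passing round-trip tests therefore demonstrate
that the *analysis* is correct and unbiased for data of this structure —
they cannot certify robustness to artefacts the generators do not produce
(baseline drift, movement, uneven staining, overlapping junctions in one
field, which is why multi-NMJ fields are explicitly out of scope).
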