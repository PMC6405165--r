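---
title: "Methods: quantitative 96-well time-lapse screening of fish embryos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative 96-well time-lapse screening of fish embryos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embryoscreen)
```

# Scope

`embryoscreen` implements the computational side of plate-based embryo
screening: fish embryos injected with reporter mRNAs (or treated with
anaesthetics) are loaded one per well into a 96-well plate, imaged
automatically over one to two days of development, and quantified
semi-automatically. The package covers five analyses that share this
acquisition:

1. **Ratiometric fluorescence quantification** — which fluorescent protein
   is brightest in vivo, controlling for injection volume.
2. **Anaesthesia scoring** — a frame-differencing movement index from
   brightfield time-lapses, plus startle-response counting.
3. **Randomized plate design** — uniform random assignment of conditions
   to wells, avoiding position effects.
4. **Cross-species intensity comparison** — rescaling in-vivo window means
   onto an external (bacterial) reference scale per colour class.
5. **Codon adaptation metrics** — CAI scoring and codon-usage-driven
   back-translation ("codon averaging").

A synthetic plate generator with full ground truth ties these together:
every pipeline stage is validated against quantities the simulator
*programmed*, not against circular re-computation.

# The measurement model

## Segmentation and masked statistics

Each frame is segmented by Otsu's method: the threshold maximizing the
between-class variance of the intensity histogram. The histogram uses 256
bins over the observed range; class means are computed from exact per-bin
pixel sums (not bin midpoints), so the maximization is over the true
between-class variance of the binned partition, and ties resolve to the
lowest maximizing threshold. Foreground is *strictly above* the threshold.
These conventions make the segmentation deterministic and testable: an
exhaustive scan over all candidate splits must (and does) reproduce the
returned threshold on every tested image.

Statistics (mean, median, sample SD, area) are taken over masked pixels
only — background is **excluded, not subtracted**. Empty masks are a
flagged outcome, not an error: they feed quality control.

Two masking modes exist:

* `dual_channel_mask()` intersects the two per-channel foregrounds, so one
  region is measured in both channels.
* `quantify_series(..., mask_channel =)` masks *both* channels by a single
  channel — conventionally the injection control. This is the mode used by
  the trace pipeline: when a test fluorophore is dim relative to the camera
  noise, thresholding the dim channel itself truncates its noise
  distribution and biases the masked mean towards the upper tail (several
  percent at 4-fold dimmer than the control in our validation runs). The
  control channel's expression is condition-independent, so its mask is
  unbiased with respect to the quantity being compared.

## z-aggregation

The imager acquires a z-stack per well (12 slices in a typical run) and a
single per-timepoint value is needed. We pool area-weighted slice
statistics: the aggregate mean and SD equal exactly those of all masked
pixels pooled across slices, reconstructed from per-slice moments. The
aggregate median is the area-weighted mean of slice medians, since the
pooled median is not recoverable from summaries; both mean and median are
retained in the output, and the mean is the default quantity downstream.
This choice is a declared convention — the acquisition itself does not
dictate one — and it is the one under which aggregation is exactly
verifiable against pooled pixels.

## Ratiometric normalization

Co-injected mRNAs scale together with the injected volume, so dividing the
test channel by the reference (injection-control) channel cancels the
per-well volume. The divisor is the reference value at the acquired
timepoint **nearest 10 hpf** — acquisition grids of 20–33 minutes never
sample 10.000 hpf exactly, and no interpolation is performed. Per-well
division is the default; it differs from dividing by a plate-mean
reference exactly when volumes vary, which is the case ratiometry exists
to handle.

## Quality control

Dead and non-developing embryos ("negative wells") are dropped by checking
fluorescence at the final acquired timepoint and at the series midpoint.
A well passes a checkpoint when the mask area reaches `min_area`
(default 20 px) and the masked mean is at least `min_signal_ratio`
(default 2) times the background mean. The thresholds are configuration
parameters: the underlying screening protocol states the checkpoints but
not numeric criteria, so the defaults are declared, conservative values
under which a background-only well cannot pass (an Otsu split of pure
Gaussian noise yields an upper-class/lower-class mean ratio of ~1.4, well
below 2) while any well with signal-to-background above ~2 passes.

## Plate fusion and ranking

Plates are joined via an internal control condition present on every
plate. The first plate is the reference; every other plate is multiplied
by the ratio of control-condition means over the plates' common time
window. The window mean (not a single frame) makes the factor robust to
single-frame noise and reduces to the same answer whenever curves are
proportional; fusing already-fused plates is a fixed point (all factors 1).
Conditions are ranked by descending mean normalized intensity at the
timepoint nearest the requested time, ties broken alphabetically.

## Cross-species comparison

For comparison against intensities measured in another system, per-condition
means over 23–30 hpf (all timepoints `t` with `23 <= t <= 30`) are rescaled
within each colour class so that the class normalizer equals its external
reference value exactly (the yellow normalizer's published value is 1.2).
The operation is invariant to rescaling a class by any positive constant,
so it transfers only *relative* brightness.

## Group comparisons

Differences between conditions (per-slice light-sheet ratios, startle
counts) are tested with a two-sided Wilcoxon rank-sum test —
distribution-free and standard for such panels — and labelled with the
conventional inclusive star thresholds (`****` at p ≤ 1e-4 down to `ns`
above 0.05). When both samples are completely tied the rank statistic has
zero variance and `wilcox.test()` returns `NaN`; identical distributions
carry no evidence of a difference, so the package reports p = 1 (`ns`).

# The movement index

For anaesthesia scoring, each well's brightfield time-lapse gives
`index(t[n+1]) = mean over pixels of (frame[n+1] - frame[n])^2`. The mean
(not the sum) makes the index comparable across image sizes; the
monotone-in-movement property holds under either convention, and the
convention is recorded in the trace metadata. No registration or
background handling is applied — the minimal recipe is the point: an
immobilized embryo leaves only the camera-noise floor. Since the
difference of two independent noise fields has variance `2 * noise_sd^2`,
the floor for a static well is taken as twice that, `4 * noise_sd^2`; the
expected index of a static well sits at `2 * noise_sd^2` exactly, so the
factor-two headroom separates sampling fluctuation from real motion.

Plates started at different developmental stages are aligned by
user-supplied stage offsets (staging is a manual act); aligned traces keep
their native sampling grids and summaries are per-condition means and SDs
on each grid.

# Codon metrics

Relative adaptiveness replaces zero frequencies by a 0.5-count
pseudo-frequency and divides each codon's frequency by its synonymous
family's maximum, so weights lie in (0, 1] with one `w = 1` codon per
family. CAI is the geometric mean of weights over all scored codons,
computed in the log domain; ATG, TGG and the stop codons — positions with
no synonymous choice — are excluded by default but can be retained to
match tools that keep the `w = 1` terms. Per-thousand frequencies and raw
counts give identical results because only within-family proportions
enter.

Codon averaging back-translates a protein using a usage table, either
deterministically (each amino acid's most frequent codon, ties to the
alphabetically first) or by seeded usage-weighted sampling within each
family — the randomized strategy used by codon-averaging web tools. The
output always translates back to the input protein, and the deterministic
mode's output has CAI = 1 against the same table by construction.

Published codon-usage snapshots are unversioned, so absolute CAI values
for specific genomes are not reproducible bit-for-bit; all shipped usage
tables are synthetic and labelled as such, and validation relies on
closed-form toy tables (e.g. a glycine family with counts 30/10/5/5 giving
weights 1, 1/3, 1/6, 1/6).

# The synthetic plate generator

`simulate_plate()` renders one 16-bit TIFF per well/channel/z/timepoint
and records every drawn quantity as ground truth. Its components:

* **Expression kinetics** `(1 - exp(-t/maturation)) * exp(-t/decay)` —
  the simplest form with both an early maturation rise and the slow decay
  of injected-mRNA fluorescence over development (defaults: 2 h
  maturation, 30 h decay; stand-ins, not calibrated values, since
  per-embryo kinetics are not measurable from the published screens).
* **Injection volume** — log-normal with mean 1 and configurable CV
  (default 0.3), shared across channels of a well; positivity and
  co-scaling are the premises of ratiometric normalization.
* **Movement** — a clamped 2-D Gaussian random walk of a rigid disk
  (per-axis step SD = `movement_amplitude`); steps that would leave the
  field of view are clamped and recorded.
* **Brightfield** — the embryo darker than the background, sufficient to
  drive frame differencing.
* **Dead wells** — drawn per well with probability `dead_well_fraction`
  (default 0.1); background-only fluorescence, motionless brightfield.
* **Noise** — i.i.d. Gaussian counts per pixel (default SD 5% of the
  full-scale signal level), rounded and clamped to the 16-bit range.

Identical configurations produce byte-identical plates. Defaults mirror a
real acquisition (8 × 12 plate, 20-minute steps over 40 h, 12 z-slices,
green/red channels); the validation suites run scaled-down versions —
64-px images, 2 z-slices, 5–9 timepoints, 24–96 wells — which preserve
every property being tested while keeping runs to seconds or a few
minutes.

What the simulator does **not** emulate: optics (PSF, chorion refraction),
pigment autofluorescence, non-rigid embryo deformation, multi-embryo
wells, or intensity-dependent (shot) noise. Passing tests therefore
demonstrate the correctness of the algorithms under the stated model, not
robustness to every artefact of real plates; on real data the QC
thresholds and the masking mode are the parameters to revisit first.

# Numerical and degenerate-input conventions

* Otsu on a constant image raises a typed error; in mask construction
  this becomes a flagged empty mask, and in ratio-image measurement a
  constant (self-)ratio is measured over all included pixels.
* Ratio images exclude zero-control pixels before thresholding; an
  entirely-zero control slice is skipped and reported.
* Sample (n − 1) standard deviations throughout.
* Movement index on integer frames is exact in double precision (sums of
  squared 16-bit differences stay far below 2^53), so oracle comparisons
  are bit-exact.
* All randomized operations (layout, simulator, usage-weighted sampling)
  take explicit integer seeds and restore the caller's RNG state.

# Worked example

```{r example, eval = FALSE}
layout <- randomize_layout(c(eGFP = 8, test = 8), rows = 2, cols = 8, seed = 1)
config <- sim_config(plate_rows = 2, plate_cols = 8, image_size = 64,
                     t_start = 6, t_end = 14, t_step = 60, z_slices = 2,
                     background_level = 50, noise_sd = 500,
                     dead_well_fraction = 0, seed = 2)
models <- list(
  condition_model("eGFP", brightness = c(green = 1, red = 1)),
  condition_model("test", brightness = c(green = 2, red = 1)))
dir <- tempfile("plate")
simulate_plate(config, layout, models, dir)

idx <- discover_series(dir, time_origin = 6, time_step = 60)
agg <- aggregate_measurements(quantify_series(idx, mask_channel = "red"))
qc  <- qc_filter(agg, qc_params(), channel = "red")
tr  <- build_traces(agg, layout, "green", "red", t_norm = 10, wells = qc$kept)
rank_conditions(tr$traces, t = 10)
```

The ranking recovers the programmed 2:1 brightness ratio to within a few
percent under the default noise settings (see the package tests, which run
this end to end on a full 96-well plate with ratios spanning 0.25–4×).
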