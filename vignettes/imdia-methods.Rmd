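---
title: "Processing ion-mobility DIA data with imdia: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing ion-mobility DIA data with imdia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imdia)
```

## The problem

Trapped-ion-mobility DIA instruments (dia-PASEF-style acquisition) record,
for every chromatographic cycle and every precursor isolation window, a
two-dimensional spectrum over TIMS scan number (equivalently inverse reduced
ion mobility, 1/K0, in Vs/cm^2^) and TOF mass bin (equivalently m/z). The
mobility dimension separates peptides that co-elute and co-isolate, which
both cleans fragment spectra and — because isolation windows can be stacked
along the mobility axis — raises the effective duty cycle. Exploiting the
extra dimension requires ion-mobility-aware processing at every stage:
peak picking, chromatogram extraction, peptide-spectrum-match scoring, and
quantification. `imdia` implements that processing chain end to end,
together with a ground-truth simulator so that every stage can be validated
without vendor raw files.

## Frame geometry

A `frame_spec` fixes the acquisition geometry. Scan number maps affinely to
1/K0; mass bin index maps affinely to sqrt(m/z), reflecting a TOF
digitizer's linearity in flight time. The default desk-scale scheme uses 8
isolation windows of 75 Th covering 400–1000 Th, 120 scans over 1/K0
0.7–1.43, and 262,144 mass bins. The bin count is chosen so that one bin is
about 3.7 ppm at mid-range: the mass-accuracy machinery of the engine works
in ppm with a 10 ppm cap and a 3 ppm floor, and a much coarser mass axis
would quantize m/z more coarsely than those tolerances, making them
meaningless.

## Two-step 2D peak picking

The picker scans the 1/K0 x m/z plane with a small window described by
three tolerances:

* ion mobility tolerance in scans: `10 * (n_scans / 900) / im_range`, kept
  real-valued (the formula rarely yields integers and comparisons are
  strict);
* m/z tolerance: 2 mass bins;
* a mixed criterion: a point at offsets `(dscan, dbin)` from the window
  center contributes only when
  `|dscan| + 2 |dbin| (n_scans / 900) / im_range` is strictly below the
  mobility tolerance — the window is a diamond truncated at 2 bins, not a
  rectangle.

The window size is deliberately independent of the ramp time (the number of
scans): it reflects typical mobility peak widths, not the sampling density.
`scan_window_tolerances()` accepts overrides for experimentation.

Step 1 reports window centers whose summed signal beats every neighboring
center inside the same window shape. Ties are exact on integer counts and
must be broken deterministically; the rule is: higher raw intensity at the
center coordinate wins, then the lower mass bin, then the lower scan. The
first key makes an isolated point report at its own coordinates rather than
at the corner of its tied plateau; the remaining keys are arbitrary but
fixed. Step 2 discards a candidate maximum when a *more intense* candidate
lies within its scanning window at no more than one bin mass difference.
Suppression is evaluated against the candidate set *before* discarding, so
a suppressed maximum still suppresses weaker ones — the filter asks whether
any stronger maximum exists, not whether it survived. Each surviving peak
stores exactly three values: the m/z and 1/K0 of its center, and the window
sum as its intensity; spectra are stored sorted by m/z.

When the scheme acquires several identical frames per cycle (a duty-cycle
device), the frames are matched by window and summed point-wise *before*
picking; `pick_run()` does this merging internally.

The picker is validated against an exhaustive oracle that evaluates the
window sum at every grid position and applies both steps literally; on
random sparse frames the two agree exactly, and translation equivariance,
intensity scaling, and merge-then-pick identities hold by construction.

## Chromatogram extraction and calibration

Picked spectra are indexed per (window, cycle) with peaks ordered by mass,
so binary search finds the first and last peak inside a ppm tolerance; of
the peaks in between, those inside the ion mobility window around the
predicted 1/K0 are kept and the most intense one is reported (ties: smaller
m/z deviation). The ion mobility window is symmetric about the predicted
value — the asymmetric case has no support in the data we simulate.

Calibration is fitted from a wide first pass (identity maps, 10 ppm, 0.1
Vs/cm^2^ window, full retention range) over up to 100 sampled library
precursors scored by cosine similarity; hits with cosine above 0.5 become
the confident identifications. From these the engine fits:

* an affine library-to-observed 1/K0 map by trimmed least squares (worst
  20% of residuals removed once, then refit), with the ion mobility window
  set to the 95th percentile of the trimmed absolute residuals, floored at
  0.02 Vs/cm^2^;
* a monotone piecewise-linear retention map (quantile-binned medians made
  monotone, linearly interpolated), with the search region set to three
  times the 95th-percentile residual (floored at one cycle) around the
  mapped cycle;
* a median ppm mass correction with tolerance `min(10, max(q95, 3))` ppm,
  applied per run.

The floors keep the windows non-degenerate on noise-free synthetic data;
with fewer than 20 confident identifications the engine falls back to
identity maps with defaults and says so in the log.

## Scoring and FDR

Candidate elution peaks are local maxima of the 3-point-smoothed summed
fragment trace at which at least two fragments have signal. Each candidate
receives a feature vector: cosine similarity of outlier-down-weighted apex
intensities to the library intensities; mean profile correlation of each
fragment to the consensus of the others; ion mobility consistency (the
robust spread of the fragment apex 1/K0 values, measured as the mean
absolute deviation from their median — the median absolute deviation
collapses to exactly zero under scan quantization of apex mobilities and
carries no signal); ion mobility deviation from the
calibrated library value; retention deviation; mean absolute ppm error;
fraction of fragments detected; and log apex intensity. A fragment whose
apex mobility deviates from the fragment median by more than half the ion
mobility window is down-weighted by 0.25 before the intensity similarity is
computed; the factor is a design choice — outliers must still contribute
slightly, since a fragment can be mildly interfered rather than wrong.

Decoys are pseudo-reversed sequences (C-terminal residue fixed, fragment
m/z recomputed from the decoy sequence, mobility and retention references
inherited), one per target. Targets and decoys are scored by an ensemble of
eight single-hidden-layer feed-forward networks (`nnet`, 8 hidden units,
weight decay 0.05) with two-fold cross-scoring: each candidate is scored
only by members not trained on it, and the score is the member mean. The
whole procedure is deterministic given the seed. Below 50 candidates per
class the engine uses a fixed, label-free linear combination of the
features instead — a desk-scale guard, since a neural ensemble trained on a
handful of examples is noise.

Precursor q-values use target-decoy competition: thresholds at the target
scores, false-discovery proportion `#(decoys >= s_k) / k`, with the lowest
threshold (accepting every target) counting *all* decoys — a deliberately
conservative convention that protects the small-candidate regime — and the
q-value is the running minimum over thresholds at or below the score.
Protein groups compete picked-pair style: the protein score is its best
precursor score, each target competes with its paired decoy protein, only
the higher of the two survives, and q-values are estimated over the
survivors.

## Quantification

Accepted precursors are quantified by integrating fragment traces over apex
±2 cycles (configurable). With the ion mobility filter on, every extracted
point whose 1/K0 deviates from the consensus (median fragment apex
mobility) by more than half the ion mobility window is excluded from the
integral. The filter is applied point-wise rather than fragment-wise
because interference is transient: an interfering peptide can hijack a few
cycles of one trace while the rest of the trace is clean. Runs are
normalized by median-of-ratios to the per-feature median profile; protein
quantities solve the MaxLFQ pairwise median log-ratio system by least
squares per connected component of the run-pair graph, anchored so total
protein intensity matches total precursor intensity. Coefficients of
variation are computed on raw (unlogged) normalized quantities, and the
median CV summary covers only features quantified in every replicate.

## Two-species entrapment validation

For a mixed-species search where the entrapment species is in the library
but not in the sample, the experimental FDR at a threshold is
`[A_id / (A_id + H_id)] * [(A_lib + H_lib) / A_lib] * pi0` with
`pi0 = (A_lib + H_lib - 0.95 H_id_05) / (A_lib + H_lib)`, `H_id_05` being
the target-species calls at q = 0.05; library counts are restricted to the
acquired m/z range (400–1000 by default). The 0.95 factor is taken as
given. `entrapment_curve()` evaluates the formula at every distinct
reported q-value rather than on a fixed grid, avoiding interpolation
artifacts. Species are read off protein-group accession prefixes.

## The synthetic data generator

`simulate_run()` emulates the statistical structure of dia-PASEF data, not
its physics. Each planted precursor contributes points with expectation
`abundance x fragment relative intensity x Gaussian(cycle; apex, sigma_el)
x Gaussian(scan; mobility, sigma_im)`, normalized so the expected planted
area equals `abundance x relative intensity`, then Poisson-sampled, with
per-point Gaussian ppm jitter (sigma 3 ppm) on top of a 2 ppm systematic
run offset. MS1 frames carry the precursor signal. Interfering peptides are
planted as foreign signals colliding with 1–3 fragment m/z values of an
affected peptide, at independently drawn abundance, shifted mobility and
shifted apex. Dark counts are uniform over the frame. Defaults (200
precursors, 40 cycles, elution sigma 2 cycles, mobility sigma 1.5 scans,
log-normal abundances with meanlog log 5000 and sdlog 0.8, 2 interferers
per window, 100 dark points per frame) were chosen once as a plausible
fast-gradient regime and are the package's fixed study conditions.

What the generator does *not* emulate: isotope envelopes, charge-state
envelopes, profile-mode TOF transients, chemical noise structure,
retention-time drift within a run, and loading differences between runs.
Passing tests therefore demonstrate the correctness and calibration of the
algorithms under the stated statistical model, not instrument-grade
performance on real data.

The validation studies use fixed scaled-down conditions (`study_config()`):
an identification study (200 precursors, 40 cycles), a null study (nothing
planted) for q-value calibration over 50 seeds, an entrapment study (160
precursors, half unplanted foreign species, 20 seeds), a 45:15 two-species
spike-in in triplicate (150 precursors, 80% background species, 10 seeds),
and a doppelganger study for the ion-mobility feature ablation (20 seeds):
40% of the library entries are not planted but receive their full fragment
ladder with perturbed intensity ratios at the entry's own retention time
and a 1/K0 shifted by 0.006–0.02 Vs/cm^2^ — co-eluting interference that
retention time cannot unmask, which is exactly the scenario the mobility
features exist for. Problem sizes are chosen so each study runs in minutes
on one CPU.

Two analysis choices in the spike-in study deserve a note. First, the
spiked species is 20% of the library: median-ratio normalization assumes a
mostly-constant feature population, and a half-regulated proteome would
bias the size factors on any median-based normalizer. Second, the ratio
readout skips run normalization entirely: the simulated runs carry
identical loading by construction, so normalization could only add
spike-induced drift; with simulated loading differences it would be
enabled. At desk scale, per-protein A and B levels are aggregated across
triplicates by the median, which is robust to a single interfered
replicate.

## Numerical choices and degenerate inputs

* All comparisons in the picking criteria are as stated: the mixed
  criterion is strict (`<`), the bin and scan bounds are inclusive.
* Tie-breaks (picking centers, extraction intensity ties, picked-pair
  protein ties) are deterministic and documented above.
* Window centers at frame edges use truncated windows; there is no padding.
* Empty frames, empty spectra, and precursors outside every isolation
  window produce empty results with diagnostics, never errors.
* A degenerate mobility axis (zero 1/K0 range) and an all-constant feature
  matrix are errors and a warned fallback, respectively.
* The frame container stores intensities with 17 significant digits, so
  doubles round-trip exactly; truncated files fail with the last complete
  cycle named.
* Peptides with non-standard residues are dropped from digests with one
  warning per protein; fixed carbamidomethyl-C is always included in
  peptide masses.

## Known limitations

* The target-decoy estimator is evaluated per run; with only a handful of
  scored candidates, q-value estimates are coarse. The accept-all-decoys
  convention at the lowest threshold keeps the single-candidate case
  conservative, but TDC with tiny candidate sets is intrinsically noisy.
* The picked peak intensity is a windowed sum, so a mobility peak wider
  than the scanning window is captured only partially (roughly 70% at the
  default widths). Ratios are unaffected; absolute quantities are
  systematically scaled.
* The classifier is a desk-scale stand-in: eight small single-hidden-layer
  networks rather than a deep ensemble. Its role — turning the feature
  vector into a calibrated discriminant — is the same.
* Profile-mode (non-peak-picked) extraction is not implemented; the engine
  always starts from 2D-picked peaks.
* Library-free search, match-between-runs, PTM localization and isotope
  envelope modelling are out of scope.
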