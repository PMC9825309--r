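---
title: "Simulating DIA LC-MS/MS runs with known ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating DIA LC-MS/MS runs with known ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diasimr)
```

`diasimr` fabricates data-independent-acquisition (DIA) bottom-up proteomics
runs whose content is exactly known, so that acquisition settings and
downstream processing software can be evaluated against ground truth. This
vignette documents the model, the parameters that matter, the numerical
choices, and what the package's own tests do — and do not — demonstrate
about real data.

## The simulation model

**Input library.** A simulation starts from a precursor library: one row per
(peptide, charge) with a retention coordinate, a base abundance and a
fragment list. Three sources are supported — a Prosit-style long CSV
(retention coordinate = iRT), a MaxQuant-style evidence/msms table pair
(observed minutes; rows with modifications other than carbamidomethyl-Cys
are dropped, because fragment-intensity prediction is only reliable for that
fixed modification), and a built-in generator of tryptic-like peptides
(length 7–20 ending in K/R, charge 2–3, b/y ladders with random intensities,
lognormal abundances with median 1e5 and `sdlog = 1`, roughly one decade of
spread — a realistic dynamic range for an identification-filtered library).
Fragment intensities are always renormalized to base peak = 1 per precursor
so the sources are commensurable.

**Chromatography.** Retention coordinates are mapped affinely (order
preserving) onto `[padding, run_length − padding]`; the padding (default 5%
of the run per end) keeps elution profiles away from the run boundaries so
their areas are conserved. Each species elutes as an exponentially modified
Gaussian with Gaussian width `peak_sigma` (s), tail constant `peak_tau` (s)
and area equal to its per-sample abundance. The defaults
(`peak_sigma = 2.5`, `peak_tau = 0.8`, FWHM ≈ 6.1 s) describe a sharp modern
UHPLC peak; an optional lognormal per-precursor width jitter (`sigma_cv`)
is off by default. Peak width and gradient length are deliberately
independent settings. The affine retention map is the simplest
order-preserving choice; nonlinear gradient warping is a configuration hook
left unimplemented.

**Acquisition.** The default duty cycle is one MS1 scan followed by
contiguous fixed-width isolation windows over `[mz_min, mz_max]` (defaults
400–1000 Th, 20 Th windows). Containment is half-open, `[lower, upper)`, so
every precursor m/z belongs to exactly one default window; a schema CSV
(`ms_level, mz_lower, mz_upper, duration_s`) expresses variable-width,
overlapping and staggered schemes (staggering = the two offset window sets
listed in one long cycle). Scan durations, not instrument physics, set the
cycle time; the expected number of points per chromatographic peak (PPP) is
profile FWHM divided by cycle time.

**Spectra.** MS1 peaks are the aggregated isotope envelopes of all species
eluting at the scan time, weighted by their EMG intensity; MS2 spectra
collect every fragment of every species in the event's window with the same
weighting, so co-eluting species superimpose additively. Mass error is a
fixed systematic ppm offset plus per-peak Gaussian ppm jitter. Ionization
instability is a per-scan lognormal factor applied coherently to all peaks
of the scan, with mean exactly 1 (`meanlog = −sd²/2`) so integrated areas
stay unbiased. Additive background centroids are available (`noise_rate`)
but default off — background is primarily modelled through decoy species
read from NIST `.msp` libraries, which receive uniform random retention
times and the same lognormal abundance family as synthetic precursors, and
then behave exactly like precursors in both MS levels.

**Study designs.** Group fold changes and within-group noise are Normal on
the log2 scale — the simplest family consistent with "customizable
distributions"; the family and its parameters are recorded in the parameter
yaml. Fragment abundances inherit the precursor's per-sample multiplier (a
single coherent factor), with an optional independent per-fragment log2
jitter (default 0). Missingness is applied after abundance sampling:
group-wise blocks with probability `prob_missing_group`, single cells with
probability `prob_missing_sample`, independently; masked cells are written
as empty fields (never zero) in the ground truth.

## Tunable parameters

| key | default | unit | meaning |
|---|---|---|---|
| `run_length` | 1200 | s | gradient length |
| `peak_sigma` / `peak_tau` | 2.5 / 0.8 | s | EMG width and tail |
| `mz_min`–`mz_max`, `window_width` | 400–1000, 20 | Th | default window scheme |
| `ms1_duration` / `ms2_duration` | 0.05 / 0.02 | s | scan durations (set PPP) |
| `resolution` | 30000 | — | FWHM = m/z / R, constant across m/z |
| `ppm_systematic` / `ppm_sd` | 0 / 0 | ppm | mass accuracy |
| `spray_instability_sd` | 0 | fraction | per-scan intensity fluctuation |
| `profile_shape`, `grid_step` | centroid, 0.002 | — / Th | profile rendering |
| `isotope_max_peaks` | 5 | — | envelope truncation |
| design block | 1×1, sd 1.0/0.2 | log2 | groups, replicates, variances |

Centroid mode is the default; profile rendering multiplies data volume and
runtime severalfold for unchanged ground truth. Constant resolving power is
the simplest reading of a single "resolution" knob; analyzer-specific m/z
scaling laws are out of scope.

## Numerical choices

- **EMG evaluation.** The textbook EMG formula overflows when `sigma/tau`
  is large. Intensities are computed on the log scale with
  `pnorm(log.p = TRUE)` supplying log erfc; below `tau < 1e-4·sigma` the
  Gaussian limit is used outright, because at more extreme ratios the
  exponent `σ²/2τ²` (~10⁸ and beyond) can no longer be cancelled against
  log erfc in double precision.
- **Isotope envelopes** use truncated convolution of per-element patterns
  (exact aggregated masses binned by nucleon count; peak spacing
  1.00286864/z). Abundance fractions are *not* renormalized after
  truncation, so the retained total measures the truncation loss; peaks
  below `1e-4` of the distribution are dropped.
- **Scheduling tie-break.** Scan events are kept while
  `start + duration ≤ run_length` to a 1 ns tolerance, which makes cycle
  counts robust to floating-point accumulation in cumulative sums.
- **Coincident peaks** (within 1 µTh after mass error) are summed into one
  centroid — the superposition the instrument would report.
- **Degenerate inputs.** Empty windows still emit (empty) spectra; empty
  runs still produce valid mzML (the `spectrumList` element is optional and
  omitted by the writer); a library retention coordinate outside the
  gradient window is clamped with a warning rather than dropped.
- **Seeding.** Every random component draws from its own stream derived
  from the master seed at a fixed offset (library, profiles, design,
  missingness, decoy placement, and per-sample spray / MS1 jitter / MS2
  jitter / noise / fragment-jitter streams). Disabling one component — e.g.
  supplying no decoys — therefore leaves every other draw bit-identical,
  and a whole experiment is reproducible byte-for-byte from its replay
  file, which records the resolved configuration plus an md5 fingerprint of
  the input library.

## The built-in quantifier and the scan-speed experiment

The package ships a deliberately naive MS1 quantifier for benchmarking
against the ground truth without external search software: it integrates
the monoisotopic extracted-ion chromatogram (default ±10 ppm) with the
inter-scan spacing, gated to ±30 s around the species' known elution apex.
The gate implements targeted extraction anchored on library retention
times, standard practice in targeted quantification: without it, any
species with an indistinguishable m/z eluting *anywhere* in the run leaks
into the sum and corrupts fold changes even in noise-free data. Only the
monoisotopic trace is integrated, so recovered areas equal abundance times
the monoisotopic envelope fraction — a per-precursor constant that cancels
in fold-change ratios. PPP is counted as scans above half the trace
maximum.

The fold-change experiment in the acceptance suite mirrors a scan-speed
optimization: 1000 synthetic precursors, two groups × three replicates,
between-group log2 sd 1.0 and within-group 0.2, simulated at cycle times of
FWHM/10, FWHM/4 and FWHM/2 (≈10, 4 and 2 points per peak). Two design
choices matter here:

- **Spray instability 0.2.** A per-scan noise source is what couples
  quantitative accuracy to sampling density: integrating a *smooth* profile
  with a Riemann sum is exponentially accurate even at two points per FWHM,
  and with identical retention times across samples any deterministic
  sampling error cancels in fold-change ratios. A 20% per-scan lognormal
  fluctuation is a realistic electrospray stability figure and makes the
  integrated-area variance scale inversely with the number of scans under
  the peak, which is the mechanism by which slow cycles degrade r².
- **Three well-separated sweep points.** Because the within-group noise
  realization is shared across sweep points (the same samples are
  "re-acquired" at each scan speed), differences in r² between points are
  driven by the spray-averaging term alone. The grid FWHM/{10, 4, 2} spaces
  the expected r² drops (~0.006 and ~0.009) several standard deviations
  above their realization noise at n = 1000, so the monotone degradation is
  resolvable rather than drowned in sampling fluctuation.

Problem sizes throughout the test suite (tens to a few hundred precursors
per unit test, 1000 × 6 runs for the sweep, 5000 precursors for missingness
rates) were chosen as the smallest sizes at which each property is measured
with comfortable statistical margin.

## What the synthetic data does and does not show

The generator emulates the *structure* of DIA data — multiplexed MS2,
envelope overlap, co-elution, controlled fold changes, missingness — under
clean-room conditions: linear detector response, no ion suppression, no
dynamic-range saturation, no retention-time drift between runs, no
interfering background proteome beyond explicit decoys, monoisotopic-only
fragment masses. Chromatographically overlapping species superimpose
additively, which is most faithful to real instruments for longer gradients
or simpler mixtures. Passing tests therefore demonstrate internal
correctness of the simulation and the recoverability of its ground truth,
not that any particular search engine will reach the same numbers on real
acquisitions.

## Known limitations

- One fixed modification (carbamidomethyl-Cys); no variable modifications.
- Fragment ions carry no isotope envelopes (library fragment m/z only).
- MNAR (intensity-dependent) missingness, batch effects and run-order drift
  are not modelled.
- The MaxQuant reader consumes a column subset of one txt dialect
  (remappable via `maxquant_column_map()`), not the full txt directory.
- mzML is the only output format.
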