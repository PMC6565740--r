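---
title: "Recovering microtubule projection images from serial fiber-diffraction snapshots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering microtubule projection images from serial fiber-diffraction snapshots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>",
                      fig.width = 6, fig.height = 4)
library(helixcdi)
```

## The problem

A liquid microjet carries taxol-stabilized microtubules across a focused
XFEL beam. Every pulse scatters from roughly twenty filaments that are
flow-aligned to within a few degrees, so each detector frame is a weak
fiber-diffraction pattern whose equatorial line tracks the instantaneous
jet direction. None of the single frames supports a reconstruction on its
own; the computational task is to (i) reject frames dominated by solution
background or jet-edge scattering, (ii) group the survivors by equatorial
angle, sum them into class averages, rotationally align and merge them into
one high-signal pattern, (iii) optionally replace that pattern by a fitted,
noise-free ideal built from separable-Gaussian diffraction peaks, and
(iv) invert the result into a 2D projection density by iterative phase
retrieval with real-space support constraints. `helixcdi` implements this
chain end to end, together with a synthetic shot generator that emulates
the statistical structure of the experiment so every stage can be validated
against known ground truth.

## Models and their geometry

Two parametric stand-ins drive both simulation and phasing:

* **Featureless tube** (`tube_model()`): a uniform hollow cylinder, default
  inner/outer diameters 17.4/25.4 nm. Its analytic projection supplies the
  initial phases and the model of the unmeasurable central beam. Projected
  pixel values are exact averages of the chord-length integral over the
  pixel width, so projected mass per row equals the annulus cross-section
  exactly. The projection of an annulus `[a, b]` peaks at `|x| = a`; its
  mass-weighted mean radius is `2(b^3 - a^3) / (3(b^2 - a^2))`
  (`com_radius()`), the quantity used to parameterize starting models.

* **Sphere-helix lattice** (`sphere_helix_model()`): 4 nm spheres on a
  helix with 14 spheres per turn and a pitch of 3 spheres per turn, helical
  radius 11.2 nm, hence an outer tube diameter of 26.4 nm. Because the
  pitch is three monomers, the monomer lattice is a 3-start helix family:
  by default three interleaved copies of the generating helix, offset
  axially by one sphere, close the tube wall with vertical neighbours at
  the 4 nm monomer repeat — the actual microtubule lattice topology. This
  choice matters for the diffraction: the 3-start lattice extinguishes
  layer lines that are not multiples of 1/(4 nm), so the first and
  strongest off-equator layer line appears at 0.25 nm^-1 (4 nm) with its
  second order at 2 nm, exactly the lines the experiment shows. A single
  1-start helix would instead place its first layer line at the 12 nm
  pitch, which matches neither the data nor the monomer interpretation.
  `n_starts` exposes the choice.

The helical radius of an N-protofilament lattice scales as
`11.2 nm x N / 14`; the generator draws protofilament numbers 11-16 from a
configurable mixture, by default dominated by the 13- and 14-protofilament
forms that the analysis of the experimental data indicates
(weights 0.02/0.08/0.40/0.35/0.10/0.05 for 11-16; in vitro preparations
are reported to contain all six forms, with exact proportions depending on
the preparation, so the split is a representative choice, not a fit).

Coordinates are `(row, col)` with `x` along columns (perpendicular to the
helical axis) and `y` along rows (the axis), matching the orientation of
the reconstructions.

## The synthetic shot generator

`simulate_shot()` renders one exposure: a Poisson count of filaments (mean
20, the number implied by the 0.16 um^3 illuminated volume at 5 mg/ml),
each with an in-plane angle drawn as per-shot jet angle plus 5 degrees of
within-shot alignment jitter (the flow-alignment figure reported for
filaments in microjets), a protofilament number from the mixture, and a
discretized rotation about its own axis (16 precomputed rotations). The
per-shot jet angle is 90 +/- 25 degrees: the instantaneous jet direction
wanders substantially between exposures — single frames and class averages
of the experiment show equatorial lines tilted by tens of degrees, and
angle-of-equator variation is one of the two dominant classification
factors — and this diversity matters mechanically, because class averages
at varied angles fill each other's rotated panel-gap shadows when merged.
A narrow spread leaves the merged equator's low-q region systematically
masked and biases the recovered wall separation toward the starting
model.
Per-filament intensities add incoherently: filaments sit at random relative
positions separated by distances far exceeding the fringe spacings of
interest, so cross terms average out. Each filament projection is modulated
by the axial illumination envelope (Gaussian, FWHM 159 nm — the same
Gaussian used later as the y-support) before squaring its centered Fourier
transform.

Photon scale: a 2 mJ, 6 keV pulse carries ~2.1e12 photons
(`photons_from_pulse_energy()`); the generator's
`scattering_efficiency = 2.5e-8` detected photons per filament per
incident photon gives ~5e4 detected photons per filament, which reproduces
the regime where single frames show equatorial spots but no usable 2 nm
signal. A smooth isotropic background (mean 1 photon/pixel, exponential
radial shape normalized so a background-only frame carries exactly
`background_level` photons per unmasked pixel) stands in for solution
scattering; it is a stand-in, not a fit to the real background, which the
experiment does not characterize. Half of all frames are background-only
"misses" and 10% carry a bright jet-edge streak, mirroring the ~60% of
frames the original processing discarded. Poisson noise, a cross-shaped
panel-gap mask, 0.2% dead pixels and a central beamstop (q <= 0.02 nm^-1)
complete the frame. All draws derive from one root seed with per-shot
counter-derived seeds, so any shot can be regenerated in isolation —
`shot_source_simulated()` exploits this to stream arbitrarily long series
with bounded memory.

The default detector is a 400 x 400 grid standing in for the central region
of a tiled detector at 3x binning (330 um pitch, 565 mm distance, 2.07 A).
Its q-range (0.56 nm^-1) covers the 2 nm layer line and its conjugate real
field (354 nm) holds the axial envelope. Simulated images live on a grid
linear in spatial frequency; at these scattering angles (< 4 degrees) the
flat-detector distortion is below 0.3%, while `q_of_pixel()` implements the
exact mapping for calibration work.

What the generator does **not** emulate: inter-filament interference,
polarization and solid-angle corrections, detector gain texture,
shot-to-shot beam intensity jitter, and the real (uncharacterized)
background shape. Tests passing on synthetic data therefore validate the
chain's logic and its statistical behaviour, not detector physics.

## Sorting, classification, merging

`shot_statistics()` computes, per frame (on the central-panel crop, as the
original processing did): total intensity; the coefficient of variation of
the radial profile about its running-median trend (layer-line structure);
the resultant length of the intensity-weighted angular distribution on the
doubled angle (anisotropy, invariant to which end of the line is "up");
and a high-q angular max/mean ratio that fingerprints jet-edge streaks in
a band where filament scattering is negligible. `reject_outliers()` first
vetoes outright any frame whose streak statistic is a gross outlier
(beyond 5 robust SDs of the batch) — jet-edge exposures are bright and
directional enough to survive any soft ranking, and even a handful of
survivors concentrate into one angle class and corrupt the merge — then
ranks the rest by robust z-scores (anisotropy + structure - 2 x residual
streak excess) and keeps the top 40%, the conservative cut of the original
chain. The exact composite used originally is not documented; this one is
calibrated on the generator's labelled shot classes, which is the role the
stage's published description assigns it.

`estimate_equatorial_angle()` scores 0.5 degree angular bins of unmasked
annulus intensity (0.05-0.30 nm^-1, excluding the beamstop and including
the 4 nm line), smooths circularly and refines the maximum with a
parabola; featureless frames return a flagged low-confidence angle rather
than an error. `classify_block()` then partitions consecutive blocks of
~1000 shots into five subgroups by k-means on the doubled-angle embedding
`(cos 2a, sin 2a)` — a standard way to cluster axial data, deterministic
given its seed. Class averages are stored as pixel sums plus per-pixel
member counts; normalization is deferred to the merge so that masked
pixels never dilute the sums. `contrast_score()` measures each class's
4 nm layer line (two highest maxima over the line mean, scale-invariant;
a flat line scores 2) and `select_align_merge()` keeps the top 69/186 by
that score, rotates each class about the beam center so its equator is
horizontal (bilinear interpolation; rotated member-count maps weight the
average, so pixels fed by masked regions are excluded rather than
averaged in) and normalizes.

## Peak fitting

`detect_peaks()` finds local maxima above `median + 5 x MAD` of a radial
noise model, enforces a 5 px separation and completes Friedel pairs.
`fit_peaks()` fits each candidate with a separable (axis-aligned) Gaussian
plus a local constant offset by Levenberg-Marquardt; pixels nearer a
competing candidate are excluded from the window, which handles arbitrary
chains of adjacent peaks without simultaneous multi-peak fits. Elongated
equatorial streaks are legitimate anisotropic fits, so only collapsed
(sub-pixel) widths, out-of-window centers and non-convergence are
rejected and logged. `render_fitted()` sums the Gaussians on a zero
background over the full grid: detector gaps, bad pixels and inter-peak
noise vanish by construction, giving the idealized pattern whose inversion
shows the sharpest detail.

## Iterative phase retrieval

`retrieve()` implements the error-reduction cycle with the experiment's
support: amplitudes are the square root of the input intensities
(documented conversion); initial phases come from the featureless-tube
projection modulated by the y-Gaussian; the unmeasured central region
(default: half the distance to the tube model's first equatorial peak) is
filled with tube amplitudes scaled so the tube's first equatorial peak
matches the measured one. Each cycle: inverse transform with measured
amplitudes and current phases (masked pixels float at the model field),
take the real part, multiply by the support — flat for `|x| <= 15.6` nm
falling as a half Gaussian of width 11.8 nm (FWHM convention by default;
the width convention is a config switch because the original description
does not define "width", and results are reported to be insensitive to
it), times a y-Gaussian of FWHM 159 nm — and every 10th cycle average the
object with its 180-degree rotation; forward transform yields the next
phases. After the last cycle the object is divided by the y-Gaussian
(clipped below 1e-3) to undo that part of the mask.

Numerical conventions: centered FFT layout with the origin on pixel
`(floor(n/2)+1, floor(n/2)+1)`; cyclic 180-degree rotation consistent with
DFT periodicity; error history is the relative amplitude misfit
`||F(object)| - A| / |A|` on measured pixels, evaluated on the
support-constrained object. Because the support is a multiplicative,
non-idempotent mask (the y-Gaussian shrinks the object envelope every
application), no object satisfies both constraints exactly and the misfit
plateaus at a finite floor (~0.27 for self-consistent tube input at the
default supports) instead of falling to zero; convergence shows as the
plateau, and reconstruction quality is validated in real space against
the generating model. The real-part constraint plus centro-symmetric
initial phases confine the phases to {0, pi}; sign flips are rare under
error reduction, so the initial model retains real influence on the
result. Two consequences are documented as limitations below.

`com_radius_scan()` reruns the retrieval from starting tubes of varying
center-of-mass radius at a fixed 4 nm wall, keeping a single central-fill
model, and reports each start's final peak-to-peak separation and the
Pearson correlation between the reconstruction's equatorial intensities
and the measured low-q equatorial band.

## Radial and helical analysis

`azimuthal_integrate()` bins unmasked intensity into equal-width
half-open momentum-transfer bins, with empty bins flagged. Profiles are
reported on the SAXS momentum-transfer scale `q = 4 pi sin(theta) /
lambda = 2 pi / d`: on this scale the first intensity lobe of a
cylindrical shell of radius R falls at `q = 3.83 / R` (the first extremum
of the zero-order Bessel form factor), which is the `J01 = 7.66 / (2R)`
relation used to convert the measured lobe position into a mean helical
radius — 0.297 nm^-1 maps to 12.9 nm. Diffraction images themselves stay
calibrated in spatial frequency `1/d` (the 4 nm layer line at 0.25 nm^-1);
only the pseudo-SAXS profile uses the SAXS convention, because the J01
arithmetic is only dimensionally consistent there.

`protofilament_estimate()` maps the mean helical radius to a protofilament
number by the linear calibration `N = round(13 R / R13)` with
`R13 = 11.94` nm, chosen so that 12.9 nm maps to 14 while the
11.5-12.3 nm band maps to 13. This is a calibration convention anchored at
the two published endpoints, not a derived relation.

`peak_to_peak()` measures the wall separation as the distance between the
two highest maxima of the y-averaged profile along x, refined by 3-point
parabolas. For an ideal annulus the projection rises to a one-sided cusp
at the inner radius, and any quadratic refinement sits a fraction of a
nanometre outside it — an irreducible ~0.2-0.3 nm outward bias for
analytic tubes that cancels when reconstruction and reference are measured
with the same estimator. `axial_repeat_peak()` locates the dominant axial
modulation after whitening the axial power spectrum by its running median;
whitening is necessary because reconstruction spectra are red (dominated by
the object envelope), and the 4 nm monomer repeat appears as the prominent
whitened peak at 0.25 nm^-1.

## Pipeline, formats, provenance

`run_pipeline()` chains the stages on any shot source — simulated
(`shot_source_simulated()`), on-disk (`read_shot_stack()`, a
directory-based stack with JSON metadata and per-shot records supporting
lazy selection and bounded-memory streaming), or an in-memory list — in
two passes (statistics, then class sums), and records one append-only
manifest entry per stage (counts in/out, seeds, parameters,
package version), serializable with `write_manifest()`. Both inversion
paths run from one merge: `fit_peaks_stage = FALSE` inverts the merged
pattern directly; `TRUE` inverts the rendered peak model.

## Problem sizes and test design

The validation suite builds everything it needs at run time: layer-line
checks use 512 x 512 patterns of a 20-turn lattice; retrieval oracles use
the 400 x 400 default geometry; sorting statistics are calibrated on a
labelled 100-shot mix; the end-to-end check generates 2000 shots
(~20 filaments each) at the default conditions and compares the
reconstruction against the mixture-weighted reference projection computed
directly from the generator's models. These sizes give stable statistics
while keeping the whole suite comfortably reproducible on a single CPU.

## Known limitations

* **Starting-model dependence of the retrieval.** With real-valued,
  centro-symmetric starts the phase problem reduces to a sign problem, and
  the error-reduction iteration flips signs only when Fourier components
  cross zero. On this package's synthetic data the basin of convergence
  around the true center-of-mass radius is roughly +/- 1 nm: starting
  tubes much fatter or thinner than the object reconstruct with a wall
  separation biased toward the start. The original study reports a much
  wider basin (starts of 10-15 nm COM radius converging to
  19.9 +/- 0.8 nm) on its experimental pattern; that breadth is not
  reproduced by this implementation on synthetic data, and the scan
  results should be read with that caveat. Hybrid input-output or
  shrink-wrap schemes, which escape such stagnation, are out of scope.
* **Misfit floor.** The per-cycle amplitude misfit cannot reach zero (see
  above); it is a convergence monitor, not a goodness-of-fit statistic.
* **Analysis conventions.** The J01-to-protofilament mapping is a
  two-point calibration; the pseudo-SAXS J01 of a mixed-population merged
  pattern reflects the wall annulus shape as much as the mean radius, so
  protofilament estimates from synthetic mixtures carry ~1-unit
  uncertainty.
* **Generator realism.** See the generator section; in particular the
  background is a structural stand-in and absolute photon calibration is
  outside scope.
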