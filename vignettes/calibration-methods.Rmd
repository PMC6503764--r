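---
title: "Calibration methods in edcal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibration methods in edcal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edcal)
```

`edcal` determines the experimental parameters a rotation-method
integration program needs from a TEM used as an electron diffractometer:
detector distance and distortion, rotation-axis azimuth, oscillation
width, plus the dose budget. This vignette explains each model, its
assumptions, the numerical choices behind the implementation, and what
the built-in synthetic data do and do not demonstrate.

## Physics layer

The electron wavelength is the relativistically corrected de Broglie
wavelength,
$$\lambda = \frac{h}{\sqrt{2 m_0 e V \left(1 + \frac{eV}{2 m_0 c^2}\right)}},$$
evaluated with CODATA-2018 constants (0.02508 Å at 200 kV). Powder-ring
geometry uses the exact relation $r = D \tan 2\theta$ with
$\theta = \arcsin(\lambda / 2d)$ rather than the small-angle shortcut
$r \approx D\lambda/d$; at $\lambda \approx 0.025$ Å the two differ by
less than 0.01 %, but exactness costs nothing and keeps
`ring_radius()`/`distance_from_radius()` exact mutual inverses. Because
$D$ enters linearly, the ratio of the distances inferred from the two
semi-axes of a distorted ring equals the axis ratio $A/B$ identically.

The calibrant model covers face-centred cubic standards only (the usual
aluminium powder; gold would work the same way via `fcc_standard()`).
Reflections obey the all-even-or-all-odd parity rule; symmetry-distinct
families are keyed by sorted $|h|,|k|,|l|$ and families whose $d$ agree
within $10^{-6}$ Å (e.g. 333/511) are merged into one ring, since they
are indistinguishable on a powder pattern. $d$ values are kept at full
precision and rounded only for display.

## Ring calibration

**Peak-to-ring assignment.** Peaks are assigned to the ring whose
predicted radius is nearest, gated by a relative radial tolerance
(default 0.05). Adjacent aluminium rings sit as little as 4 % apart in
radius, so a rough distance guess would systematically shift every
assignment; `assign_peaks_to_rings()` therefore first refines the guess
by a global radial scale search over $[0.5, 2]$ (561 log-spaced scales,
scored by the number of peaks inside the tolerance and, as tie-break, the
mean radial deviation). With the refinement the distance guess only needs
to be right within a factor of two. The search can be disabled
(`refine_scale = FALSE`) when the guess is trusted, and fully manual
per-ring peak files remain possible by constructing the assignment tibble
directly.

**Ellipse fitting.** Each ring is fitted by the direct algebraic
least-squares conic fit with the ellipse-enforcing normalisation
$4AC - B^2 = 1$, solved in the numerically stable block form after
centring and scaling the coordinates (the normalisation class is
invariant under that conditioning, so the solution is the constrained
optimum in the original frame too). The conic is converted to centre,
semi-axes and orientation; for a circle ($A = B$ within $10^{-10}$
relative) the orientation is reported as 0 by convention. Degenerate
inputs — fewer than five distinct points, collinear points, a hyperbolic
best conic — raise classed errors rather than returning garbage. The
reported RMS residual is the Sampson distance (algebraic residual over
its gradient norm), a first-order approximation of the orthogonal
point-to-ellipse distance, which has no closed form.

Each ring is fitted independently; a joint fit with a shared centre would
be a reasonable variant but would hide per-ring centre drift, which is
itself diagnostic.

**Distortion is reported, not corrected.** The ellipticity
$e = A/B - 1$ (typically 2–3 % on a TEM) is small enough that structure
solution succeeds uncorrected, and integration programs have their own
per-pixel distortion machinery. Per-peak radial correction is out of
scope. Which semi-axis corresponds to the true camera length cannot be
decided from the powder standard alone; the calibration report carries
both distances, their across-ring means and standard deviations, and a
flag when the spread exceeds 1 % of the mean (usually a mis-assigned
ring). The A-versus-B ambiguity must be resolved against a sample with
known unit-cell parameters.

## Rotation-axis azimuth

Summing frames over at least one oscillation period of a wobbled powder
standard produces rings with an azimuthal intensity modulation:
reflections on or near the rotation axis stay in diffracting condition
and pile up, while a reflection-free segment on the axis stays empty —
the minimum is the easier feature to detect. `azimuthal_profile()` bins
the annulus around a predicted ring radius (default half-width ±5 px)
into ≥36 azimuthal bins, measuring azimuth from the +fast axis towards
the +slow axis; empty bins are marked invalid, never zero.

`find_axis()` proceeds in three steps:

1. circular moving-average smoothing (odd window, default 5 bins);
2. localisation and validation: the two lowest local minima must be
   antipodal within 10°, and the profile contrast
   $(\max - \min)/(\max + \min)$ must exceed 0.05 — a flat profile means
   the pattern was not oscillated, and the estimator refuses rather than
   guesses;
3. refinement: the final azimuth is the phase of the profile's second
   circular harmonic, $\psi = \tfrac12\,\mathrm{atan2}(-\sum I\sin 2\theta,
   -\sum I \cos 2\theta)$.

The harmonic step matters numerically. Azimuthal binning on a square
pixel grid produces a spurious intensity ripple with 90° periodicity
(the pixel count per polar bin fluctuates), and the $\cos^2$ modulation
is flat near its minimum, so a bare argmin can be pulled several degrees
off even without noise. The second harmonic is exact for a
$\cos^2$-family modulation and orthogonal both to a flat background and
to any 4θ-periodic artefact, so it recovers the azimuth to a fraction of
a degree while the argmin machinery still provides the sanity checks. If
the two disagree by more than 15° the estimator warns that the profile is
not $\cos^2$-like.

The azimuth is reported mod 180° with both directed candidates
$(\cos\psi, \sin\psi, 0)$ and its negation: the twofold direction
ambiguity is deliberately left to the downstream indexing statistics,
which resolve it cleanly. The template writer emits one candidate and
comments out the other.

## Rotation rate and oscillation width

The goniometer angle log records, per readout, the wall-clock times just
before and just after the angle call plus the angle itself. The fit uses
the bracket midpoint as abscissa with x-uncertainty
$\tfrac12(t_\mathrm{after} - t_\mathrm{before})$, propagated into weights
through the slope in a deterministic two-pass scheme: ordinary least
squares gives a slope estimate, x-variances become y-variances via that
slope, and the line is refit with inverse-variance weights. With equal
x-errors the scheme reduces exactly to ordinary least squares. The
oscillation width is $\Delta\varphi = \text{rate}/\nu$; a negative rate
(reverse rotation) yields a negative width, and the template writer folds
the sign into the emitted axis candidate while keeping the oscillation
range positive.

Readout loops on some stages report each angle twice on consecutive
records. Such duplicates are kept by default — they carry real timing
information — and `dedup = TRUE` collapses each pair to its midpoint
record for comparison; on an exact line both routes recover the slope to
$10^{-9}$. Integration programs assume a constant width, so nonuniform
rotation (an unbalanced holder makes the stage run fast downhill and slow
uphill) is not modelled; instead the fit reports the residual RMS and a
piecewise-slope diagnostic so nonuniformity is visible.

The two-screenshot fallback for stages without digital readout is plain
arithmetic, $\Delta\varphi = \frac{\alpha_2 - \alpha_1}{t_2 - t_1} /\nu$,
and the package follows that arithmetic exactly rather than any rounded
display value.

## Dose and magnification

STEM dose per image is $I \cdot t_\mathrm{dwell} / e$ electrons per scan
pixel divided by the pixel's sample-plane area — independent of image
size but quadratic in magnification, which is why the magnification
reference pair matters. That pair (e.g. 1500× ↔ 194 nm per pixel) is
instrument-specific and must be supplied via configuration, never
hard-coded. The spot-size rule halves the current per increment, which
extrapolates a measurable screen current down to spot sizes the meter
cannot read. Imaging fluence per frame is defined strictly as the ratio
flux/ν: at 0.01 e⁻Å⁻²s⁻¹ and 100 Hz that is 10⁻⁴ e⁻Å⁻² per frame (a
quoted per-frame dose of 10⁻³ at those settings corresponds to a 0.1 s
accumulation, not a single 100 Hz frame).

## Synthetic data: what it emulates, and what it does not

`synthetic_scene()` fixes the reference conditions: 200 kV beam,
1030 × 1065 px detector at 75 µm and 100 Hz saturating at 16 bits,
effective distance 500 mm, direct beam near the detector centre at
(508, 530), distortion $e = 0.023$, axis azimuth 37°, modulation depth
0.5, flat background 10 counts/px, ring amplitude 100 counts/px, Poisson
noise. The azimuthal modulation is modelled as
$1 - m\cos^2(\theta - \psi_0)$ — a modelling choice: only the existence
and position of the extrema are physically mandated, and both the form
and the depth are parameters so alternative profiles can be tested.
Rings are drawn as Gaussian annuli (radial σ = 2 px) following the
distorted ellipse radius; the direct beam is a bright blob clipped
exactly at the saturation count. Generators are bit-reproducible for a
fixed seed.

This is a geometric and statistical emulation, not a physical one: no
structure factors, no dynamical scattering, no mosaicity, no frame-to-
frame crystal motion, no detector point-spread. Passing tests therefore
demonstrate that the estimators recover the geometry they were designed
to recover under realistic counting statistics — not that every real
pattern is as well-behaved. On real data the dominant unmodelled effects
are non-cos² modulation shapes (handled by the argmin/harmonic
consistency warning), background gradients, and nonuniform rotation
(surfaced by the rate diagnostics).

Test problem sizes were chosen to keep the default suite quick while
leaving no estimator untested at full scale: unit-level property loops
run on a 400 × 420 px detector at 250 mm, while the acceptance-style
checks use the full 1030 × 1065 px geometry (100 noisy axis replicates,
50 rate logs, 200-point ellipse fits).

## Conventions and degenerate inputs

* Pixel coordinates are 0-based array indices internally; the SPOT.XDS
  peak dialect and the template writer convert to the 1-based
  pixel-centre convention at the I/O boundary, and only there.
* The detector distance is emitted positive with the beam along
  (0, 0, 1). Setups that use the negative-distance dialect should negate
  the value in their configuration; the package does not guess.
* Frame containers are TIFF series (16-bit, exact for integer counts up
  to 65535) or ASCII grids. Writers are deterministic: identical inputs
  give byte-identical files, with the provenance timestamp isolated on a
  comment line.
* Everything validates early with classed errors: non-positive voltages,
  empty peak lists, annuli outside the image, non-monotone time brackets,
  all-equal angles (zero-rate warning with rate 0 ± 0), mixed-direction
  logs, templates with missing fields.

## Known limitations

* fcc calibrants only; no general space-group machinery.
* No spot finding on images beyond the azimuthal machinery — peak lists
  come from the upstream spot finder.
* No per-pixel distortion maps and no distortion correction.
* No refinement of the axis against indexed single-crystal data; the
  azimuth here is the starting value an integration program refines.
* Reflecting range and beam divergence are sample- and optics-specific
  and are left to the integration program.
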