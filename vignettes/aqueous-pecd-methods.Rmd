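---
title: "Methods: extracting the dichroic parameter b1 from liquid-jet photoemission"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: extracting the dichroic parameter b1 from liquid-jet photoemission}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquapecd)
```

## The measurement model

Photoelectron circular dichroism (PECD) is a forward–backward asymmetry in
the angular distribution of photoelectrons emitted when chiral molecules are
ionized by circularly polarized light. Within the electric-dipole
approximation, the normalized photoelectron angular distribution for a
randomly oriented sample is

$$I^p(\theta) = 1 + b_1^p P_1(\cos\theta) + b_2^p P_2(\cos\theta),$$

where $\theta$ is measured from the photon-propagation direction, $p = \pm 1$
labels the circular polarization ($p = 0$ linear), and $P_n$ are Legendre
polynomials. The chiral information sits entirely in $b_1$: it vanishes for
achiral targets and flips sign on exchange of enantiomer or handedness
($b_1^{+1} = -b_1^{-1}$), while $b_2^{\pm 1} = -\beta/2$ carries the familiar
anisotropy parameter. The asymmetry factor of a polarization pair,

$$G = \frac{I^+ - I^-}{\tfrac12 (I^+ + I^-)}
    = \frac{2\, b_1 P_1(\cos\theta)}{1 + b_2 P_2(\cos\theta)},$$

becomes $2 b_1 \cos\theta$ at the magic angle
$\theta_m = \arccos(1/\sqrt3) = 54.74^\circ$, where $P_2$ vanishes; the sign
is negative for backward-hemisphere detection. All angles in this package
are stored absolutely — the experimental "50 degrees, backward" geometry is
$\theta = 130^\circ$ — so every sign falls out of $\cos\theta$ with no
hemisphere flags in the algebra.

A real analyzer at $\theta = 130^\circ$ with a $\pm 15^\circ$ acceptance is
only *near* the magic angle. `b2_correction_factor()` computes the residual
$b_2$ influence as $1 + b_2 \langle P_2(\cos\theta)\rangle$ with a uniform
average over the acceptance window; under the conservative upper-limit
assumption $\beta = 0.5$ this evaluates to 0.97, applied multiplicatively to
the naive magic-angle inversion (`b1_from_G()`). Uniform-in-$\theta$
weighting is the default because nothing is known about the transmission
profile of the analyzer across its acceptance; a solid-angle weighting is
available behind a flag and changes the factor by well under a percent.

## Speciation

Alanine changes charge state with pH (pKa 2.3 for the carboxylic acid, 9.9
for the amine). `species_fractions()` implements two-step
Henderson–Hasselbalch speciation with activities approximated by
concentrations; ionic-strength corrections are deliberately omitted since
only thermodynamic pKa values are available. At the three working pH values
the dominant forms are the cation (95.2% at pH 1), the zwitterion (99.97%
at pH 6), and the anion (99.92% at pH 13), which justifies treating each
dataset as a single species.

## What the synthetic-data generator emulates

`generate_pair()` forward-simulates one polarization pair per condition with
known ground truth, reproducing every statistical feature the extraction
chain has to cope with:

* **Three EMG peaks** at the tabulated binding energies of the carboxyl
  (C1), chiral-center (C2), and methyl (C3) carbons, converted to kinetic
  energy by $KE = h\nu - BE$, with the measured per-charge-state area
  ratios (e.g. 1 : 1.09 : 1.13 for the cation). The lineshape is a Gaussian
  ($\sigma$ = 0.45 eV) convolved with a one-sided exponential whose tail
  points toward lower kinetic energy; the dimensionless asymmetry
  $\tau/\sigma$ = 0.25 sits mid-range of the 0.2–0.3 fitting convention.
  The width is wider than a high-photon-energy measurement would give
  because quasi-elastic scattering broadens low-KE liquid-phase features.
* **A scattered-electron background** — exponential in KE (decay constant
  2.5 eV) plus a constant — that dominates the peaks at low kinetic energy
  (background-to-peak-height ratio ≥ 3 at KE = 10 eV). The background is
  achiral: identical for both polarizations up to the flux factor.
* **Polarization-dependent peak intensities**: each site's area is
  modulated by $I^p(\theta)$ evaluated with the *effective* in-liquid
  $b_1 = b_1^{\mathrm{true}} / a$, where $a = 4$ is the scattering
  attenuation divisor (mid-range of the 3–5 estimate), and
  $b_2 = -\beta/2$ with $\beta = 0.5$. The default pre-scattering
  $b_1(C1) = 0.08$ therefore yields an effective 0.02, the magnitude the
  liquid-jet measurement reports; C2 and C3 carry no dichroism, matching
  the non-detection for those sites.
* **A 2% flux imbalance** between the + and − acquisitions (the persistent
  1–3% difference in light intensity), applied multiplicatively to the −
  spectrum.
* **Poisson counting noise** from a mandatory seed. The counts scale
  (C1 area $2\times10^6$ counts·eV per spectrum) was chosen so that the
  per-channel percent-difference noise is about 1% and a single pair
  determines $b_1$ to roughly $\pm 0.003$ — the statistical regime visible
  in the reference measurements, which average about ten acquisitions per
  spectrum over 30–60 minutes of synchrotron time.

The generator does **not** emulate: gas-phase satellite contributions,
energy-dependent transmission, streaming-potential drifts beyond a
constant (injectable) KE offset, lineshape physics of quasi-elastic
broadening beyond EMG width inflation, or any kinetic-energy dependence of
$b_1$ itself. Passing tests on this synthetic data therefore demonstrates
that the *reduction chain* is unbiased and correctly calibrated under the
stated noise model — not that real spectra obey the model.

## The extraction chain and its numerical choices

**Baseline scaling.** `scale_to_baseline()` rescales the − spectrum by a
single factor so both spectra agree on the outer 15% edge windows, where
only the achiral background is present. Windows that overlap declared peak
regions raise an error rather than being silently moved. The factor's
shot-noise uncertainty multiplies the whole − spectrum coherently, so it is
recorded and propagated into the asymmetry uncertainty downstream.

**Background handling.** `subtract_background()` fits the
exponential-plus-constant family to the edge windows only and interpolates
beneath the peaks (linear and spline alternatives are selectable). This
edge-anchored estimate is excellent for display and percent-difference
curves, but its interpolation error under the peaks is absorbed by the
fitted areas at the fraction-of-a-percent level — comparable to the
asymmetry being measured. The pipeline therefore refines the background
parameters *jointly* with the peaks (`fit_peaks(background = "exp_const")`),
using the edge fit as the starting point; the background uncertainty then
appears in the area covariance where it belongs. Skipping background
removal altogether demonstrably dilutes the asymmetry: the achiral
background cancels in the numerator of $G$ but not in the denominator,
biasing $|b_1|$ low — a property the test suite checks on twenty seeds.

**Peak fitting.** Up to three EMG profiles, the asymmetry parameter bounded
to [0.2, 0.3], centers confined to ±0.3 eV around their initial values
(from the binding-energy table or from local maxima), widths bounded to
[0.15, 1.2] eV. The optimizer is box-constrained Levenberg–Marquardt
(minpack.lm) on shot-noise-weighted residuals, ftol/ptol $10^{-8}$, up to
three restarts; a fit that stalls at the iteration limit with stable
deviance (a parameter pinned at a bound can cycle) is accepted with a
warning. Parameter covariances are rebuilt from a central-difference
Jacobian at the optimum, inverted with diagonal pre-scaling and eigenvalue
flooring so that degenerate directions (the strongly overlapping anionic
C2/C3 pair, flagged with a warning) get conservative rather than spuriously
small variances. `fit_peaks_joint()` additionally ties peak widths across
the three charge-state spectra through shared width multipliers bounded so
the max/min ratio cannot exceed 1.05.

**From areas to b1.** $G$ is formed from the fitted C1 areas — not from
pointwise intensities — so that peak overlap is handled by the constrained
fit; `b1_from_G()` inverts it at $\theta = 130^\circ$ and applies the 0.97
acceptance correction. One estimate is produced per (pair, site, photon
energy).

**Uncertainties.** The default per-pair $\sigma(b_1)$ propagates the fitted
area variances (including background and scale-factor contributions)
through the $G \to b_1$ map. A second convention, the standard deviation of
the percent-difference curve within ±1 FWHM of the peak, is retained as an
option and always reported as a diagnostic: it is the spread conventionally
drawn as error bars on such plots, but it measures *per-channel* noise and
so overstates the uncertainty of an area-integrated estimate by roughly the
square root of the number of channels. With the default convention, seeded
simulation campaigns show ~0.4% bias on $b_1 = 0.02$ and empirical 1σ
coverage of 61–62%, consistent with nominal.

**Binning.** Estimates are averaged in 250 meV kinetic-energy windows on a
grid anchored at 0 eV with half-open intervals
$[c - 0.125, c + 0.125)$, combined by inverse variance
(`1/\sqrt{\sum \sigma_i^{-2}}` as the combined error); an unweighted
combiner is selectable. Binding energies are nominal ($h\nu - KE$ on the
as-measured axis); no absolute energy referencing is attempted, and none of
the analysis depends on it.

**Validation.** `enantiomer_consistency()` tests, per matched (site, pH,
bin) cell, that $b_1(D) + b_1(L) = 0$ and $b_1(DL) = 0$ within two combined
sigmas, and supports blind operation where enantiomer labels are withheld
until after the $b_1$ computation. `attenuation_correct()` maps measured
values onto the implied pre-scattering interval $[3 b_1, 5 b_1]$.

## Problem sizes used by the tests and the acceptance script

The shipped checks run campaigns of 5 photon energies × 6 replicate pairs
(30 pairs) for the anionic recovery, 50 seeded 3-pair campaigns for the
coverage study, and 20 seeds for the background-bias property; these sizes
give standard errors a factor of several below the tolerances being
checked while completing in minutes on a single core.

## Known limitations

* The background family is phenomenological; real spectra may need the
  spline alternative or a physics-based model, and the joint refinement
  assumes the family is correct over the full window.
* The EMG asymmetry convention is $\tau/\sigma$; other conventions exist
  and fitted asymmetries are only comparable within one convention. The
  convention is recorded in the outputs.
* For the anionic form the C2/C3 areas are strongly degenerate; their
  individual $b_1$ estimates are reported with correspondingly large
  uncertainties and should not be over-interpreted, mirroring the
  experimental situation.
* The uncertainty model assumes independent Poisson channels; correlated
  systematic drifts (beyond the constant flux imbalance) are not modeled.
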