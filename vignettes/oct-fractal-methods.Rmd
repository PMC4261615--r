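---
title: "Methods: fractal dimension and morphometry of intraretinal layers"
author: "octfractal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fractal dimension and morphometry of intraretinal layers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octfractal)
```

## The measurement model

An OCT B-scan is a matrix of backscatter intensities, rows running from the
vitreous downward in depth, columns running laterally (one column per
A-scan). Given per-A-scan positions of the eight boundaries delimiting the
seven intraretinal layers (RNFL, GCL+IPL, INL, OPL, ONL+IS, OS, RPE), three
eye-level features are measured per layer:

* **Fractal dimension (FD).** The depth reflectivity profile inside one
  layer at one A-scan is treated as a 1-D fractal signal whose power
  spectrum decays as a power law, $P(\omega) \propto \omega^{-\beta}$.
  The spectral exponent $\beta$ is estimated as minus the slope of an
  ordinary least-squares line through $(\log \omega, \log P(\omega))$, and
  the fractal dimension follows from the standard 1-D relation
  $$\mathrm{FD} = \frac{5 - \beta}{2},$$
  so $\beta \in (1, 3)$ maps to $\mathrm{FD} \in (1, 2)$: rougher,
  more disordered profiles have flatter spectra (smaller $\beta$) and
  larger FD. Per-layer values are the mean over A-scans of one scan, and
  eye-level values the unweighted mean over that eye's scans. FD is
  invariant to rescaling the intensities, so no normalization is needed
  before the fit.
* **Thickness.** Mean boundary-to-boundary distance times the axial pitch.
  Boundary positions are continuous (sub-pixel) depth coordinates, so
  thickness is a geometric quantity: the seven layer thicknesses add
  exactly to the total retinal thickness under the shared-boundary
  convention.
* **Normalized reflectivity.** Mean layer intensity divided by mean RPE
  intensity over the same (non-shadowed) A-scans. The ratio is
  dimensionless and cancels global gain; it also cancels any column-wise
  uniform attenuation, which is why vessel shadows are primarily a problem
  for the FD and raw-intensity measurements rather than for this ratio.

Blood vessels cast dark vertical shadows through the retina. Shadowed
A-scans keep valid boundaries (thickness is unaffected) but corrupt
reflectivity-based measurements, so they are detected from a *shadowgram*
— the lateral profile of mean outer-retina intensity — and excluded from
the FD and reflectivity computations.

Groups (healthy vs mild diabetic retinopathy, MDR) are compared per layer
and feature with one-way ANOVA followed by Newman–Keuls post-hoc tests at
a fixed significance threshold of $p < 0.001$, and discrimination is
quantified with empirical ROC curves: AUROC with Hanley–McNeil standard
error and asymptotic 95% CI, a cutoff (mean-minus-2SD or Youden), and the
positive likelihood ratio $\mathrm{PLR} =
\mathrm{sensitivity}/(1 - \mathrm{specificity})$ at that cutoff.

## The spectral fit: numerical choices

**Spectrum.** The periodogram $|{\rm FFT}|^2/n$ of the profile, keeping
positive-frequency bins strictly below the Nyquist bin ($\omega = k/n$
cycles/pixel, $k = 1, \dots, \lceil n/2\rceil - 1$). The DC bin is always
excluded, which removes the profile mean from the fit.

**Detrending is off by default.** This was an open design point and was
settled by simulation. On layer-length profiles (tens of pixels) removing
a fitted straight line strips genuine low-frequency fractal power: with a
planted $\beta = 1.84$ (FD 1.58) on 39-pixel profiles, the detrended fit
recovers a mean FD of about 1.68 (bias $+0.10$), while the raw periodogram
recovers 1.577. Adding a strong linear intensity ramp (±0.3 on a
fluctuation of SD 0.3) to the raw fit biases FD by only about $+0.04$ —
less than half the harm detrending causes. `detrend = TRUE` remains
available for profiles with severe ramps.

**Taper and band limits.** A Hann taper and a fitted frequency band are
exposed for long-profile work. The raw periodogram of a *nonstationary*
fractal signal is leakage-limited: the implicit boxcar window has sidelobes
decaying as $\omega^{-2}$, so spectra steeper than $\beta = 2$ cannot be
measured without a taper (a true fractional Brownian path with $H = 0.8$,
$\beta = 2.6$, fits to FD $\approx 1.5$ instead of 1.2 at any band). With
the Hann taper and a low-frequency band (`band = c(0, 0.125)`), the
estimator recovers FD within 0.02 of $2 - H$ for $H \in \{0.2, 0.4, 0.6,
0.8\}$ at $n \ge 1024$ against an exact Davies–Harte fBm oracle. At
layer lengths the taper costs far more than it buys (its wide main lobe
smears the few available bins), so both options default to off.

**Short and degenerate profiles.** Profiles shorter than `min_profile`
(default 8 pixels) are excluded, never zero-padded — padding flattens the
spectral slope. Fits need at least `min_points = 4` strictly positive
power bins; zero-power bins are dropped. At a coarse axial pitch the OS
and RPE layers (≈8 and 6 pixels at 2 µm) are therefore excluded wholesale,
and the per-layer summaries record how many A-scans were excluded and why
(`shadow`, `too_short`, `invalid`); used plus excluded always equals the
A-scan count.

**No clamping.** Estimates with FD outside $[1, 2] \pm 0.5$ are flagged
invalid and excluded from means rather than clamped; clamping would bias
group means toward the interior of the range.

## The synthetic phantom

The phantom plants known truth in exactly the direction the estimator
measures. Within each layer, each A-scan's depth profile is
$r_\ell (1 + f)$, where $r_\ell$ is the layer's mean reflectivity and $f$
is a zero-mean fluctuation synthesized spectrally: independent
complex-Gaussian Fourier coefficients with variance $\propto k^{-\beta}$,
Hermitian-symmetrized and inverted, scaled to a relative SD of
`texture_sd` (default 0.3). The expected periodogram is the planted power
law by construction; the averaged periodogram over realizations regresses
to slope $-\beta$ within ±0.1, which is tested directly.

Geometry defaults emulate a Stratus-class time-domain macular scan:
512 A-scans over 6 mm, 1024 depth pixels at ≈2 µm axial pitch (the axial
sampling of the original instrument is not documented; 2 µm is this
package's convention, stated as such), per-layer thickness/reflectivity/FD
defaults from the literature reference table shipped in
`reference_moments()`, and a Gaussian foveal pit (FWHM 1 mm, 100 µm deep)
thinning the inner four layers proportionally, capped so boundary order is
preserved. Between-eye variation in `make_cohort()` jitters per-eye FD
(and optionally thickness and reflectivity) with normal deviates;
draws producing impossible parameters are rejected and counted.

**Speckle defaults to off** (`speckle_looks = Inf`; finite values give
unit-mean gamma multiplicative noise with that shape). The reasoning is a
noise-floor argument, worked out before any test was written: white
multiplicative noise adds a flat periodogram floor of height
$\approx \sigma_e^2$ per bin ($\sigma_e^2 = 1/\mathrm{looks}$), while the
planted power-law tail at the Nyquist bin of a 39-pixel profile with
texture SD 0.3 is $\approx 0.005$. Keeping the floor below the tail
requires several hundred looks — no realistic speckle level survives the
comparison. Clinically, the FD stage of this kind of pipeline consumes
*despeckled* images (vendor denoising is an upstream step and out of
scope here), so the phantom default emulates the despeckled input and
finite speckle is opt-in for exercising the preprocessing stages. Vessel
shadows are rendered by multiplying whole columns below the inner retinal
surface by `shadow_attenuation` (default 0.35).

All randomness flows from one integer seed through a deterministic
sub-seed derivation, so a spec plus seed reproduces every image
bit-identically.

**What the phantom does not emulate:** real speckle statistics (fully
developed speckle, spatial correlation), depth-dependent signal
attenuation, fan-beam geometry, motion artifacts, retinal curvature
beyond the pit, pathology such as edema, and 2-D texture correlation
across A-scans (texture is planted per-column in the measured direction
only). Passing tests therefore demonstrate the *method's* correctness on
signals with known spectral truth, not clinical performance on real
scans.

## Shadow detection

The shadowgram is the per-column mean intensity over the outer-retina band
(OPL/ONL+IS boundary down to OS/RPE), where shadows are most pronounced;
the depth band, the derivative operator and the threshold are not fixed by
prior art, so they are package conventions exposed as parameters. Columns
below `median − k_sigma × robust SD` (MAD-based, `k_sigma = 2`) are
candidates; maximal candidate runs — whose edges coincide with the
derivative sign changes of the steep shadow walls to within a column —
are merged across single-column gaps (shadows are contiguous) and kept if
their width lies in `[min_width, max_width]` (defaults 3–40 columns).
Because both threshold terms scale with the image, detection is invariant
to any positive global rescale. The robust SD is floored at `rel_floor`
(1%) of the profile median: on a noise-free phantom the shadowgram's only
lateral variation is pixel-discretization steps, and without the floor the
MAD collapses to quantization scale and sub-percent steps get flagged.
A ≥65% planted attenuation clears the floored threshold by an order of
magnitude. Masked columns are excluded from FD and reflectivity but not
from thickness.

The despeckler is a plain 2-D median filter with replicated edges
(window 1 is the identity); it is a generic speckle reducer for phantom
and external images, not a reproduction of any vendor denoising chain.

## Group statistics

ANOVA is the classical equal-variance F test; "significant" in the
comparison table means $p < 0.001$, implemented literally as a fixed
threshold. Newman–Keuls uses the studentized-range distribution
(`ptukey`/`qtukey`): means are ordered, each pair's
$q = |\bar x_i - \bar x_j| / \sqrt{MS_w / n_h}$ (harmonic-mean $n_h$ for
unequal groups, flagged) is compared to the critical value at the pair's
span, and pairs nested inside a non-significant span are blocked without
testing. With two groups the procedure reduces exactly to the pooled
t-test ($q = t\sqrt{2}$).

The ROC orientation is declared per study (`direction = "low"`: low
values call disease) and never auto-flipped, so features that move the
"wrong" way report AUROCs below 0.5 — that is information, not an error.
AUROC is computed in the rank (Mann–Whitney) form with weight ½ at ties;
its standard error uses the Hanley–McNeil formula with
$Q_1 = A/(2-A)$, $Q_2 = 2A^2/(1+A)$, and the 95% CI is $A \pm 1.96\,SE$.
The `mean_minus_2sd` cutoff places the threshold two healthy SDs from the
healthy mean on the disease side; with the reference GCL+IPL FD moments
(healthy $1.68 \pm 0.01$) this lands at $1.66$ with "FD ≤ cutoff calls
disease". `youden` maximizes sensitivity + specificity − 1 with ties
broken toward higher specificity. A perfect specificity flags the PLR as
infinite rather than reporting a number.

## Validation scale

The shipped validation uses desk-scale problem sizes chosen to exercise
every stage: estimator calibration on 200 profiles of $n = 1024$ per
$\beta \in \{1.4, 1.8, 2.2\}$ (observed |bias| < 0.01, SD ≈ 0.03 in FD);
binormal-consistency cohorts of 74 + 43 eyes over 100 seeds (empirical
AUROC within 0.005 of the closed form
$\Phi(\Delta\mu/\sqrt{\sigma_1^2+\sigma_2^2}) \approx 0.975$);
shadow recovery on 100 full-size phantoms (recall 1.0, FPR 0 at
defaults); Newman–Keuls null level over 1000 three-group simulations; and
an end-to-end study of 8 + 8 phantom eyes, two 256-A-scan scans each,
with separation planted only in GCL+IPL FD, which the comparison table
must rank first by AUROC. `scripts/acceptance.R` recomputes all of these
from scratch.

## Known limitations

* The FD estimator is consistent for the planted spectral model; on real
  OCT data residual speckle adds a white floor that biases $\beta$
  downward (FD upward), which is why shadow exclusion and upstream
  despeckling matter and why the fitted band is exposed for sensitivity
  analysis.
* Thin layers at coarse axial pitch (OS, RPE at 2 µm) cannot support a
  spectral fit and are reported as excluded rather than guessed.
* "Macular region" averaging is whole-scan; ring-wise partitions are not
  implemented.
* The Newman–Keuls procedure controls the complete-null error rate at
  $\alpha$ but is not a simultaneous confidence procedure; it is provided
  because it is the field's convention for this analysis.
* Phantom realism is deliberately limited (see above); clinical claims
  require real cohorts.
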