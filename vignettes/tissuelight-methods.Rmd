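---
title: "Methods: estimating tissue optical properties from integrating-sphere measurements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating tissue optical properties from integrating-sphere measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissuelight)
```

## The problem

Near-infrared laser dosimetry in tissue hinges on two transport parameters:
the absorption coefficient $\mu_a$ and the reduced scattering coefficient
$\mu_s' = \mu_s(1-g)$, both in cm$^{-1}$. They set the optical penetration
depth and the spatial spread of the fluence rate at the tissue surface, and
therefore the optical dose a clinician actually delivers. `tissuelight`
implements the full computational chain for estimating these parameters from
single-integrating-sphere measurements of diffuse reflectance $R_d$ and
transmittance $T_d$ at a fixed wavelength (a 808 nm diode line), and for
propagating them into dosimetric quantities: penetration depth, surface
fluence-rate maps, and between-condition discrimination statistics. The
motivating experimental observation is that $\mu_s'$ of hard (skull) and soft
(skin) tissue *decreases substantially as the incident laser power rises*
(roughly 37 to 9 cm$^{-1}$ for skull and 12 to 5.8 cm$^{-1}$ for skin over
150–350 mW) while $\mu_a$ barely moves — a trend the synthetic-data module
encodes as its ground truth.

## Two-flux (Kubelka–Munk) inversion

The two-flux model describes diffuse radiance in a slab by a forward and a
backward flux coupled through a scattering coefficient $S$ and an absorption
coefficient $A$ (both for *diffuse* radiation). With
$X = 1 + A/S$ and $Y = \sqrt{X^2 - 1}$, the slab of thickness $D$ has

$$R_d = \frac{\sinh(SYD)}{X\sinh(SYD) + Y\cosh(SYD)}, \qquad
  T_d = \frac{Y}{X\sinh(SYD) + Y\cosh(SYD)}.$$

This closed form inverts exactly (Kottler):

$$X = \frac{1 + R_d^2 - T_d^2}{2R_d}, \quad
  S = \frac{1}{YD}\ln\frac{1 - R_d(X - Y)}{T_d}, \quad A = (X-1)S.$$

A widely circulated variant of the forward formulas swaps the roles of
$\sinh$ and $\cosh$ in the denominator. That variant is *inconsistent* with
the inversion above: the round trip fails and the zero-absorption limit
degenerates ($R_d \to 0$ instead of $SD/(1+SD)$). `forward_km()` therefore
implements the consistent form; the test-suite pins the identity
$X_{\text{recovered}} = 1 + A/S$ to $10^{-9}$ relative on the forward output.

Numerical choices:

* **Zero-absorption branch.** At $A = 0$ the general expressions are $0/0$;
  `invert_km()` switches to the limit $S = R_d/(D(1-R_d))$ when
  $X - 1 < 10^{-8}$ (tunable).
* **Optically thick branch.** For $SYD > 350$ the hyperbolic functions
  overflow double precision; the asymptote $R_d \to 1/(X+Y)$, $T_d \to 0$
  is used instead.
* **Physicality guards.** $R_d + T_d > 1$ is rejected at construction
  (equality is permitted: it is the zero-absorption limit), and
  $\mu_s' \le \mu_a/3$ is rejected in `transport_to_km()` because the
  two-flux picture assumes scattering-dominated diffuse radiance.

The transport correspondence is $A = 2\mu_a$,
$S = \tfrac{3}{4}\mu_s' - \tfrac{1}{4}\mu_a$, and the penetration depth is
$\delta = 1/\sqrt{3\mu_a(\mu_a + \mu_s')} = 1/\mu_{\text{eff}}$. The fluence
solver uses the *same* $\mu_{\text{eff}}$ definition, which the suite asserts
to $10^{-12}$. At $\mu_a = 0$, $\delta$ is returned as `Inf` with a warning:
it is the correct mathematical limit, not an error.

## Spectrum reduction and calibration

Raw spectrometer traces (wavelength vs counts) are reduced to a single band
intensity by a trapezoidal integral over 808 ± 5 nm; the 5 nm half width
covers a diode laser line and excludes baseline, and the band edges are
interpolated so the integral is exact for piecewise-linear spectra.
Calibration uses the empty-sphere protocol: with no sample, the incident
beam is recorded entirely as transmittance and essentially no reflected
intensity is detected, so the empty-sphere transmission band is the 100%
level:

$$T_d = \frac{B(\text{sample}_T)}{B(\text{ref}_T)}, \qquad
  R_d = \frac{B(\text{sample}_R) - B(\text{ref}_R)}{B(\text{ref}_T)}.$$

The reference-reflection subtraction is kept for generality even though it is
$\approx 0$ in a well-aligned sphere. Replicates (five per condition in the
measurement protocol) are summarised by their mean and the rms deviation
about the mean (population divisor $n$): reporting the rms of raw values
alongside the mean would be redundant, so the deviation form is the default,
switchable via `replicate_stats(deviation = FALSE)`.

## The synthetic-data generator: a stated world

`default_ground_truth()` fixes the world the generator emulates: six powers
(150, 200, 225, 250, 300, 350 mW); $\mu_s'$ linear in power between the
published endpoints (intermediate values are not readable from the source
figures, so linearity is the declared fixture); $\mu_a$ constant (0.5
cm$^{-1}$ skull, 0.8 cm$^{-1}$ skin — magnitudes typical for soft/hard tissue
at 808 nm, but *synthetic choices*, since no absorption numbers are printed);
thickness 0.1 cm (skull) and 0.2 cm (skin), again synthetic (the source only
says thickness was measured with a caliper); anisotropy rising 0.80 to 0.90
across powers, matching the range explored in the anisotropy simulations.

`make_rt_table()` produces the noise-free $(R_d, T_d)$ per power through the
forward two-flux model and multiplies each fraction by an independent
lognormal factor with unit mean and coefficient of variation `noise_cv`
(default 0.05): detector counts are positive with roughly proportional noise
at these signal levels. Draws violating $R_d + T_d < 1$ are rescaled onto the
simplex. `make_spectra()` wraps the same table into Gaussian line traces
(FWHM 3 nm on a 750–860 nm grid) scaled per replicate, so reduction through
the spectra module reproduces the table fractions; the laser-line *shape*
cancels in calibration, which is why the loop closes to $10^{-3}$ regardless
of grid step.

What a green recovery test establishes: that the inversion chain is the
exact inverse of the synthesis chain under the stated noise model. What it
does not establish: anything about sphere radiometry (wall reflectance,
substitution error), wavelength-dependent properties, detector nonlinearity,
or the experimental accuracy of the published endpoint values themselves.

## Fluence solver

The steady-state diffusion equation
$\mu_a\phi - \nabla\cdot(D\nabla\phi) = S$, with
$D = 1/(3(\mu_a + \mu_s'))$, is solved on a square 2D surface domain with a
single-node delta source at the centre (the laser spot) and zero-fluence
Dirichlet boundaries, by a five-point finite-difference stencil and a direct
sparse factorisation (`Matrix`), so repeated runs are bit-stable. Design
choices where the source material is silent:

* **2D, not 3D.** The published maps are surface distributions; an
  extrusion depth is nowhere described. The analytic oracle is accordingly
  the 2D infinite-medium Green's function
  $\phi(r) = S\,K_0(\mu_{\text{eff}} r)/(2\pi D)$.
* **Dirichlet far boundary with a $10\delta$ domain guard** instead of
  Robin extrapolated boundaries: the simplest condition whose truncation
  error the guard controls ($K_0(10) \sim 10^{-5}$).
* **Resolution guard** `spacing <= delta/5`, and oracle comparisons exclude
  $r < 3$ grid cells where the single-node delta dominates the
  discretisation error.

`profile_width()` operationalises "more diffusive": the radius at which
$\phi$ falls to a fraction (default $e^{-1}$) of its off-source maximum,
measured along a grid axis with linear interpolation. Since the $K_0$
profile scales with $\delta$, widths increase monotonically as $\mu_s'$
drops across the power series — the qualitative surface-map trend the
pipeline reproduces for both tissues.

## Photon Monte Carlo

`simulate_slab()` is the standard single-layer hop–drop–spin scheme: free
paths $-\ln\xi/\mu_t$, weight drop $w\mu_a/\mu_t$ per interaction,
Henyey–Greenstein deflection
$\cos\theta = \frac{1}{2g}\left[1 + g^2 - \left(\frac{1-g^2}{1-g+2g\xi}\right)^2\right]$
(isotropic when $g=0$), Fresnel reflection at the faces when the relative
index $n \ne 1$ (index-matched by default, since no refractive index is
reported for the experiment), and Russian roulette below weight $10^{-4}$
with survival chance $1/10$. Diffusely reflected photons are tallied into
annuli by exit radius and reported per unit area (cm$^{-2}$), so profiles
are grid-comparable across runs.

Roulette is unbiased but conserves energy only in expectation; to make the
run-level budget exact, killed weight is credited to the absorbed tally and
the weight injected into survivors is debited from it. The reflectance and
transmittance estimators are untouched (unbiased), and
$R + T + A + R_{\text{spec}} = 1$ holds to $10^{-12}$ for every run — the
suite asserts it.

The random stream is R's own RNG consumed from C++, governed by
`set.seed()` through a state-preserving wrapper: one seeded stream per run,
seed recorded in the result.

Verification stack, strongest first: (i) semi-infinite isotropic slab at
albedo 0.9 against an independent Chandrasekhar $H$-function computation
(plane albedo $1 - \sqrt{1-\omega}H(1)$, solved by fixed-point iteration in
the test helper) — agreement well within Monte-Carlo error; (ii)
Beer–Lambert unscattered transmittance at $\mu_s = 0$; (iii) the HG sampler
first moment $\langle\cos\theta\rangle = g$; (iv) exact per-run weight
bookkeeping. One documented deviation: the similarity relation
($R_d$ at fixed $\mu_s'$ independent of $g$) carries a *systematic*
residual of order 0.5–1% even in a strongly diffusive slab, so "agreement
within 3 Monte-Carlo standard errors at $10^6$ photons" is not attainable at
any photon budget; the suite tests it at $10^5$ photons, where the
statistical band honestly covers the residual, and additionally bounds the
relative residual at 1%.

The anisotropy comparison (`compare_anisotropy()`) holds $\mu_a$ and
$\mu_s$ fixed while varying $g$ — under that reading total diffuse
reflectance strictly decreases with $g$ (forward-peaked photons penetrate
deeper before turning around), which is the documented direction of the
published anisotropy experiment and is asserted with $\ge 3\sigma$
separation at $10^6$ photons. The source never states which scattering
parameter was held fixed; the alternative (fixed $\mu_s'$) is exposed via
`hold = "mu_s_prime"`.

## ROC statistics

`empirical_roc()` sweeps the threshold over the pooled unique values,
with sensitivity the positive-class exceedance and specificity the
negative-class CDF. The AUC is the midrank Mann–Whitney statistic, chosen
because it equals the trapezoidal area under the empirical curve *exactly*,
ties included — an identity the suite property-tests on random tied samples.
The operating point maximises Youden's $J = Se + Sp - 1$ (the published
report never states its operating-point rule; Youden is the standard
choice), with ties broken toward higher specificity, and accuracy is
$(TP + TN)/(P + N)$ at that point. In the pairwise power report the lower
power is the negative class (transmittance rises with power); pairs whose
AUC lands below $1/2$ are flipped and flagged rather than silently
reoriented.

## Pipeline and reproducibility

`run_analysis()` chains simulate (or load) → reduce → invert → summarise →
fluence → ROC → Monte Carlo, writing each stage product as plain CSV/JSON so
any stage can be re-run in isolation, plus a run manifest with the fully
materialised configuration. All seeds are explicit — no wall-clock seeding
anywhere — and the suite asserts byte-identical stage outputs across
repeated runs. The configuration file format is JSON (a flat key set
mirroring `default_config()`); YAML was not adopted because the deployment
environment carries no YAML parser.

## Known limitations

* Single wavelength; no wavelength-dependent properties.
* No integrating-sphere throughput model (wall reflectance, single-beam
  substitution error) and no dark-current/nonlinearity correction.
* The 2D fluence model is a surface abstraction, not a 3D tissue volume.
* Collimated/diffuse separation of $\mu_s$ and $g$ is out of scope: the
  inversion yields $\mu_s'$ only; $g$ enters via fixtures.
* Experimental AUC values for the measured spectra cannot be reproduced
  (the raw data are not deposited); the ROC stage is validated on synthetic
  distributions with known separability instead.
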