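---
title: "The Poisson/Gaussian occupancy model behind scramblase assay analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Poisson/Gaussian occupancy model behind scramblase assay analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scramblr)
```

## The experiment in brief

The dithionite scramblase assay asks whether a membrane protein moves
phospholipids between bilayer leaflets. Proteoliposomes carry a trace of an
NBD-labelled reporter lipid, distributed symmetrically between leaflets.
Dithionite, which cannot cross the membrane, irreversibly bleaches only
outer-leaflet NBD: protein-free vesicles lose ~50% of their fluorescence,
while vesicles carrying at least one active scramblase lose (ideally) all
of it, because inner-leaflet lipids are flipped out faster than dithionite
consumes them. Titrating the protein-to-phospholipid ratio (PPR, grams of
protein per mole of phospholipid) therefore titrates the *fraction of
vesicles carrying at least one functional scramblase* — and the shape of
that curve encodes the molar mass of the functional unit, because heavier
units mean fewer units per gram of protein.

`scramblr` implements this analysis end to end: the closed-form occupancy
mathematics, simulators for every input the analysis consumes, trace
reduction, and the inverse problem (occupancy constant → functional mass).

## The occupancy model

Reconstitution places protein into vesicles at random. For a vesicle of
radius $r$, the expected number of functional units is proportional to its
lipid content ($8\pi r^2/A$ lipids for two leaflets at equal radius, with
$A$ the area per lipid) and to the corrected protein-to-phospholipid ratio
$PPR^*$:

$$\lambda(r) = \frac{PPR^*\, (8\pi r^2/A)}{M} = \frac{\alpha}{2} PPR^* r^2,
\qquad \alpha = \frac{16\pi}{A\,M},$$

where $M$ is the molar mass of the functional unit. Counts are Poisson, so
a vesicle of radius $r$ is occupied with probability
$1 - e^{-\lambda(r)}$ (`prob_occupied_fixed_radius()`).

Vesicle radii are not uniform: dynamic light scattering shows a Gaussian
distribution (defaults $\bar r = 100.8$ nm, $\sigma = 32.8$ nm). Averaging
the fixed-radius law over $r \sim N(\bar r, \sigma)$ gives the closed form
implemented in `prob_occupied_gaussian()`:

$$P(\ge 1) = 1 - \frac{1}{\sqrt{1 + \sigma^2 \alpha PPR^*}}
\exp\left(-\frac{\bar r^2\, PPR^*\, \alpha/2}{1 + \sigma^2 \alpha PPR^*}\right).$$

The exponent is negative; the positive-exponent variant sometimes seen in
print exceeds 1 for any $PPR^* > 0$ and cannot be a probability. The test
suite verifies the closed form against direct numerical quadrature of the
Poisson non-occupancy over the Gaussian density to better than $10^{-6}$
across 100 random parameter sets.

**Truncation.** The closed form integrates the untruncated Gaussian,
including the (unphysical) $r \le 0$ tail; the simulators resample
non-positive radii instead. At $\sigma/\bar r = 0.33$ the truncated mass is
~0.1% and the resulting discrepancy is below $10^{-4}$; at
$\sigma/\bar r = 0.4$ it can reach a few $10^{-3}$. The defaults sit well
inside the safe regime, and this is an approximation contract of the model,
not a fitting knob.

### Two endpoint non-idealities

Measured endpoints deviate from the ideal 50%/100%:

* protein-free vesicles reduce to $F_0$ = 43.0% rather than 50%, and
* saturating protein gives $F_{max}$ = 76.2% rather than 100%, because a
  fraction of vesicles is refractory to protein insertion (early detergent
  depletion is one hypothesis; the model is agnostic).

The measured reduction $F$ at a given PPR is converted to an occupancy
probability by the affine transform $P = (F - F_0)/(F_{max} - F_0)$
(`compute_P()`; noisy values outside $[0,1]$ are clipped and flagged, and
clipped points are retained in fits because dropping them biases the
plateau). The refractory pool also rescales the abscissa: protein is shared
over only the reconstitutable fraction $f = 0.524$ of vesicles, so the
model is evaluated at $PPR^* = PPR/f$ (`apply_ppr_correction()`).

These three constants are mutually phenomenological: no within-vesicle
mechanism can simultaneously produce $F_0 = 43$, $F_{max} = 76.2$ *and*
$f = 0.524$ (the occupied-vesicle endpoint would have to exceed 100%). The
trace simulator therefore calibrates per vesicle — an unoccupied vesicle's
reducible pool is $F_0$% of its signal, an occupied one's $F_{max}$% — which
reproduces both observed endpoints in the pure populations used for
calibration and keeps the protected inner-leaflet pool of unoccupied
vesicles strictly conserved, the assay's topological premise.

### From fit constant to functional mass

`fit_occupancy_model()` fits $\alpha$ — the only free parameter — by
Levenberg–Marquardt nonlinear least squares (unweighted by default, since
no error model for individual titration points is assumed; per-point
weights are accepted). $\bar r$ and $\sigma$ are held fixed at their
DLS-measured values rather than co-estimated, matching the experimental
workflow (size distribution is measured before reconstitution) and keeping
the fit identifiable. Initialisation inverts the fixed-radius law at the
smallest informative titration point; $\alpha$ is bounded to
$(10^{-8}, 1)$. The standard error comes from the Jacobian-based
covariance; a point-resampling bootstrap is available as a cross-check and
agrees within a factor of two on well-conditioned data.

The functional mass follows as $M = 16\pi/(A\hat\alpha)$ with
$\sigma_M/M = \sigma_\alpha/\hat\alpha$ — the delta method, which is exact
for an inverse map. With $\hat\alpha = 8.96\times10^{-4}$ mol g$^{-1}$
nm$^{-2}$ and $A = 0.70$ nm$^2$ this gives $M \approx 80{,}100$ g/mol — a
trimer of a ~27 kDa monomer, reproducing the reference value 80,800 ±
3,010 g/mol within 1%.

Two conventions deserve a note. First, $\alpha$ is stored in
mol g$^{-1}$ nm$^{-2}$, the only unit assignment under which
$\sigma^2 \alpha PPR^*$ is dimensionless. Second, the area per lipid is
not part of the assay readout; 0.70 nm$^2$ (typical for POPC/POPG) is the
package default and reproduces both the ~3.5×10$^5$ lipids per 100 nm
vesicle and the ~80.8 kg/mol mass; back-solving the reference mass exactly
would give $A \approx 0.694$ nm$^2$. It is exposed as a parameter
everywhere it enters.

Geometry uses two documented conventions: the α↔M conversion uses the
equal-leaflet count $8\pi r^2/A$ (consistent with the occupancy
derivation), while `lipids_per_vesicle()` additionally supports an
inner-leaflet radius offset (default 4 nm, the bilayer thickness) for the
lipid-count use case, giving $4\pi(r^2 + (r-d)^2)/A$.

## Kinetics: reduction half-life and the scrambling-rate bound

Fluorescence after dithionite addition follows a single exponential with a
floor, $F(t) = F_\infty + \Delta F e^{-k_{red}(t - t_{add})}$ — the minimal
model consistent with the observed traces, fitted by `fit_decay()`
(Levenberg–Marquardt; plateau and rate initialised from the tail mean and
a log-linear regression). The observed half-life (~15.2 s) is
indistinguishable between protein-free and scramblase-containing vesicles,
which means scrambling is *not* rate-limiting. That observation converts
into a lower bound: an occupied vesicle's entire pool (~3.5×10$^5$ lipids)
turns over at least as fast as the reduction,

$$\text{rate} > \frac{\ln 2}{t_{1/2}} N_{lipids} \approx 1.6\times10^4
\ \text{lipids s}^{-1},$$

implemented in `scrambling_rate_lower_bound()` under the first-order
($\ln 2/t_{1/2}$) convention.

`percent_reduction()` uses window means — baseline defaulting to the 30 s
before the addition, plateau to 300–400 s after (the windows are not
dictated by the chemistry and are exposed as arguments) — and flags a
still-sloping plateau instead of silently reporting it.

## Proton pumping and pH conversion

The pyranine assay verifies that the reconstituted pump is functional:
under illumination, protons accumulate in the vesicle lumen and pyranine
fluorescence, linear in pH over the assay range, falls. The simulator
(`simulate_pyranine_trace()`) relaxes pH exponentially toward an asymptote
at rate $k_{pump}$ during light-on intervals and holds it during light-off
(passive leak neglected over the 20 min assay). The three presets pin the
analytic trajectory to the reference endpoints at 20 min of illumination
(pH$_{20}$): no protein 7.57 (no pumping), pump-containing 6.90
(asymptote 6.90, $k = 0.005$ s$^{-1}$), and with valinomycin 6.45
(asymptote 6.45, $k = 0.012$ s$^{-1}$ — dissipating the membrane potential
permits faster, deeper acidification; the ionophore's effect is encoded
parametrically, not mechanistically). Only the endpoints are anchored by
measurement; the rates are the package's choice of plausible kinetics.
`trace_to_pH()` inverts the linear calibration and reports pH at the
nearest sample to the report time (default 1200 s; traces are densely
sampled, so no interpolation).

## Spectral purity

For a retinal chromoprotein, $A_{560}$ counts folded, pigment-bound
protein and $A_{280}$ all protein. `estimate_purity()` reports
$(A_{560}/A_{280})/\rho_{pure}$ capped at 1. The reference convention
$\rho_{pure} = 0.5$ reproduces the customary 98% figure for a 0.6/1.22
spectrum; note this is *not* derivable from the extinction-coefficient
ratio 54,000/66,000 = 0.818, which would be the alternative convention —
the discrepancy is a documented convention choice, with the reference
ratio exposed as an argument. Concentration uses Beer–Lambert at 560 nm
with a 1 cm path.

## What the simulators emulate — and what they do not

The generators (`sample_radii()`, `assign_scramblases()`,
`simulate_dithionite_trace()`, `generate_ppr_series()`, `simulate_dls()`,
`simulate_pyranine_trace()`) reproduce the statistical structure the
analysis assumes: Gaussian radii (resampled positive), Bernoulli
refractory flags, Poisson occupancy with radius-dependent mean,
single-exponential reduction of per-vesicle reducible pools weighted by
lipid content, additive Gaussian measurement noise (default 0.5% of the
initial signal on traces, 0.02 on the probability scale for titration
points — engineering choices, as no noise model accompanies the reference
measurements), and optional linear baseline drift (default 0; the
light/dark control found no photochemical artefact). Every generator takes
an explicit seed and leaves the global RNG state untouched.

They deliberately do not model dithionite diffusion or consumption,
detergent-removal kinetics, multi-species occupancy (e.g. monomer/trimer
mixtures), proton electrochemistry, or instrument-specific artefacts.
Passing tests on these synthetics therefore demonstrate the *estimators'*
correctness and calibration under the model's assumptions — not that real
traces obey a clean single exponential or that real size distributions are
exactly Gaussian. Real-data quirks (scattering tails in DLS, slow
post-plateau drift, bleaching) must be judged against the flags the
analysis functions raise (`converged`, `clipped`, `out_of_range`).

## Numerical choices and problem sizes

* Nonlinear fits use `minpack.lm::nlsLM`; non-convergence raises an error
  carrying the initialisation, never a silent fallback.
* The occupancy fit refuses degenerate inputs: fewer than 3 distinct
  $PPR^*$ values, all-zero $P$, or no point with $P > 0.2$ (with only the
  toe of the curve, $\alpha$ trades off against noise).
* `fit_gaussian_radii()` uses the sample mean/SD (exact standard errors
  $\sigma/\sqrt{n}$, $\sigma/\sqrt{2n}$) for raw samples and weighted
  least squares (weights $1/\max(c_i, 1)$) for histograms; an all-equal
  sample is flagged degenerate rather than fitted.
* Simulation studies in the test suite use 10$^4$–10$^5$ vesicles for
  population checks, 10$^4$ radii for DLS recovery, and 50–100 seeded
  replicates for fit-calibration checks — sizes at which binomial/CLT
  error bars are a few per mil, so the 3-standard-error acceptance bands
  are meaningful.

## Known limitations

* The refractory fraction $f$ is taken as a fixed, externally supplied
  constant (default 0.524), not estimated from the data.
* $F_0$ and $F_{max}$ are inputs to the probability transform, not
  co-fitted; their measurement uncertainty is not propagated into
  $\sigma_\alpha$.
* The rate bound is a bound, not an estimate: it assumes scrambling at
  least as fast as reduction and says nothing about how much faster.
* The closed form's untruncated-Gaussian convention degrades for
  $\sigma/\bar r > 0.4$ (see above); fits in that regime should use the
  quadrature oracle instead.
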