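---
title: "Models and methods behind quenchbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind quenchbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quenchbind)
```

quenchbind implements the complete quantitative chain of a steady-state
fluorescence binding study: a protein whose intrinsic fluorophore
(tryptophan, in serum albumin Trp-214) is titrated with a small-molecule
ligand, and the progressive loss of emission intensity is converted into a
quenching mechanism, binding thermodynamics, conformational-change
indicators, and an intramolecular distance.  This vignette records the
models, the tunable constants, and the design decisions a user or
maintainer needs to interpret the outputs.

## The quenching model

With quencher concentration $[Q]$ and intensities $F_0$ (no quencher) and
$F$, the Stern–Volmer relation

$$\frac{F_0}{F} = 1 + K_q \tau_0 [Q] = 1 + K_{SV}[Q]$$

is fitted by ordinary least squares of $F_0/F$ on $[Q]$
(`stern_volmer_fit()`).  $\tau_0$ is the unquenched fluorescence lifetime
(default $10^{-8}$ s, the literature value for serum albumin), so the
bimolecular quenching rate constant is $K_q = K_{SV}/\tau_0$.

Two fit variants exist because real titrations rarely pass exactly through
an intercept of 1: the default leaves the intercept free and reports it; a
constrained fit (`fix_intercept = TRUE`) forces the model's own intercept.
$R^2$ is computed about the mean of $F_0/F$ in both variants so they are
comparable; a zero-variance response (no quenching, perfectly reproduced)
is reported as $R^2 = 1$.

### Mechanism classification

Collisional (dynamic) quenching is diffusion-limited, so its rate constant
cannot exceed the diffusion-controlled ceiling (default
$7.4 \times 10^{9}$ L mol$^{-1}$ s$^{-1}$ at 298 K) and $K_{SV}$ rises
with temperature.  Ground-state complex formation (static quenching)
shows the opposite signature: $K_q$ far above the ceiling and $K_{SV}$
falling with temperature.  `classify_mechanism()` therefore labels a
multi-temperature series *static* when every $K_q$ exceeds the limit and
the OLS slope of $K_{SV}$ against $T$ is negative, *dynamic* when every
$K_q$ is at or below the limit and the slope is positive, and *ambiguous*
otherwise — reporting both evidence flags so the caller sees which leg
failed.

Two deliberate choices here.  First, the diffusion limit is a configurable
parameter, not a constant baked in: published values for the "maximum
diffusion-controlled rate constant" differ by an order of magnitude
between sources, and the verdict can hinge on which one is used.  Second,
the *label* uses the sign of the OLS slope (the overall direction), while
the `ksv_temperature_trend` field separately reports `"non-monotone"`
whenever the pointwise differences change sign.  Measured $K_{SV}$ series
are frequently non-monotone within their standard errors while still
trending downward overall; collapsing that to a single monotonicity test
would misclassify typical static-quenching data, but hiding the
non-monotonicity would overstate the evidence.  The field reports what was
computed.

## The binding isotherm

For $n$ equivalent sites forming a ground-state complex, the quenched
fraction follows

$$\log_{10}\frac{F_0 - F}{F} = \log_{10} K_b + n \log_{10} [Q],$$

fitted by OLS in log–log space (`double_log_fit()`), with
$K_b = 10^{\text{intercept}}$ and $n$ the slope.  Base-10 logarithms are
used throughout, the convention of double-log binding plots (the choice of
base cancels in $K_b$ since the intercept is exponentiated in the same
base).  Free ligand is approximated by total added ligand; no depletion
correction is applied.  Points with $F \ge F_0$ — expected from noise when
quenching is weak — make the left side undefined and are dropped with a
warning rather than an error, with the count reported.

The Gibbs free energy uses $\Delta G = -RT\ln K_b$ with
$R = 8.314$ J K$^{-1}$ mol$^{-1}$, in kJ/mol.

### What the intercept can and cannot deliver

The titration samples $[Q]$ over 5–50 µM, i.e. $\log_{10}[Q]$ from about
$-5.3$ to $-4.3$, while the intercept lives at $\log_{10}[Q] = 0$ — an
extrapolation of more than four decades.  Standard regression leverage
then multiplies the per-point scatter of the log-ratio by a factor of
$\sim$30 into the intercept.  At 1% multiplicative intensity noise the
lowest-concentration points (where only a few percent of the fluorescence
is quenched) carry log-ratio scatter of order 0.1–0.2, so the fitted
$\log_{10} K_b$ inherits a standard error of a few tenths: individual
noisy titrations routinely return $K_b$ off by tens of percent even when
$R^2 > 0.98$, while the slope $n$ is much better determined.  This is a
property of the estimator, not a bug: the package's Monte Carlo tests
measure it directly, and users should treat the reported
`K_b_stderr_log10` — not $R^2$ — as the honest uncertainty of $K_b$.
Averaging replicate titrations, or widening the concentration range,
is the experimental remedy.

### Site-marker displacement

`displacement_analysis()` compares apparent $K_b$ values fitted in the
presence of site-specific marker ligands (e.g. warfarin for albumin site
I, flufenamic acid for site II, digitoxin for site III) against a
marker-free baseline, reporting the percent change in $K_b$ and
$\Delta\Delta G$ per marker.  A marker is called displacing when $K_b$
drops by more than a threshold, default 10%: the literature calls small
changes "negligible" without stating a cutoff, so the cutoff here is
explicit and configurable rather than implicit.

## Conformational probes

**Synchronous scans.** `synchronous_scan()` reads the EEM along
$\lambda_{em} = \lambda_{ex} + \Delta\lambda$; offsets of 15 nm and 60 nm
isolate tyrosine and tryptophan microenvironments.  Because the excitation
coordinate stays on-grid, bilinear interpolation reduces to linear
interpolation along the emission axis; excitation points whose target
emission falls outside the grid are dropped, and fewer than three
admissible points is a range error.

**Peak picking.** Peaks are grid argmaxima with ties broken toward the
shorter wavelength.  No sub-grid refinement is attempted: band positions
in this assay are conventionally reported at integer nm on 1–10 nm
instrument grids, and fitting sub-nm peak positions would add precision
the data cannot support.  Percent intensity changes are reported rounded
(default 1 decimal, matching the tables of published studies) with the
unrounded value retained.

**EEM regions.** `eem_peak_table()` summarises rectangular regions;
defaults cover the Rayleigh-scatter peak
($\lambda_{ex} = \lambda_{em}$, region 350–370/350–370 nm), which tracks
overall protein surface area, and the intrinsic tryptophan peak
(270–290/320–360 nm).  The Rayleigh line is treated as an ordinary region,
not specially modelled.

**UV-Vis shifts.** `uvvis_shift()` reports the absorption maximum of the
free protein, of the complex (ligand absorbance subtracted), and of the
free ligand within a window (default 240–320 nm, the aromatic band), plus
the complex's shift against each — negative = blue, positive = red.  A
complex band distinct from both free species is the absorption-side
evidence of a ground-state complex.

## Förster energy transfer

The chain (`fret_analysis()`) is:

1. $\varepsilon(\lambda) = A(\lambda)/(c\,l)$ (Beer–Lambert,
   `molar_absorptivity()`);
2. $J = \sum F(\lambda)\varepsilon(\lambda)\lambda^4\Delta\lambda \,/\,
   \sum F(\lambda)\Delta\lambda$ over the donor-emission /
   acceptor-absorption overlap (`overlap_integral()`);
3. $R_0 = 0.211\,(\kappa^2 n^{-4} \Phi_D J)^{1/6}$ (`forster_radius()`);
4. $E = (F_0 - F)/F_0$ (`transfer_efficiency()`);
5. $r = R_0((1-E)/E)^{1/6}$ (`donor_acceptor_distance()`).

Defaults $\kappa^2 = 2/3$ (isotropic tumbling), $n = 1.336$ (PBS),
$\Phi_D = 0.15$ (tryptophan in albumin), all overridable.

**Units.** $J$ is computed in M$^{-1}$ cm$^{-1}$ nm$^4$: with that unit
the 0.211 prefactor yields $R_0$ in ångströms, which the package converts
to nm.  This is the only convention under which the widely quoted
reference values ($J \approx 9.4\times10^{12}$ with $R_0 \approx 1.7$ nm)
are mutually consistent; papers sometimes print $J$ with the unit
"cm³ L mol$^{-1}$", which is dimensionally inconsistent with those same
numbers, so the unit is documented here explicitly.

**Quadrature.** Both spectra are resampled by linear interpolation onto a
uniform grid (default 0.5 nm) over the overlap window — taken from the
input spectra (`range = "auto"`) rather than from any fixed constant,
since published emission maxima for the same protein vary between
sections of the same study — and the sums are rectangle-rule, mirroring
the discrete definition of $J$.  On smooth bands the 0.5 nm result agrees
with $10^{-3}$ nm brute-force quadrature to well under 0.1% (tested), so
the grid step is not a practically relevant tolerance.  An overlap
narrower than 3 nm is rejected as a range error.  The returned
`forster_result` satisfies $E = R_0^6/(R_0^6 + r^6)$ to machine precision
by construction, and $E \in \{0, 1\}$ is a domain error since $r$ is
there unbounded or zero.

## The synthetic generator

`generate_titration()` realizes the static-quenching model directly:
$F = F_0/(1 + K_b [Q]^n)$, then multiplicative Gaussian noise
$F \cdot (1 + \mathcal{N}(0, \sigma_{rel}))$ under a recorded seed
(photon-counting noise is approximately multiplicative at high counts).
Defaults mirror the study conditions this pipeline targets: 10 equally
spaced concentrations over 5–50 µM, $F_0 = 10^4$ counts,
$K_b = 38.301\times10^3$ L/mol, $n = 1.161$, emission band centred at
322 nm, 298 K.  Only the static model is generated — no collisional term —
matching the mechanism the pipeline is designed to diagnose.

Emission and absorbance spectra are sums of Gaussian bands (width =
standard deviation, nm); absorbance bands are specified on the
$\varepsilon$ scale and multiplied by $c\,l$, so `molar_absorptivity()`
recovers the band amplitudes exactly.  `generate_eem()` builds EEMs from
separable 2-D Gaussian peaks on the 10-nm instrument grids
(excitation 200–500, emission 200–600 nm) and returns a matched
free/bound pair, the bound one with per-peak intensity factors and
emission-centre shifts.

What the generator does *not* emulate: Raman and second-order scatter
bands, inner-filter attenuation at high absorbance, detector saturation,
baseline drift, and correlated (non-i.i.d.) noise.  Tests passing on
synthetic data therefore validate the estimators against the stated
model, not robustness to instrument artifacts; real data should be
background-corrected and inner-filter-corrected upstream.

## Numerical and interface choices

* **File dialect.** One CSV dialect for all five object types:
  `# key=value` metadata lines, one header row, numeric rows, values
  written with 17 significant digits so read∘write is the identity on
  doubles.  Validation rejects every invariant violation (non-monotone
  axes, dimension mismatches, malformed headers name the offending line)
  and never silently repairs.  Wavelength grids need not be uniform;
  consumers interpolate.
* **Intensities are doubles** even though instruments report integer
  counts: synthetic and normalised spectra need fractional values.
* **Suspect points.** Titration intensities above $1.05 F_0$ are flagged
  with a warning and kept — the 5% margin admits ordinary noise at zero
  quenching while still surfacing drift; exclusion (of $F \ge F_0$) is
  applied only where the double-log transform is undefined.
* **Problem sizes in tests.** The Monte Carlo recovery study uses 1000
  replicates of 10-point titrations with $K_b \in [10^3, 10^5]$
  (log-uniform), $n \in [0.8, 1.4]$, 1% noise; quadrature oracles use
  $10^{-3}$ nm grids over ~150 nm windows.  These sizes make the
  statistical assertions stable at fixed seeds while keeping the full
  suite run in seconds.
* **Known limitations.** No inner-filter correction; no combined
  static+dynamic (sphere-of-action) model; no van't Hoff
  $\Delta H/\Delta S$ decomposition (single-temperature $\Delta G$ only);
  no ligand-depletion correction; no $\kappa^2$ estimation from
  anisotropy.  Each is a deliberate scope boundary, not an oversight.
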