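# quenchbind

Quantitative analysis of steady-state fluorescence titrations of a protein
with a small-molecule ligand — the experiment behind most published
drug/serum-albumin binding studies.  A fluorophore-bearing protein (for
serum albumin, Trp-214) is titrated with increasing ligand, and the loss of
emission intensity is turned into binding constants, a quenching mechanism,
conformational-change indicators and a donor–acceptor distance.

The package is aimed at spectroscopists and pharmacokinetics researchers
who have titration tables and spectra (as delimited text) and want the full
published analysis chain, plus a synthetic-data generator with known ground
truth so every step can be validated without instrument data.

## What it computes

* **Stern–Volmer quenching** — OLS fit of `F0/F = 1 + K_SV·[Q]`, the
  quenching rate constant `K_q = K_SV/τ0`, and a static/dynamic mechanism
  verdict from the temperature trend of `K_SV` and the diffusion-limit test
  on `K_q` (`stern_volmer_fit()`, `classify_mechanism()`).
* **Binding isotherm** — the double-logarithmic fit
  `log₁₀((F0−F)/F) = log₁₀K_b + n·log₁₀[Q]`, giving the association
  constant `K_b`, stoichiometry `n` and `ΔG = −RT·lnK_b`
  (`double_log_fit()`, `gibbs_free_energy()`), and site-marker competitive
  displacement reports (`displacement_analysis()`).
* **Conformational probes** — synchronous-fluorescence scans at fixed
  Δλ (15 nm tyrosine / 60 nm tryptophan), excitation–emission-matrix peak
  tables, and UV-Vis absorption-maximum shifts (`synchronous_scan()`,
  `compare_scans()`, `eem_peak_table()`, `uvvis_shift()`).
* **FRET** — the overlap integral
  `J = Σ F(λ)ε(λ)λ⁴Δλ / Σ F(λ)Δλ`, the Förster radius
  `R0 = 0.211·(κ²n⁻⁴Φ_D·J)^{1/6}` (Å, returned in nm), the transfer
  efficiency `E = (F0−F)/F0` and the donor–acceptor distance
  `r = R0·((1−E)/E)^{1/6}` (`overlap_integral()`, `forster_radius()`,
  `fret_analysis()`).
* **Synthetic data** — titrations from the static-quenching model
  `F = F0/(1 + K_b·[Q]ⁿ)` with seeded multiplicative noise, Gaussian
  emission/absorbance bands, and matched free/bound EEMs
  (`ground_truth()`, `generate_titration()`, `generate_eem()`, ...).

## Worked example

A small synthetic titration (10 points, 5–50 µM quencher, 1% noise) ships
with the package:

```r
library(quenchbind)
path <- system.file("extdata", "titration_synthetic_298K.csv", package = "quenchbind")
tt <- read_spectrum(path, "titration")
stern_volmer_fit(tt)
#> Stern-Volmer fit (10 points, T = 298 K)
#>   K_SV = 7966 +/- 232 L/mol   intercept = 0.9775
#>   K_q  = 7.966e+11 L/mol/s (tau0 = 1e-08 s)   R^2 = 0.9933
double_log_fit(tt)
#> Double-log binding fit (10 points, T = 298 K)
#>   K_b = 2.592e+04 L/mol (log10 se 0.132)   n = 1.125 +/- 0.0283
#>   delta G = -25.18 kJ/mol   R^2 = 0.9950
```

`K_q ≈ 8×10¹¹ L mol⁻¹ s⁻¹` is two orders of magnitude above the
diffusion-controlled ceiling (~7.4×10⁹), the signature of static quenching
through a ground-state complex; `K_b ≈ 2.6×10⁴ L/mol` with `n ≈ 1.1` is a
moderate-affinity, roughly 1:1 association, and the negative `ΔG` says it
is spontaneous.  (The data are noisy: the generating truth was
`K_b = 38.3×10³`, `n = 1.161` — see the vignette for why the intercept of a
double-log plot is the least certain number in this analysis.)

The FRET chain on the literature constants for a tryptophan donor
(κ² = 2/3, n = 1.336, Φ_D = 0.15):

```r
r0 <- forster_radius(9.42e12)      # J in M^-1 cm^-1 nm^4
r  <- donor_acceptor_distance(0.06, r0)
cat(sprintf("R0 = %.2f nm, r = %.2f nm\n", r0, r))
#> R0 = 1.72 nm, r = 2.72 nm
```

A command-line front end (`inst/cli/quenchbind`) wraps the same functions:

```sh
Rscript inst/cli/quenchbind simulate --out-dir demo --seed 2
Rscript inst/cli/quenchbind report --titration demo/titration.csv \
    --emission demo/emission.csv --absorbance demo/absorbance.csv --out-dir demo/rep
```

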