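#' Orientation, refractive-index and quantum-yield parameters for FRET
#'
#' Bundles the three constants of the Forster-radius formula: the dipole
#' orientation factor `kappa^2` (2/3 for isotropic tumbling; range 0-4),
#' the refractive index of the medium, and the donor fluorescence
#' quantum yield.  Defaults are the literature values for a tryptophan
#' donor in phosphate-buffered saline: `kappa^2 = 2/3`, `n = 1.336`,
#' `Phi_D = 0.15`.
#'
#' @param kappa_squared Orientation factor, in `[0, 4]`.
#' @param refractive_index Medium refractive index, >= 1.
#' @param donor_quantum_yield Donor quantum yield, in `(0, 1]`.
#' @return An object of class `forster_parameters`.
#' @export
forster_parameters <- function(kappa_squared = 2 / 3, refractive_index = 1.336,
                               donor_quantum_yield = 0.15) {
  check_number(kappa_squared, "kappa_squared")
  if (kappa_squared < 0 || kappa_squared > 4) {
    stop_domain("`kappa_squared` must lie in [0, 4]")
  }
  check_number(refractive_index, "refractive_index")
  if (refractive_index < 1) stop_domain("`refractive_index` must be >= 1")
  check_number(donor_quantum_yield, "donor_quantum_yield", positive = TRUE)
  if (donor_quantum_yield > 1) stop_domain("`donor_quantum_yield` must be <= 1")
  structure(
    list(kappa_squared = kappa_squared, refractive_index = refractive_index,
         donor_quantum_yield = donor_quantum_yield),
    class = "forster_parameters"
  )
}

#' Molar absorption coefficient from an absorbance spectrum
#'
#' Beer-Lambert conversion `epsilon(lambda) = A(lambda) / (c * l)`,
#' evaluated pointwise on the spectrum's own wavelength grid.
#'
#' @param abs An [absorbance_spectrum()] with positive concentration and
#'   path length.
#' @return An object of class `molar_absorptivity`: `wavelength` (nm)
#'   and `epsilon` (M^-1 cm^-1).
#' @export
molar_absorptivity <- function(abs) {
  stopifnot(inherits(abs, "absorbance_spectrum"))
  check_number(abs$concentration, "concentration", positive = TRUE)
  check_number(abs$path_length, "path_length", positive = TRUE)
  structure(
    list(wavelength = abs$wavelength,
         epsilon = abs$absorbance / (abs$concentration * abs$path_length)),
    class = "molar_absorptivity"
  )
}

#' Donor-acceptor spectral overlap integral
#'
#' Discrete overlap integral
#' `J = sum(F(lambda) * epsilon(lambda) * lambda^4 * dlambda) / sum(F(lambda) * dlambda)`
#' over the region where the donor emission and the acceptor absorption
#' overlap.  Both spectra are resampled by linear interpolation onto a
#' uniform grid (default 0.5 nm) before the rectangle-rule sums, so
#' non-uniform input grids are handled correctly.  The normalisation by
#' the donor intensity makes `J` independent of any uniform scaling of
#' the emission spectrum.
#'
#' Units: with `epsilon` in M^-1 cm^-1 and wavelengths in nm, `J` is in
#' M^-1 cm^-1 nm^4 - the convention under which the 0.211 prefactor of
#' [forster_radius()] yields the Forster radius in angstroms.
#'
#' @param donor An [emission_spectrum()] of the donor.
#' @param epsilon A [molar_absorptivity()] object (or an
#'   [absorbance_spectrum()], converted internally).
#' @param range `"auto"` (the intersection of the two wavelength ranges)
#'   or an explicit length-2 nm interval.
#' @param step Resampling step in nm (default 0.5).
#' @return `J` in M^-1 cm^-1 nm^4, with the integration window attached
#'   as attribute `overlap_range` and the grid step as `step`.
#' @seealso [forster_radius()], [fret_analysis()]
#' @export
overlap_integral <- function(donor, epsilon, range = "auto", step = 0.5) {
  stopifnot(inherits(donor, "emission_spectrum"))
  if (inherits(epsilon, "absorbance_spectrum")) {
    epsilon <- molar_absorptivity(epsilon)
  }
  stopifnot(inherits(epsilon, "molar_absorptivity"))
  check_number(step, "step", positive = TRUE)
  lo <- max(min(donor$wavelength), min(epsilon$wavelength))
  hi <- min(max(donor$wavelength), max(epsilon$wavelength))
  if (is.numeric(range)) {
    if (length(range) != 2L || range[1] >= range[2]) {
      stop_validation("`range` must be an increasing length-2 nm interval")
    }
    lo <- max(lo, range[1])
    hi <- min(hi, range[2])
  }
  if (!is.finite(lo) || !is.finite(hi) || hi - lo < 3) {
    stop_range("donor emission and acceptor absorption must overlap over >= 3 nm")
  }
  grid <- seq(lo, hi, by = step)
  f <- stats::approx(donor$wavelength, donor$intensity, xout = grid)$y
  e <- stats::approx(epsilon$wavelength, epsilon$epsilon, xout = grid)$y
  denom <- sum(f * step)
  if (denom <= 0) stop_range("donor carries no intensity inside the overlap window")
  j <- sum(f * e * grid^4 * step) / denom
  structure(j, overlap_range = c(lo, hi), step = step)
}

#' Forster radius
#'
#' `R0 = 0.211 * (kappa^2 * n^-4 * Phi_D * J)^(1/6)`, the donor-acceptor
#' distance at which transfer efficiency is 50%.  With `J` in
#' M^-1 cm^-1 nm^4 the prefactor yields `R0` in angstroms; the value is
#' returned in nm.
#'
#' @param J Overlap integral in M^-1 cm^-1 nm^4 (> 0), e.g. from
#'   [overlap_integral()].
#' @param params A [forster_parameters()] object; `kappa_squared` must
#'   be > 0 (a zero orientation factor makes transfer impossible).
#' @return `R0` in nm.
#' @examples
#' forster_radius(9.42e12)  # 1.72 nm with the default parameters
#' @export
forster_radius <- function(J, params = forster_parameters()) {
  J <- as.numeric(J)
  check_number(J, "J", positive = TRUE)
  stopifnot(inherits(params, "forster_parameters"))
  if (params$kappa_squared <= 0) {
    stop_domain("`kappa_squared` must be > 0 for a finite Forster radius")
  }
  r0_angstrom <- 0.211 * (params$kappa_squared * params$refractive_index^-4 *
                            params$donor_quantum_yield * J)^(1 / 6)
  r0_angstrom / 10
}

#' Energy-transfer efficiency from donor quenching
#'
#' `E = (F0 - F) / F0`: the fraction of donor excitations transferred to
#' the acceptor, read from the donor intensity with (`F`) and without
#' (`F0`) acceptor at equal donor concentration.
#'
#' @param F0 Donor intensity without acceptor (> 0).
#' @param F Donor intensity with acceptor, in `[0, F0]`.
#' @return `E`, dimensionless in `[0, 1]`.
#' @export
transfer_efficiency <- function(F0, F) {
  check_number(F0, "F0", positive = TRUE)
  check_number(F, "F")
  if (F < 0 || F > F0) {
    stop_domain("`F` must lie in [0, F0]; F > F0 implies a negative efficiency")
  }
  (F0 - F) / F0
}

#' Donor-acceptor distance from transfer efficiency
#'
#' Inverts `E = R0^6 / (R0^6 + r^6)` to
#' `r = R0 * ((1 - E) / E)^(1/6)`.  Undefined at the boundaries: `E = 0`
#' puts the acceptor infinitely far away, `E = 1` at zero distance.
#'
#' @param E Transfer efficiency, strictly inside `(0, 1)`.
#' @param R0 Forster radius in nm (> 0).
#' @return Distance `r` in nm.
#' @examples
#' donor_acceptor_distance(0.06, 1.72)  # 2.72 nm
#' @export
donor_acceptor_distance <- function(E, R0) {
  check_number(E, "E")
  if (E <= 0 || E >= 1) {
    stop_domain("`E` must lie strictly inside (0, 1); r is unbounded at E = 0 and zero at E = 1")
  }
  check_number(R0, "R0", positive = TRUE)
  R0 * ((1 - E) / E)^(1 / 6)
}

#' Full Forster energy-transfer analysis
#'
#' Chains the FRET computation end to end: Beer-Lambert conversion of
#' the acceptor absorbance, overlap integral `J`, Forster radius `R0`,
#' transfer efficiency `E` from the donor intensities, and donor-acceptor
#' distance `r`.  The returned object satisfies
#' `E = R0^6 / (R0^6 + r^6)` to machine precision by construction.
#'
#' @param donor Donor [emission_spectrum()].
#' @param acceptor Acceptor [absorbance_spectrum()].
#' @param F0,F Donor intensities without / with acceptor (`0 < F < F0`
#'   for a finite distance).
#' @param params [forster_parameters()].
#' @param range,step Passed to [overlap_integral()].
#' @return An object of class `forster_result`: `J`, `R0`, `E`, `r`,
#'   `overlap_range`.
#' @export
fret_analysis <- function(donor, acceptor, F0, F,
                          params = forster_parameters(),
                          range = "auto", step = 0.5) {
  j <- overlap_integral(donor, acceptor, range = range, step = step)
  r0 <- forster_radius(j, params)
  e <- transfer_efficiency(F0, F)
  r <- donor_acceptor_distance(e, r0)
  structure(
    list(J = as.numeric(j), R0 = r0, E = e, r = r,
         overlap_range = attr(j, "overlap_range"), params = params),
    class = "forster_result"
  )
}

#' @export
print.forster_result <- function(x, ...) {
  cat("Forster energy-transfer analysis\n")
  cat(sprintf("  J  = %.4g M^-1 cm^-1 nm^4 (overlap %g-%g nm)\n",
              x$J, x$overlap_range[1], x$overlap_range[2]))
  cat(sprintf("  R0 = %.3g nm   E = %.3g   r = %.3g nm\n", x$R0, x$E, x$r))
  invisible(x)
}
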