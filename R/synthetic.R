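# Evaluate a sum of Gaussian bands.  `bands` is a list of numeric
# vectors c(center, width, amplitude); width is the standard deviation
# in nm and the amplitude is the peak height (not the area).
sum_of_gaussians <- function(x, bands) {
  if (is.numeric(bands)) bands <- list(bands)
  y <- numeric(length(x))
  for (b in bands) {
    b <- unname(b)
    if (length(b) != 3L || b[2] <= 0) {
      stop_validation("each band must be c(center, width > 0, amplitude)")
    }
    y <- y + b[3] * exp(-(x - b[1])^2 / (2 * b[2]^2))
  }
  y
}

# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Ground truth for synthetic titrations
#'
#' The parameters of the static-quenching model used by
#' [generate_titration()]: a 1:n ground-state complex with association
#' constant `K_b` quenches the fluorophore, so
#' `F = F0 / (1 + K_b * [Q]^n)`.  Multiplicative Gaussian noise emulates
#' photon-counting noise at high counts.  Defaults mirror a typical
#' ligand / serum-albumin titration: `K_b = 38.301e3` L/mol,
#' `n = 1.161`, emission band centred at 322 nm.
#'
#' @param K_b Association constant, L/mol (> 0).
#' @param n_sites Apparent binding stoichiometry (> 0).
#' @param F0 Unquenched intensity, counts (> 0).
#' @param emission_band `c(center, width, amplitude)` of the protein's
#'   emission band in nm/nm/counts (amplitude defaults to `F0`).
#' @param noise_sd_relative Relative standard deviation of the
#'   multiplicative intensity noise (>= 0).
#' @param temperature Temperature in K.
#' @param seed Integer RNG seed recorded with the truth; generation is
#'   deterministic for a fixed seed.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(K_b = 38.301e3, n_sites = 1.161, F0 = 1e4,
                         emission_band = c(center = 322, width = 25, amplitude = F0),
                         noise_sd_relative = 0, temperature = 298, seed = 1L) {
  check_number(K_b, "K_b", positive = TRUE)
  check_number(n_sites, "n_sites", positive = TRUE)
  check_number(F0, "F0", positive = TRUE)
  check_number(noise_sd_relative, "noise_sd_relative")
  if (noise_sd_relative < 0) stop_domain("`noise_sd_relative` must be >= 0")
  check_number(temperature, "temperature", positive = TRUE)
  if (length(emission_band) != 3L) {
    stop_validation("`emission_band` must be c(center, width, amplitude)")
  }
  structure(
    list(K_b = K_b, n_sites = n_sites, F0 = F0,
         emission_band = unname(emission_band),
         noise_sd_relative = noise_sd_relative,
         temperature = temperature, seed = as.integer(seed)),
    class = "ground_truth"
  )
}

#' Generate a quenching titration with known ground truth
#'
#' Evaluates the static-quenching model
#' `F = F0 / (1 + K_b * [Q]^n)` at the requested quencher
#' concentrations, then applies multiplicative Gaussian noise
#' `F * (1 + N(0, noise_sd_relative))` under the truth's seed.  At zero
#' noise, [double_log_fit()] recovers `K_b` and `n` exactly (closed
#' loop); generation is deterministic for a fixed seed.
#'
#' @param truth A [ground_truth()].
#' @param concentrations Quencher concentrations in mol/L, positive and
#'   strictly increasing.  Default: 10 equally spaced points over
#'   5-50 uM, the standard titration design for this assay.
#' @return A [quench_titration()] at the truth's temperature, with the
#'   reference wavelength set to the emission-band centre.
#' @export
generate_titration <- function(truth,
                               concentrations = seq(5e-6, 5e-5, length.out = 10)) {
  stopifnot(inherits(truth, "ground_truth"))
  if (any(concentrations <= 0)) {
    stop_validation("synthetic titration concentrations must be > 0")
  }
  f <- truth$F0 / (1 + truth$K_b * concentrations^truth$n_sites)
  if (truth$noise_sd_relative > 0) {
    f <- with_seed(truth$seed,
                   f * (1 + stats::rnorm(length(f), 0, truth$noise_sd_relative)))
    f <- pmax(f, .Machine$double.eps * truth$F0)
  }
  quench_titration(concentrations, f, F0 = truth$F0,
                   temperature = truth$temperature,
                   ref_wavelength = truth$emission_band[1],
                   label = sprintf("synthetic (seed %d)", truth$seed))
}

#' Generate a Gaussian-band emission spectrum
#'
#' Sum of Gaussian bands evaluated on a uniform wavelength grid - the
#' idealised shape of a protein emission band (no Raman band, scatter or
#' detector saturation).
#'
#' @param bands List of `c(center, width, amplitude)` vectors (width =
#'   standard deviation, nm).
#' @param from,to,step Wavelength grid in nm.
#' @param excitation Excitation wavelength metadata (nm).
#' @param temperature Optional temperature metadata (K).
#' @return An [emission_spectrum()].
#' @export
generate_emission_spectrum <- function(bands, from = 290, to = 500, step = 0.5,
                                       excitation = 280, temperature = NULL) {
  check_number(step, "step", positive = TRUE)
  grid <- seq(from, to, by = step)
  emission_spectrum(grid, sum_of_gaussians(grid, bands),
                    excitation = excitation, temperature = temperature,
                    label = "synthetic")
}

#' Generate a Gaussian-band absorbance spectrum
#'
#' Builds `A(lambda) = c * l * sum(epsilon-bands)`: the bands are given
#' on the molar-absorptivity scale (amplitude = peak `epsilon` in
#' M^-1 cm^-1) and scaled by concentration and path length, so
#' [molar_absorptivity()] recovers the band amplitudes exactly.
#'
#' @param bands List of `c(center, width, epsilon_max)` vectors.
#' @param concentration Chromophore concentration, mol/L.
#' @param path_length Path length, cm.
#' @param from,to,step Wavelength grid in nm.
#' @return An [absorbance_spectrum()].
#' @export
generate_absorbance <- function(bands, concentration = 5e-6, path_length = 1,
                                from = 240, to = 340, step = 0.5) {
  check_number(step, "step", positive = TRUE)
  grid <- seq(from, to, by = step)
  absorbance_spectrum(grid,
                      concentration * path_length * sum_of_gaussians(grid, bands),
                      concentration = concentration, path_length = path_length,
                      label = "synthetic")
}

# Default EEM peaks: the Rayleigh-scatter peak (on the lambda_ex =
# lambda_em diagonal) and the intrinsic tryptophan peak, with free-
# protein intensities matching a typical serum-albumin measurement.
default_eem_peaks <- function() {
  list(
    "peak I" = c(ex = 360, em = 360, intensity = 252756, ex_width = 8, em_width = 8),
    "peak II" = c(ex = 280, em = 340, intensity = 9080, ex_width = 10, em_width = 14)
  )
}

#' Generate matched free/bound excitation-emission matrices
#'
#' Builds an EEM as a sum of separable 2-D Gaussian peaks, then a
#' "bound" counterpart in which each peak's intensity is multiplied by a
#' quench factor and its emission centre shifted - the signature of
#' ligand-induced quenching plus a red/blue shift of the fluorophore's
#' microenvironment.
#'
#' @param peaks Named list of peaks,
#'   `c(ex, em, intensity, ex_width, em_width)` (centres nm, peak
#'   intensity counts, widths = Gaussian standard deviations nm).
#' @param quench_factors Per-peak intensity multipliers for the bound
#'   matrix (recycled if scalar).
#' @param em_shifts Per-peak emission-centre shifts in nm for the bound
#'   matrix, positive = red (recycled if scalar).
#' @param excitation,emission Wavelength grids in nm (defaults: the
#'   10-nm instrument grids, 200-500 / 200-600 nm).
#' @return `list(free = , bound = )` of [eem_matrix()] objects.
#' @export
generate_eem <- function(peaks = default_eem_peaks(),
                         quench_factors = 1, em_shifts = 0,
                         excitation = seq(200, 500, by = 10),
                         emission = seq(200, 600, by = 10)) {
  if (!is.list(peaks) || length(peaks) == 0) {
    stop_validation("`peaks` must be a non-empty list")
  }
  np <- length(peaks)
  quench_factors <- rep_len(quench_factors, np)
  em_shifts <- rep_len(em_shifts, np)
  if (any(quench_factors < 0)) stop_validation("quench factors must be >= 0")

  build <- function(factors, shifts) {
    grid <- matrix(0, length(excitation), length(emission))
    for (i in seq_len(np)) {
      p <- peaks[[i]]
      need <- c("ex", "em", "intensity", "ex_width", "em_width")
      if (!all(need %in% names(p))) {
        stop_validation(sprintf("peak %d must have fields %s",
                                i, paste(need, collapse = ", ")))
      }
      gx <- exp(-(excitation - p[["ex"]])^2 / (2 * p[["ex_width"]]^2))
      gm <- exp(-(emission - (p[["em"]] + shifts[i]))^2 / (2 * p[["em_width"]]^2))
      grid <- grid + factors[i] * p[["intensity"]] * outer(gx, gm)
    }
    grid
  }
  list(
    free = eem_matrix(excitation, emission, build(rep(1, np), rep(0, np)),
                      label = "synthetic free"),
    bound = eem_matrix(excitation, emission, build(quench_factors, em_shifts),
                       label = "synthetic bound")
  )
}
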