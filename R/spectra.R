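#' Emission spectrum
#'
#' A fluorescence emission spectrum recorded at a fixed excitation
#' wavelength: intensity (counts per second) sampled on a strictly
#' increasing emission-wavelength grid.  The grid need not be uniform;
#' downstream operations interpolate.
#'
#' @param wavelength Emission wavelengths in nm, strictly increasing.
#' @param intensity Fluorescence intensities (counts), same length as
#'   `wavelength`, finite and non-negative.
#' @param excitation Excitation wavelength in nm.
#' @param temperature Temperature in K, or `NULL` if not recorded.
#' @param label Free-text label.
#' @return An object of class `emission_spectrum`.
#' @examples
#' sp <- emission_spectrum(300:400, dnorm(300:400, 330, 15), excitation = 280)
#' peak_wavelength(sp)
#' @export
emission_spectrum <- function(wavelength, intensity, excitation,
                              temperature = NULL, label = "") {
  check_axis(wavelength, "wavelength")
  check_intensity(intensity, length(wavelength), "intensity")
  check_number(excitation, "excitation", positive = TRUE)
  if (!is.null(temperature)) check_number(temperature, "temperature", positive = TRUE)
  structure(
    list(wavelength = as.numeric(wavelength), intensity = as.numeric(intensity),
         excitation = excitation, temperature = temperature,
         label = as.character(label)),
    class = "emission_spectrum"
  )
}

#' Absorbance spectrum
#'
#' A UV-Vis absorbance spectrum with the chromophore concentration and cell
#' path length needed to convert absorbance to a molar absorption
#' coefficient via the Beer-Lambert law.
#'
#' @param wavelength Wavelengths in nm, strictly increasing.
#' @param absorbance Absorbance in AU, same length as `wavelength`.
#' @param concentration Chromophore concentration in mol/L, > 0.
#' @param path_length Optical path length in cm, > 0.
#' @param label Free-text label.
#' @return An object of class `absorbance_spectrum`.
#' @seealso [molar_absorptivity()]
#' @export
absorbance_spectrum <- function(wavelength, absorbance, concentration,
                                path_length = 1, label = "") {
  check_axis(wavelength, "wavelength")
  if (!is.numeric(absorbance) || length(absorbance) != length(wavelength)) {
    stop_validation("`absorbance` must be numeric and match `wavelength` in length")
  }
  if (any(!is.finite(absorbance))) stop_validation("`absorbance` must be finite")
  check_number(concentration, "concentration", positive = TRUE)
  check_number(path_length, "path_length", positive = TRUE)
  structure(
    list(wavelength = as.numeric(wavelength), absorbance = as.numeric(absorbance),
         concentration = concentration, path_length = path_length,
         label = as.character(label)),
    class = "absorbance_spectrum"
  )
}

#' Quenching titration
#'
#' Fluorescence intensity read at a fixed reference emission wavelength as
#' a function of quencher concentration, together with the unquenched
#' intensity `F0`.  This is the substrate of the Stern-Volmer and
#' double-logarithmic binding analyses.
#'
#' Intensities exceeding `1.05 * F0` are physically suspect (more emission
#' with quencher than without, beyond plausible noise); they are kept but
#' flagged with a warning, and the flagged indices are stored in the
#' `flagged` element.
#'
#' @param concentration Quencher concentrations in mol/L, non-negative and
#'   strictly increasing (the first entry may be 0).
#' @param intensity Fluorescence intensities (counts), all > 0.
#' @param F0 Intensity at zero quencher (counts), > 0.
#' @param temperature Temperature in K (default 298).
#' @param ref_wavelength Reference emission wavelength in nm at which the
#'   intensities were read, or `NA` if unknown.
#' @param label Free-text label.
#' @return An object of class `quench_titration`.
#' @examples
#' tt <- quench_titration(seq(5e-6, 5e-5, length.out = 10),
#'                        1e4 / (1 + 8.5e3 * seq(5e-6, 5e-5, length.out = 10)),
#'                        F0 = 1e4)
#' stern_volmer_fit(tt)
#' @export
quench_titration <- function(concentration, intensity, F0, temperature = 298,
                             ref_wavelength = NA_real_, label = "") {
  if (!is.numeric(concentration) || any(is.na(concentration))) {
    stop_validation("`concentration` must be numeric without NA")
  }
  if (any(concentration < 0)) stop_validation("quencher concentrations must be non-negative")
  if (any(diff(concentration) <= 0)) {
    stop_validation("quencher concentrations must be strictly increasing")
  }
  check_intensity(intensity, length(concentration), "intensity")
  if (any(intensity <= 0)) stop_validation("all intensities must be > 0")
  check_number(F0, "F0", positive = TRUE)
  check_number(temperature, "temperature", positive = TRUE)
  flagged <- which(intensity > 1.05 * F0)
  if (length(flagged)) {
    warning(sprintf("%d intensit%s exceed 1.05 * F0; check for instrument drift",
                    length(flagged), if (length(flagged) == 1L) "y" else "ies"),
            call. = FALSE)
  }
  structure(
    list(concentration = as.numeric(concentration),
         intensity = as.numeric(intensity), F0 = F0,
         temperature = temperature, ref_wavelength = as.numeric(ref_wavelength),
         label = as.character(label), flagged = flagged),
    class = "quench_titration"
  )
}

#' Excitation-emission matrix
#'
#' The 3D-fluorescence landscape: an intensity grid over an excitation
#' axis (rows) and an emission axis (columns).
#'
#' @param excitation Excitation wavelengths in nm, strictly increasing.
#' @param emission Emission wavelengths in nm, strictly increasing.
#' @param intensity Numeric matrix of counts, `length(excitation)` rows by
#'   `length(emission)` columns, non-negative.
#' @param label Free-text label.
#' @return An object of class `eem_matrix`.
#' @seealso [synchronous_scan()], [eem_peak_table()]
#' @export
eem_matrix <- function(excitation, emission, intensity, label = "") {
  check_axis(excitation, "excitation")
  check_axis(emission, "emission")
  intensity <- as.matrix(intensity)
  if (nrow(intensity) != length(excitation) || ncol(intensity) != length(emission)) {
    stop_validation(sprintf(
      "intensity grid is %d x %d but axes imply %d x %d",
      nrow(intensity), ncol(intensity), length(excitation), length(emission)))
  }
  if (any(!is.finite(intensity))) stop_validation("EEM intensities must be finite")
  if (any(intensity < 0)) stop_validation("EEM intensities must be non-negative")
  structure(
    list(excitation = as.numeric(excitation), emission = as.numeric(emission),
         intensity = unname(intensity), label = as.character(label)),
    class = "eem_matrix"
  )
}

# Internal constructor: synchronous scans are produced by
# synchronous_scan(); direct construction is not part of the user API.
new_synchronous_scan <- function(delta_lambda, excitation, intensity) {
  check_number(delta_lambda, "delta_lambda", positive = TRUE)
  if (length(excitation) != length(intensity)) {
    stop_validation("excitation and intensity lengths differ")
  }
  structure(
    list(delta_lambda = delta_lambda, excitation = as.numeric(excitation),
         intensity = as.numeric(intensity)),
    class = "synchronous_scan"
  )
}

check_axis <- function(x, name) {
  if (!is.numeric(x) || length(x) < 2L || any(is.na(x))) {
    stop_validation(sprintf("`%s` must be a numeric vector (length >= 2) without NA", name))
  }
  if (any(diff(x) <= 0)) {
    stop_validation(sprintf("`%s` must be strictly increasing", name))
  }
  invisible(x)
}

check_intensity <- function(x, n, name) {
  if (!is.numeric(x) || length(x) != n) {
    stop_validation(sprintf("`%s` must be numeric with length %d", name, n))
  }
  if (any(!is.finite(x))) stop_validation(sprintf("`%s` must be finite", name))
  if (any(x < 0)) stop_validation(sprintf("`%s` must be non-negative", name))
  invisible(x)
}

#' Wavelength of maximum intensity
#'
#' Grid argmax of a spectrum; ties break toward the shorter wavelength.
#' No sub-grid refinement is attempted, matching the integer-nm reporting
#' convention of band-shift tables.
#'
#' @param x An `emission_spectrum` or `absorbance_spectrum`.
#' @param window Optional length-2 nm range to restrict the search.
#' @return The wavelength (nm) of the maximum.
#' @export
peak_wavelength <- function(x, window = NULL) {
  y <- if (inherits(x, "absorbance_spectrum")) x$absorbance else x$intensity
  w <- x$wavelength
  if (!is.null(window)) {
    keep <- w >= window[1] & w <= window[2]
    if (!any(keep)) stop_range("window lies outside the spectrum's wavelength range")
    w <- w[keep]; y <- y[keep]
  }
  w[which.max(y)]
}

#' @export
print.emission_spectrum <- function(x, ...) {
  cat(sprintf("<emission_spectrum> %d points, %g-%g nm, ex %g nm%s\n",
              length(x$wavelength), min(x$wavelength), max(x$wavelength),
              x$excitation,
              if (is.null(x$temperature)) "" else sprintf(", %g K", x$temperature)))
  invisible(x)
}

#' @export
print.absorbance_spectrum <- function(x, ...) {
  cat(sprintf("<absorbance_spectrum> %d points, %g-%g nm, c = %g M, l = %g cm\n",
              length(x$wavelength), min(x$wavelength), max(x$wavelength),
              x$concentration, x$path_length))
  invisible(x)
}

#' @export
print.quench_titration <- function(x, ...) {
  cat(sprintf("<quench_titration> %d points, [Q] %g-%g M, F0 = %g, T = %g K\n",
              length(x$concentration), min(x$concentration),
              max(x$concentration), x$F0, x$temperature))
  invisible(x)
}

#' @export
print.eem_matrix <- function(x, ...) {
  cat(sprintf("<eem_matrix> %d x %d (ex %g-%g nm, em %g-%g nm)\n",
              length(x$excitation), length(x$emission),
              min(x$excitation), max(x$excitation),
              min(x$emission), max(x$emission)))
  invisible(x)
}

#' @export
print.synchronous_scan <- function(x, ...) {
  cat(sprintf("<synchronous_scan> delta-lambda %g nm, %d points, ex %g-%g nm\n",
              x$delta_lambda, length(x$excitation),
              min(x$excitation), max(x$excitation)))
  invisible(x)
}
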