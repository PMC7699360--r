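#' Extract a synchronous-fluorescence scan from an EEM
#'
#' A synchronous scan records intensity along the line
#' `lambda_em = lambda_ex + delta_lambda` of the excitation-emission
#' matrix.  Offsets of 15 nm and 60 nm report the tyrosine and
#' tryptophan microenvironments respectively.  For each excitation grid
#' point whose target emission wavelength lies inside the emission axis,
#' the intensity is obtained by linear interpolation along the emission
#' axis (the excitation coordinate is on-grid, so bilinear interpolation
#' reduces to this 1-D case); excitation points whose target falls
#' outside the grid are dropped.
#'
#' @param eem An [eem_matrix()].
#' @param delta_lambda Wavelength offset in nm (> 0).
#' @return An object of class `synchronous_scan` with `delta_lambda`,
#'   `excitation`, `intensity`.
#' @seealso [compare_scans()]
#' @export
synchronous_scan <- function(eem, delta_lambda) {
  stopifnot(inherits(eem, "eem_matrix"))
  check_number(delta_lambda, "delta_lambda", positive = TRUE)
  target <- eem$excitation + delta_lambda
  ok <- target >= min(eem$emission) & target <= max(eem$emission)
  if (sum(ok) < 3L) {
    stop_range(sprintf(
      "delta_lambda = %g nm leaves %d excitation point(s) inside the emission axis (need >= 3)",
      delta_lambda, sum(ok)))
  }
  idx <- which(ok)
  intensity <- vapply(idx, function(i) {
    stats::approx(eem$emission, eem$intensity[i, ], xout = target[i])$y
  }, numeric(1))
  new_synchronous_scan(delta_lambda, eem$excitation[idx], intensity)
}

#' Compare free and ligand-bound synchronous scans
#'
#' Locates the global maximum of each scan (grid argmax, ties toward the
#' shorter wavelength) and summarises the ligand-induced change: percent
#' intensity change at the peak and the peak shift on the emission axis
#' (`lambda_ex + delta_lambda`; positive = red shift).
#'
#' @param free,bound `synchronous_scan` objects with equal
#'   `delta_lambda`.
#' @param rounding Decimals for the reported percent change (default 1).
#'   The unrounded value is kept in `percent_change_raw`.
#' @return An object of class `peak_summary` with free/bound peak
#'   intensities and emission-axis positions, `percent_change`, `shift`.
#' @export
compare_scans <- function(free, bound, rounding = 1) {
  stopifnot(inherits(free, "synchronous_scan"), inherits(bound, "synchronous_scan"))
  if (abs(free$delta_lambda - bound$delta_lambda) > 1e-9) {
    stop_validation("free and bound scans must share delta_lambda")
  }
  if (max(free$excitation) < min(bound$excitation) ||
      max(bound$excitation) < min(free$excitation)) {
    stop_validation("free and bound scans have non-overlapping excitation ranges")
  }
  i_f <- which.max(free$intensity)
  i_b <- which.max(bound$intensity)
  peak_summary(
    free_intensity = free$intensity[i_f],
    bound_intensity = bound$intensity[i_b],
    free_position = free$excitation[i_f] + free$delta_lambda,
    bound_position = bound$excitation[i_b] + bound$delta_lambda,
    rounding = rounding
  )
}

peak_summary <- function(free_intensity, bound_intensity, free_position,
                         bound_position, rounding = 1) {
  pct <- 100 * (bound_intensity - free_intensity) / free_intensity
  structure(
    list(free_intensity = free_intensity, bound_intensity = bound_intensity,
         percent_change = round(pct, rounding), percent_change_raw = pct,
         free_position = free_position, bound_position = bound_position,
         shift = bound_position - free_position),
    class = "peak_summary"
  )
}

#' @export
print.peak_summary <- function(x, ...) {
  cat(sprintf("peak %g -> %g counts (%+.*f%%), position %s -> %s nm (shift %+g nm)\n",
              x$free_intensity, x$bound_intensity,
              max(0, ceiling(-log10(max(abs(x$percent_change), 0.1))) + 1),
              x$percent_change,
              paste(x$free_position, collapse = "/"),
              paste(x$bound_position, collapse = "/"), x$shift))
  invisible(x)
}

# Default EEM report regions: the Rayleigh-scatter peak (lambda_ex =
# lambda_em, tracks overall protein surface area) and the intrinsic
# tryptophan fluorescence peak.  The Rayleigh peak is treated as an
# ordinary rectangular region, not specially modelled.
default_eem_regions <- function() {
  list(
    "peak I (Rayleigh)" = list(excitation = c(350, 370), emission = c(350, 370)),
    "peak II (Trp)" = list(excitation = c(270, 290), emission = c(320, 360))
  )
}

#' Peak table from free and bound excitation-emission matrices
#'
#' For each rectangular (excitation window x emission window) region,
#' finds the grid argmax of the free EEM and of every bound EEM, and
#' reports per bound matrix the percent intensity change relative to the
#' free protein and the emission-wavelength shift of the peak.  This is
#' the standard 3D-fluorescence summary used to read conformational
#' change out of ligand titrations.
#'
#' @param free An [eem_matrix()] of the free protein.
#' @param bound_list Named list of `eem_matrix` objects (e.g. one per
#'   ligand:protein ratio).
#' @param regions Named list of regions, each
#'   `list(excitation = c(lo, hi), emission = c(lo, hi))`.  The default
#'   covers the Rayleigh peak (350-370/350-370 nm) and the tryptophan
#'   peak (270-290/320-360 nm).
#' @param rounding Decimals for percent changes (default 1).
#' @return A data frame with one row per region x system (`free` first):
#'   `region`, `system`, `ex_nm`, `em_nm`, `intensity`,
#'   `percent_change`, `shift_em_nm` (both `NA` for the free rows).
#' @seealso [generate_eem()] for matched synthetic inputs.
#' @export
eem_peak_table <- function(free, bound_list, regions = default_eem_regions(),
                           rounding = 1) {
  stopifnot(inherits(free, "eem_matrix"))
  if (inherits(bound_list, "eem_matrix")) bound_list <- list(bound = bound_list)
  if (!is.list(bound_list) || length(bound_list) == 0 ||
      is.null(names(bound_list)) || any(!nzchar(names(bound_list)))) {
    stop_validation("`bound_list` must be a non-empty named list of eem_matrix objects")
  }
  if (is.null(names(regions)) || any(!nzchar(names(regions)))) {
    stop_validation("`regions` must be a named list")
  }
  rows <- list()
  for (rg in names(regions)) {
    reg <- regions[[rg]]
    fp <- eem_region_max(free, reg, rg)
    rows[[length(rows) + 1L]] <- data.frame(
      region = rg, system = "free", ex_nm = fp$ex, em_nm = fp$em,
      intensity = fp$intensity, percent_change = NA_real_,
      shift_em_nm = NA_real_)
    for (nm in names(bound_list)) {
      bp <- eem_region_max(bound_list[[nm]], reg, rg)
      rows[[length(rows) + 1L]] <- data.frame(
        region = rg, system = nm, ex_nm = bp$ex, em_nm = bp$em,
        intensity = bp$intensity,
        percent_change = round(100 * (bp$intensity - fp$intensity) / fp$intensity,
                               rounding),
        shift_em_nm = bp$em - fp$em)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Grid argmax inside a rectangular region.  The intensity submatrix is
# scanned in column-major order (excitation fastest), so ties resolve to
# the shortest excitation, then shortest emission, wavelength.
eem_region_max <- function(eem, region, region_name) {
  stopifnot(inherits(eem, "eem_matrix"))
  ex_in <- which(eem$excitation >= region$excitation[1] &
                 eem$excitation <= region$excitation[2])
  em_in <- which(eem$emission >= region$emission[1] &
                 eem$emission <= region$emission[2])
  if (length(ex_in) == 0 || length(em_in) == 0) {
    stop_range(sprintf("region '%s' does not intersect the EEM grid", region_name))
  }
  sub <- eem$intensity[ex_in, em_in, drop = FALSE]
  k <- which.max(sub)
  i <- (k - 1L) %% nrow(sub) + 1L
  j <- (k - 1L) %/% nrow(sub) + 1L
  list(ex = eem$excitation[ex_in[i]], em = eem$emission[em_in[j]],
       intensity = sub[i, j])
}

#' UV-Vis absorption-maximum shifts of a ligand-protein complex
#'
#' Locates the absorbance maximum (grid argmax, no sub-grid refinement)
#' of the free protein, the complex (ligand contribution subtracted) and
#' the free ligand inside a common wavelength window, and reports the
#' complex's band shift against each reference: negative = blue shift,
#' positive = red shift.  A shifted complex band distinct from both free
#' species is the classic absorption-side signature of ground-state
#' complex formation.
#'
#' @param free_protein,complex_minus_ligand,free_ligand
#'   [absorbance_spectrum()] objects covering `window`.
#' @param window Length-2 nm range to search (default `c(240, 320)`, the
#'   aromatic protein band).
#' @return An object of class `uvvis_shift_report`: the three lambda-max
#'   values plus `shift_vs_protein` and `shift_vs_ligand` (nm).
#' @export
uvvis_shift <- function(free_protein, complex_minus_ligand, free_ligand,
                        window = c(240, 320)) {
  for (sp in list(free_protein, complex_minus_ligand, free_ligand)) {
    stopifnot(inherits(sp, "absorbance_spectrum"))
  }
  if (length(window) != 2L || window[1] >= window[2]) {
    stop_validation("`window` must be an increasing length-2 nm range")
  }
  lam_protein <- peak_wavelength(free_protein, window)
  lam_complex <- peak_wavelength(complex_minus_ligand, window)
  lam_ligand <- peak_wavelength(free_ligand, window)
  structure(
    list(lambda_max_protein = lam_protein, lambda_max_complex = lam_complex,
         lambda_max_ligand = lam_ligand,
         shift_vs_protein = lam_complex - lam_protein,
         shift_vs_ligand = lam_complex - lam_ligand,
         window = window),
    class = "uvvis_shift_report"
  )
}

#' @export
print.uvvis_shift_report <- function(x, ...) {
  cat(sprintf("lambda_max: protein %g nm, complex %g nm, ligand %g nm (window %g-%g nm)\n",
              x$lambda_max_protein, x$lambda_max_complex, x$lambda_max_ligand,
              x$window[1], x$window[2]))
  cat(sprintf("  complex vs protein: %+g nm (%s shift); vs ligand: %+g nm (%s shift)\n",
              x$shift_vs_protein,
              if (x$shift_vs_protein < 0) "blue" else if (x$shift_vs_protein > 0) "red" else "no",
              x$shift_vs_ligand,
              if (x$shift_vs_ligand < 0) "blue" else if (x$shift_vs_ligand > 0) "red" else "no"))
  invisible(x)
}
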