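#' Double-logarithmic binding isotherm
#'
#' For static quenching by 1:n ground-state complex formation, the
#' quenched fraction obeys `log10((F0 - F)/F) = log10(Kb) + n * log10([Q])`.
#' Ordinary least squares of `log10((F0 - F)/F)` on `log10([Q])` therefore
#' yields the number of binding sites `n` from the slope and the
#' association constant `Kb` from the exponentiated intercept.  The Gibbs
#' free energy of association at the titration temperature is attached
#' via [gibbs_free_energy()].
#'
#' Points with `F >= F0` (no apparent quenching, expected from noise near
#' zero quencher) make the left-hand side undefined; they are dropped
#' with a warning and counted in `n_excluded`.  Free ligand is
#' approximated by total added ligand (no depletion correction).
#'
#' @param titration A [quench_titration()].
#' @return An object of class `binding_fit`: `K_b` (L/mol), `n_sites`,
#'   `K_b_stderr_log10` (standard error of the intercept, log10 units),
#'   `n_stderr`, `r_squared`, `temperature` (K), `delta_G` (kJ/mol),
#'   `n_points`, `n_excluded`.
#' @examples
#' q <- seq(5e-6, 5e-5, length.out = 10)
#' f <- 1e4 / (1 + 38.301e3 * q^1.161)
#' double_log_fit(quench_titration(q, f, F0 = 1e4))
#' @seealso [stern_volmer_fit()], [displacement_analysis()]
#' @export
double_log_fit <- function(titration) {
  stopifnot(inherits(titration, "quench_titration"))
  F0 <- titration$F0
  if (is.null(F0) || !is.finite(F0) || F0 <= 0) {
    stop_validation("titration must carry a positive F0")
  }
  usable <- titration$concentration > 0 & titration$intensity > 0 &
    titration$intensity < F0
  n_excluded <- sum(titration$concentration > 0) - sum(usable)
  if (n_excluded > 0) {
    warning(sprintf("%d point(s) with F >= F0 excluded from the double-log fit",
                    n_excluded), call. = FALSE)
  }
  if (sum(usable) < 3L) {
    stop_insufficient("double-log fit needs at least 3 points with 0 < F < F0")
  }
  q <- titration$concentration[usable]
  f <- titration$intensity[usable]
  x <- log10(q)
  y <- log10((F0 - f) / f)
  fit <- stats::lm(y ~ x)
  se <- lm_stderr(fit)
  kb <- 10^unname(stats::coef(fit)[["(Intercept)"]])
  n_sites <- unname(stats::coef(fit)[["x"]])
  structure(
    list(K_b = kb, n_sites = n_sites,
         K_b_stderr_log10 = se[["(Intercept)"]],
         n_stderr = se[["x"]],
         r_squared = r_squared_about_mean(y, stats::fitted(fit)),
         temperature = titration$temperature,
         delta_G = gibbs_free_energy(kb, titration$temperature),
         n_points = sum(usable), n_excluded = n_excluded),
    class = "binding_fit"
  )
}

#' Gibbs free energy of association
#'
#' `delta G = -R * T * ln(Kb)` with `R = 8.314 J K^-1 mol^-1`, returned
#' in kJ/mol.  Negative for any association constant above 1, i.e. for
#' any thermodynamically favourable binding.
#'
#' @param K_b Association constant, L/mol (> 0).
#' @param temperature Temperature in K (> 0).
#' @return Gibbs free energy change in kJ/mol.
#' @examples
#' gibbs_free_energy(38.301e3, 298)  # -26.15 kJ/mol
#' @export
gibbs_free_energy <- function(K_b, temperature) {
  check_number(K_b, "K_b", positive = TRUE)
  check_number(temperature, "temperature", positive = TRUE)
  -8.314 * temperature * log(K_b) / 1000
}

#' Site-marker competitive displacement analysis
#'
#' Compares apparent association constants fitted in the presence of
#' site-specific marker ligands against a marker-free baseline.  A marker
#' that occupies the ligand's binding site depresses the apparent `Kb`;
#' the analysis reports the percent change in `Kb` and the change in
#' Gibbs free energy per marker, and calls a marker displacing when `Kb`
#' drops by more than `threshold_percent`.
#'
#' @param baseline [double_log_fit()] result without any site marker.
#' @param marker_fits Named list of `binding_fit` objects, one per
#'   marker, all at the baseline's temperature.
#' @param threshold_percent Percent drop in `Kb` required to call
#'   displacement.  Default 10; there is no community cutoff, so it is
#'   explicit and configurable.
#' @return An object of class `displacement_report`: a data frame with
#'   one row per marker (`marker`, `K_b`, `n_sites`,
#'   `percent_change_Kb`, `delta_delta_G`, `displaces`), with the
#'   baseline fit and threshold stored as attributes.
#' @export
displacement_analysis <- function(baseline, marker_fits, threshold_percent = 10) {
  stopifnot(inherits(baseline, "binding_fit"))
  if (!is.list(marker_fits) || length(marker_fits) == 0 ||
      is.null(names(marker_fits)) || any(!nzchar(names(marker_fits)))) {
    stop_validation("`marker_fits` must be a non-empty named list")
  }
  if (!all(vapply(marker_fits, inherits, logical(1), "binding_fit"))) {
    stop_validation("all marker fits must be binding_fit objects")
  }
  check_number(threshold_percent, "threshold_percent", positive = TRUE)
  temps <- vapply(marker_fits, `[[`, numeric(1), "temperature")
  if (any(abs(temps - baseline$temperature) > 1e-9)) {
    stop_validation("all fits must be at the baseline temperature")
  }
  pct <- vapply(marker_fits, function(f) {
    100 * (f$K_b - baseline$K_b) / baseline$K_b
  }, numeric(1))
  ddg <- vapply(marker_fits, function(f) f$delta_G - baseline$delta_G, numeric(1))
  report <- data.frame(
    marker = names(marker_fits),
    K_b = vapply(marker_fits, `[[`, numeric(1), "K_b"),
    n_sites = vapply(marker_fits, `[[`, numeric(1), "n_sites"),
    percent_change_Kb = unname(pct),
    delta_delta_G = unname(ddg),
    displaces = unname(pct < -threshold_percent),
    row.names = NULL
  )
  structure(report, class = c("displacement_report", "data.frame"),
            baseline = baseline, threshold_percent = threshold_percent)
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("Double-log binding fit (%d points%s, T = %g K)\n",
              x$n_points,
              if (x$n_excluded) sprintf(", %d excluded", x$n_excluded) else "",
              x$temperature))
  cat(sprintf("  K_b = %.4g L/mol (log10 se %.3g)   n = %.4g +/- %.3g\n",
              x$K_b, x$K_b_stderr_log10, x$n_sites, x$n_stderr))
  cat(sprintf("  delta G = %.2f kJ/mol   R^2 = %.4f\n", x$delta_G, x$r_squared))
  invisible(x)
}

#' @export
print.displacement_report <- function(x, ...) {
  base <- attr(x, "baseline")
  cat(sprintf("Displacement analysis vs baseline K_b = %.4g L/mol (threshold %g%%)\n",
              base$K_b, attr(x, "threshold_percent")))
  print.data.frame(x, digits = 4)
  invisible(x)
}
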