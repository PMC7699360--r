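#' Analysis configuration
#'
#' Collects every tunable constant of the pipeline in one serializable
#' object: the unquenched lifetime `tau0` (s), the diffusion-controlled
#' quenching ceiling (L mol^-1 s^-1), the displacement-call threshold
#' (percent), the three Forster parameters, the FRET resampling step
#' (nm), the report rounding (decimals) and the RNG seed.
#'
#' @param tau0 Unquenched fluorescence lifetime, s.
#' @param diffusion_limit Diffusion-controlled rate ceiling, L mol^-1 s^-1.
#' @param displacement_threshold Percent drop in `Kb` that calls a
#'   marker displacing.
#' @param kappa_squared,refractive_index,donor_quantum_yield Forster
#'   parameters (see [forster_parameters()]).
#' @param grid_step Overlap-integral resampling step, nm.
#' @param rounding Decimals for percent changes in reports.
#' @param seed Integer RNG seed.
#' @return An object of class `analysis_config`.
#' @seealso [read_config()], [write_config()]
#' @export
analysis_config <- function(tau0 = 1e-8, diffusion_limit = 7.4e9,
                            displacement_threshold = 10,
                            kappa_squared = 2 / 3, refractive_index = 1.336,
                            donor_quantum_yield = 0.15,
                            grid_step = 0.5, rounding = 1, seed = 1L) {
  check_number(tau0, "tau0", positive = TRUE)
  check_number(diffusion_limit, "diffusion_limit", positive = TRUE)
  check_number(displacement_threshold, "displacement_threshold", positive = TRUE)
  params <- forster_parameters(kappa_squared, refractive_index, donor_quantum_yield)
  check_number(grid_step, "grid_step", positive = TRUE)
  check_number(rounding, "rounding")
  structure(
    list(tau0 = tau0, diffusion_limit = diffusion_limit,
         displacement_threshold = displacement_threshold,
         kappa_squared = params$kappa_squared,
         refractive_index = params$refractive_index,
         donor_quantum_yield = params$donor_quantum_yield,
         grid_step = grid_step, rounding = rounding, seed = as.integer(seed)),
    class = "analysis_config"
  )
}

#' Read an analysis configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path Path to a YAML file of `analysis_config` fields.
#' @return An [analysis_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("config file does not exist: %s", path))
  vals <- yaml::read_yaml(path)
  if (!is.list(vals)) stop_format("config file must be a YAML mapping")
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop_format(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  do.call(analysis_config, vals)
}

#' Write an analysis configuration to a YAML file
#'
#' @param config An [analysis_config()].
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  for (k in names(x)) cat(sprintf("  %s = %g\n", k, x[[k]]))
  invisible(x)
}
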