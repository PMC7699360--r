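# Classed conditions so callers (and tests) can distinguish failure modes
# without string matching.
abort_qb <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "quenchbind_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

stop_validation <- function(message) abort_qb(message, "qb_validation_error")
stop_format <- function(message) abort_qb(message, "qb_format_error")
stop_domain <- function(message) abort_qb(message, "qb_domain_error")
stop_range <- function(message) abort_qb(message, "qb_range_error")
stop_insufficient <- function(message) abort_qb(message, "qb_insufficient_data_error")

# Coefficient standard errors without summary.lm's "essentially perfect
# fit" warning, which is routine on noiseless synthetic data.
lm_stderr <- function(fit) {
  co <- withCallingHandlers(
    stats::coef(summary(fit)),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  stats::setNames(co[, "Std. Error"], rownames(co))
}

check_number <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_validation(sprintf("`%s` must be a single non-missing number", name))
  }
  if (finite && !is.finite(x)) {
    stop_validation(sprintf("`%s` must be finite", name))
  }
  if (positive && x <= 0) {
    stop_domain(sprintf("`%s` must be > 0 (got %g)", name, x))
  }
  invisible(x)
}
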