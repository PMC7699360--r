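# Shared fixture builders.  Titrations are synthesized directly from the
# static-quenching model F = F0 / (1 + Kb * [Q]^n) so fit tests do not
# depend on the generator module they are meant to cross-check.

model_titration <- function(K_b, n = 1, F0 = 1e4,
                            conc = seq(5e-6, 5e-5, length.out = 10),
                            temperature = 298) {
  quench_titration(conc, F0 / (1 + K_b * conc^n), F0 = F0,
                   temperature = temperature)
}

# A Stern-Volmer fit with a prescribed K_SV at a given temperature,
# obtained by fitting noiseless model data (n = 1 makes Kb == K_SV).
sv_fit_with <- function(K_SV, temperature, tau0 = 1e-8) {
  stern_volmer_fit(model_titration(K_SV, temperature = temperature),
                   tau0 = tau0, fix_intercept = TRUE)
}

# Binding fit with prescribed (Kb, n) from noiseless model data.
binding_fit_with <- function(K_b, n, temperature = 298) {
  double_log_fit(model_titration(K_b, n = n, temperature = temperature))
}

gauss <- function(x, center, width, amplitude = 1) {
  amplitude * exp(-(x - center)^2 / (2 * width^2))
}

# EEM whose intensity depends only on the excitation coordinate: its
# synchronous scan equals the profile for every admissible offset.
profile_eem <- function(excitation, profile, emission) {
  eem_matrix(excitation, emission,
             outer(profile, rep(1, length(emission))))
}
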