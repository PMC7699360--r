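test_that("Beer-Lambert conversion is pointwise and linear in 1/c", {
  grid <- seq(250, 320, by = 1)
  ab <- absorbance_spectrum(grid, rep(0.05, length(grid)),
                            concentration = 5e-6, path_length = 1)
  eps <- molar_absorptivity(ab)
  expect_equal(eps$epsilon, rep(1e4, length(grid)))

  ab2 <- absorbance_spectrum(grid, rep(0.05, length(grid)),
                             concentration = 1e-5, path_length = 1)
  expect_equal(molar_absorptivity(ab2)$epsilon, eps$epsilon / 2)

  # constructed from a known band: the band amplitude comes back
  band <- generate_absorbance(list(c(280, 12, 2.3e4)), concentration = 3e-6,
                              from = 240, to = 340, step = 0.5)
  eps3 <- molar_absorptivity(band)
  expect_equal(max(eps3$epsilon), 2.3e4, tolerance = 1e-9)
})

test_that("a delta-like donor against flat absorptivity gives J = eps * lambda0^4", {
  grid <- seq(300, 360, by = 0.5)
  intensity <- numeric(length(grid))
  intensity[grid == 330] <- 750
  donor <- emission_spectrum(grid, intensity, excitation = 280)
  flat <- absorbance_spectrum(seq(290, 400, by = 0.5),
                              rep(5e3 * 5e-6, 221), concentration = 5e-6)
  j <- overlap_integral(donor, flat)
  expect_equal(as.numeric(j), 5e3 * 330^4, tolerance = 1e-12)
})

test_that("J is invariant under uniform donor scaling", {
  donor <- generate_emission_spectrum(list(c(330, 15, 1e4)), from = 280, to = 400)
  scaled <- emission_spectrum(donor$wavelength, donor$intensity * 123.4,
                              excitation = donor$excitation)
  acc <- generate_absorbance(list(c(300, 20, 1e4)), from = 250, to = 400)
  j1 <- as.numeric(overlap_integral(donor, acc))
  j2 <- as.numeric(overlap_integral(scaled, acc))
  expect_equal(j1, j2, tolerance = 1e-12)
})

test_that("the 0.5-nm overlap integral matches fine-grained quadrature", {
  donor <- generate_emission_spectrum(list(c(330, 15, 1e4)), from = 280, to = 400)
  acc <- generate_absorbance(list(c(300, 20, 1e4)), concentration = 5e-6,
                             from = 250, to = 400)
  j <- as.numeric(overlap_integral(donor, acc))

  # brute-force oracle: 1e-3 nm rectangle rule on the analytic bands
  x <- seq(280, 400, by = 1e-3)
  f <- gauss(x, 330, 15, 1e4)
  e <- gauss(x, 300, 20, 1e4)
  j_oracle <- sum(f * e * x^4) / sum(f)
  expect_lt(abs(j - j_oracle) / j_oracle, 1e-3)

  # quadrature convergence: halving the step barely moves J
  j_half <- as.numeric(overlap_integral(donor, acc, step = 0.25))
  expect_lt(abs(j - j_half) / j, 1e-3)
})

test_that("disjoint spectra are a range error", {
  donor <- generate_emission_spectrum(list(c(330, 10, 1e3)), from = 300, to = 380)
  acc <- generate_absorbance(list(c(260, 10, 1e4)), from = 240, to = 290)
  expect_error(overlap_integral(donor, acc), class = "qb_range_error")
})

test_that("the Forster radius follows the sixth-root law", {
  r0 <- forster_radius(9.42e12)
  expect_lt(abs(r0 - 1.72), 0.01)
  expect_equal(forster_radius(64 * 9.42e12), 2 * r0, tolerance = 1e-12)
  expect_error(forster_radius(0), class = "qb_domain_error")
  expect_error(forster_radius(9.42e12, forster_parameters(kappa_squared = 0)),
               class = "qb_domain_error")
  expect_error(forster_parameters(kappa_squared = 5), class = "qb_domain_error")
  expect_error(forster_parameters(refractive_index = 0.9), class = "qb_domain_error")
})

test_that("transfer efficiency is the fractional intensity loss", {
  expect_equal(transfer_efficiency(1e4, 1e4), 0)
  expect_equal(transfer_efficiency(1e4, 0), 1)
  expect_equal(transfer_efficiency(1e4, 9.4e3), 0.06)
  expect_error(transfer_efficiency(1e4, 1.1e4), class = "qb_domain_error")
  expect_error(transfer_efficiency(0, 0), class = "qb_domain_error")
})

test_that("distance inversion is exact and self-consistent", {
  r <- donor_acceptor_distance(0.06, 1.72)
  expect_lt(abs(r - 2.72), 0.01)
  expect_equal(donor_acceptor_distance(0.5, 1.72), 1.72, tolerance = 1e-12)
  expect_error(donor_acceptor_distance(0, 1.72), class = "qb_domain_error")
  expect_error(donor_acceptor_distance(1, 1.72), class = "qb_domain_error")

  # algebraic roundtrip r -> E -> r at random radii
  set.seed(7)
  for (i in 1:20) {
    r0 <- runif(1, 1, 5)
    rr <- runif(1, 0.5, 8)
    e <- r0^6 / (r0^6 + rr^6)
    expect_equal(donor_acceptor_distance(e, r0), rr, tolerance = 1e-10)
  }
})

test_that("the assembled FRET chain is internally consistent", {
  donor <- generate_emission_spectrum(list(c(330, 15, 1e4)), from = 280, to = 450)
  acc <- generate_absorbance(list(c(300, 20, 1e4)), from = 250, to = 450)
  res <- fret_analysis(donor, acc, F0 = 1e4, F = 9.4e3)
  expect_equal(res$E, 0.06)
  expect_equal(res$E, res$R0^6 / (res$R0^6 + res$r^6), tolerance = 1e-12)
  expect_gt(res$J, 0)
  expect_gt(res$R0, 0)
  expect_gt(res$r, res$R0)  # E < 0.5 puts the pair beyond R0
})
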