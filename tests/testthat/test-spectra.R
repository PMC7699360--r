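test_that("read/write roundtrip is the identity on all object types", {
  dir <- withr::local_tempdir()

  sp <- emission_spectrum(c(300.25, 315.5, 333 + pi), c(12.5, exp(1) * 1e3, 0),
                          excitation = 280, temperature = 298, label = "hsa")
  sp2 <- read_spectrum(write_spectrum(sp, file.path(dir, "em.csv")), "emission")
  expect_identical(sp2$wavelength, sp$wavelength)
  expect_identical(sp2$intensity, sp$intensity)
  expect_identical(sp2$excitation, sp$excitation)
  expect_identical(sp2$temperature, sp$temperature)
  expect_identical(sp2$label, sp$label)

  ab_wl <- seq(240, 340, by = 7.3)
  ab <- absorbance_spectrum(ab_wl, runif(length(ab_wl), 0, 0.6),
                            concentration = 5e-6, path_length = 1.0)
  ab2 <- read_spectrum(write_spectrum(ab, file.path(dir, "abs.csv")), "absorbance")
  expect_identical(ab2$absorbance, ab$absorbance)
  expect_identical(ab2$concentration, ab$concentration)
  expect_identical(ab2$path_length, ab$path_length)

  tt <- quench_titration(seq(5e-6, 5e-5, length.out = 10),
                         1e4 / (1 + 8.5e3 * seq(5e-6, 5e-5, length.out = 10)),
                         F0 = 1e4, temperature = 310, ref_wavelength = 322)
  tt2 <- read_spectrum(write_spectrum(tt, file.path(dir, "tit.csv")), "titration")
  expect_identical(tt2$concentration, tt$concentration)
  expect_identical(tt2$intensity, tt$intensity)
  expect_identical(tt2$F0, tt$F0)
  expect_identical(tt2$temperature, tt$temperature)
  expect_identical(tt2$ref_wavelength, tt$ref_wavelength)

  eem <- eem_matrix(seq(200, 500, by = 10), seq(200, 600, by = 10),
                    matrix(runif(31 * 41, 0, 1e5), 31, 41))
  eem2 <- read_spectrum(write_spectrum(eem, file.path(dir, "eem.csv")), "eem")
  expect_identical(eem2$excitation, eem$excitation)
  expect_identical(eem2$emission, eem$emission)
  expect_identical(eem2$intensity, eem$intensity)
})

test_that("constructors enforce the type invariants", {
  expect_error(emission_spectrum(c(300, 300, 310), c(1, 2, 3), excitation = 280),
               class = "qb_validation_error")
  expect_error(emission_spectrum(c(300, 310), c(1, -2), excitation = 280),
               class = "qb_validation_error")
  expect_error(emission_spectrum(c(300, 310), c(1, NaN), excitation = 280),
               class = "qb_validation_error")
  expect_error(absorbance_spectrum(c(300, 310), c(0.1, 0.2), concentration = 0),
               class = "qb_domain_error")
  expect_error(quench_titration(c(2e-6, 1e-6), c(10, 20), F0 = 30),
               class = "qb_validation_error")
  expect_error(quench_titration(c(1e-6, 2e-6), c(10, 0), F0 = 30),
               class = "qb_validation_error")
  # grid dimensions must match the axes
  expect_error(eem_matrix(c(300, 310, 320), c(350, 360), matrix(1, 2, 2)),
               class = "qb_validation_error")
  expect_error(eem_matrix(c(300, 310), c(350, 360), matrix(-1, 2, 2)),
               class = "qb_validation_error")
})

test_that("suspiciously bright titration points are flagged, not dropped", {
  expect_warning(
    tt <- quench_titration(c(1e-6, 2e-6, 3e-6), c(900, 1100, 800), F0 = 1000),
    "exceed 1.05"
  )
  expect_identical(tt$flagged, 2L)
  expect_length(tt$intensity, 3L)
})

test_that("malformed files are rejected with the offending line named", {
  dir <- withr::local_tempdir()
  bad_meta <- file.path(dir, "bad_meta.csv")
  writeLines(c("# excitation 280", "wavelength,intensity", "300,1"), bad_meta)
  expect_error(read_spectrum(bad_meta, "emission"),
               "line 1", class = "qb_format_error")

  bad_header <- file.path(dir, "bad_header.csv")
  writeLines(c("# excitation=280", "wl,counts", "300,1"), bad_header)
  expect_error(read_spectrum(bad_header, "emission"),
               "line 2", class = "qb_format_error")

  ragged <- file.path(dir, "ragged.csv")
  writeLines(c("excitation,350,360", "300,1,2", "310,1"), ragged)
  expect_error(read_spectrum(ragged, "eem"), "line 3", class = "qb_format_error")

  non_numeric <- file.path(dir, "nn.csv")
  writeLines(c("# excitation=280", "wavelength,intensity", "300,1", "abc,2"),
             non_numeric)
  expect_error(read_spectrum(non_numeric, "emission"),
               "line 4", class = "qb_format_error")

  # non-monotone wavelengths are a validation error, never repaired
  non_mono <- file.path(dir, "nm.csv")
  writeLines(c("# excitation=280", "wavelength,intensity", "310,1", "300,2"),
             non_mono)
  expect_error(read_spectrum(non_mono, "emission"), class = "qb_validation_error")

  # missing required metadata
  no_f0 <- file.path(dir, "nof0.csv")
  writeLines(c("concentration,intensity", "1e-6,10", "2e-6,9", "3e-6,8"), no_f0)
  expect_error(read_spectrum(no_f0, "titration"), "f0", class = "qb_format_error")

  # declared kind must match the requested kind
  tt <- quench_titration(c(1e-6, 2e-6, 3e-6), c(10, 9, 8), F0 = 11)
  p <- write_spectrum(tt, file.path(dir, "tit.csv"))
  expect_error(read_spectrum(p, "emission"), class = "qb_format_error")

  expect_error(read_spectrum(file.path(dir, "absent.csv"), "emission"),
               class = "qb_format_error")
})

test_that("writing to an impossible path errors", {
  tt <- quench_titration(c(1e-6, 2e-6), c(10, 9), F0 = 11)
  expect_error(write_spectrum(tt, file.path(tempdir(), "no", "such", "dir", "x.csv")),
               class = "qb_format_error")
})
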