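test_that("a scan of an excitation-only EEM returns the profile for any offset", {
  ex <- seq(260, 320, by = 1)
  em <- seq(270, 400, by = 1)
  profile <- gauss(ex, 287, 9, 4303)
  eem <- profile_eem(ex, profile, em)
  for (dl in c(15, 60)) {
    sc <- synchronous_scan(eem, dl)
    keep <- ex + dl <= max(em)
    expect_equal(sc$intensity, profile[keep], tolerance = 1e-12)
  }
})

test_that("the scan peak of a separable Gaussian EEM sits at the analytic maximum", {
  ex <- seq(240, 320, by = 0.5)
  em <- seq(280, 420, by = 0.5)
  eem <- eem_matrix(ex, em, outer(gauss(ex, 280, 10), gauss(em, 330, 20, 1e4)))
  sc <- synchronous_scan(eem, 60)
  # maximize G(x; 280, 10) * G(x + 60; 330, 20): precision-weighted mean
  x_star <- (280 / 10^2 + (330 - 60) / 20^2) / (1 / 10^2 + 1 / 20^2)
  expect_equal(x_star, 278)
  expect_equal(sc$excitation[which.max(sc$intensity)], x_star)
})

test_that("synchronous scans commute with intensity scaling", {
  ex <- seq(250, 320, by = 2)
  em <- seq(260, 420, by = 2)
  grid <- outer(gauss(ex, 285, 12), gauss(em, 340, 25, 5e3)) + 1
  e1 <- eem_matrix(ex, em, grid)
  e2 <- eem_matrix(ex, em, 3.7 * grid)
  s1 <- synchronous_scan(e1, 60)
  s2 <- synchronous_scan(e2, 60)
  expect_equal(s2$intensity, 3.7 * s1$intensity, tolerance = 1e-12)
})

test_that("an offset exceeding the emission range is a range error", {
  ex <- seq(260, 320, by = 10)
  em <- seq(270, 340, by = 10)
  eem <- profile_eem(ex, rep(1, length(ex)), em)
  expect_error(synchronous_scan(eem, 500), class = "qb_range_error")
})

test_that("free/bound scan comparison reproduces the published summaries", {
  # tryptophan offset: peak 12166 cps at 346 nm free, 11430 at 348 nm bound
  ex <- seq(266, 320, by = 1)
  em <- seq(300, 400, by = 1)
  free60 <- synchronous_scan(profile_eem(ex, gauss(ex, 286, 8, 12166), em), 60)
  bound60 <- synchronous_scan(profile_eem(ex, gauss(ex, 288, 8, 11430), em), 60)
  s <- compare_scans(free60, bound60, rounding = 2)
  expect_equal(s$percent_change, -6.05)
  expect_equal(s$free_position, 346)
  expect_equal(s$bound_position, 348)
  expect_equal(s$shift, 2)

  # tyrosine offset: intensities 4303 -> 3910, no wavelength shift;
  # the computed change is -9.13% (one rounding step from the raw counts)
  ex15 <- seq(270, 305, by = 1)
  em15 <- seq(280, 330, by = 1)
  free15 <- synchronous_scan(profile_eem(ex15, gauss(ex15, 287, 7, 4303), em15), 15)
  bound15 <- synchronous_scan(profile_eem(ex15, gauss(ex15, 287, 7, 3910), em15), 15)
  s15 <- compare_scans(free15, bound15, rounding = 2)
  expect_equal(s15$percent_change, -9.13)
  expect_equal(s15$shift, 0)

  ident <- compare_scans(free60, free60)
  expect_equal(ident$percent_change, 0)
  expect_equal(ident$shift, 0)

  expect_error(compare_scans(free60, bound15), class = "qb_validation_error")
})

test_that("percent change carries the sign of the intensity difference", {
  ex <- seq(270, 310, by = 1)
  em <- seq(300, 400, by = 1)
  lo <- synchronous_scan(profile_eem(ex, gauss(ex, 286, 8, 900), em), 60)
  hi <- synchronous_scan(profile_eem(ex, gauss(ex, 286, 8, 1000), em), 60)
  expect_lt(compare_scans(hi, lo)$percent_change, 0)
  expect_gt(compare_scans(lo, hi)$percent_change, 0)
})

test_that("EEM peak tables reproduce the published free/bound changes", {
  pair_11 <- generate_eem(quench_factors = c(235360, 8393) / c(252756, 9080))
  pair_21 <- generate_eem(quench_factors = c(220564, 8293) / c(252756, 9080),
                          em_shifts = c(0, 10))
  tab <- eem_peak_table(pair_11$free,
                        list("1:1" = pair_11$bound, "2:1" = pair_21$bound))
  free_rows <- tab[tab$system == "free", ]
  expect_equal(free_rows$intensity, c(252756, 9080), tolerance = 1e-9)
  expect_equal(free_rows$ex_nm, c(360, 280))
  expect_equal(free_rows$em_nm, c(360, 340))

  b11 <- tab[tab$system == "1:1", ]
  b21 <- tab[tab$system == "2:1", ]
  expect_equal(b11$percent_change, c(-6.9, -7.6))
  expect_equal(b21$percent_change, c(-12.7, -8.7))
  expect_equal(b11$shift_em_nm, c(0, 0))
  expect_equal(b21$shift_em_nm, c(0, 10))
  expect_equal(b21$em_nm[2], 350)

  ident <- eem_peak_table(pair_11$free, list(same = pair_11$free))
  same_rows <- ident[ident$system == "same", ]
  expect_equal(same_rows$percent_change, c(0, 0))
  expect_equal(same_rows$shift_em_nm, c(0, 0))

  expect_error(
    eem_peak_table(pair_11$free, list(b = pair_11$bound),
                   regions = list(off = list(excitation = c(900, 950),
                                             emission = c(900, 950)))),
    "off", class = "qb_range_error")
})

test_that("UV-Vis band shifts are read from grid maxima inside the window", {
  mk <- function(center) {
    generate_absorbance(list(c(center, 9, 1.2e4)), concentration = 5e-6,
                        from = 240, to = 320, step = 1)
  }
  rep <- uvvis_shift(mk(277), mk(269), mk(266))
  expect_equal(rep$lambda_max_protein, 277)
  expect_equal(rep$lambda_max_complex, 269)
  expect_equal(rep$shift_vs_protein, -8)
  expect_equal(rep$shift_vs_ligand, 3)

  same <- uvvis_shift(mk(300), mk(300), mk(300), window = c(240, 320))
  expect_equal(same$shift_vs_protein, 0)
  expect_equal(same$shift_vs_ligand, 0)
  expect_equal(same$lambda_max_complex, 300)

  expect_error(uvvis_shift(mk(277), mk(269), mk(266), window = c(500, 600)),
               class = "qb_range_error")
})
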