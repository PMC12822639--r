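test_that("truncation keeps exactly the points inside closed windows", {
  s <- new_spectrum(default_grid(), seq_along(default_grid()))
  tr <- truncate_spectrum(s, list(c(1445, 1750), c(2760, 3000)))
  # enumeration oracle: count grid points satisfying the closed intervals
  g <- default_grid()
  expected <- sum((g >= 1445 & g <= 1750) | (g >= 2760 & g <= 3000))
  expect_equal(length(tr$wavenumbers), expected)
  expect_equal(expected, 137)  # 77 + 60 points on the 4 cm-1 grid
  full <- truncate_spectrum(s, list(c(650, 4000)))
  expect_equal(full$absorbance, s$absorbance)
  expect_error(truncate_spectrum(s, list(c(100, 200))), "no points")
  expect_error(truncate_spectrum(s, list(c(1445, 1750), c(1700, 3000))),
               "disjoint")
})

test_that("rubberband removes a pure line and ALS is ramp-invariant", {
  g <- seq(1000, 1500, by = 5)
  line <- new_spectrum(g, 0.3 + 0.002 * g)
  rb <- baseline_correct(line, "rubberband")
  expect_lt(max(abs(rb$absorbance)), 1e-6 * max(line$absorbance))
  zero <- baseline_correct(new_spectrum(g, rep(0, length(g))), "rubberband")
  expect_equal(zero$absorbance, rep(0, length(g)))
  # peaked spectrum plus a linear ramp: ALS correction of both agrees
  peak <- exp(-(g - 1250)^2 / (2 * 20^2))
  s0 <- baseline_correct(new_spectrum(g, peak), "als")
  s1 <- baseline_correct(new_spectrum(g, peak + 0.1 + 0.0004 * g), "als")
  expect_lt(max(abs(s1$absorbance - s0$absorbance)), 0.02 * max(peak))
  bad <- new_spectrum(g, c(rep(1, length(g) - 1), Inf))
  expect_error(baseline_correct(bad, "als"), "non-finite")
})

test_that("gaussian smoothing preserves constants and damps noise", {
  g <- seq(1000, 1400, by = 4)
  const <- gaussian_smooth(new_spectrum(g, rep(2.5, length(g))), 2)
  expect_equal(const$absorbance, rep(2.5, length(g)), tolerance = 1e-12)
  reduced <- 0L
  for (i in 1:100) {
    y <- withr::with_seed(i, rnorm(length(g)))
    sm <- gaussian_smooth(new_spectrum(g, y), 2)
    reduced <- reduced + (stats::var(sm$absorbance) < stats::var(y))
  }
  expect_equal(reduced, 100L)
  y <- withr::with_seed(1, rnorm(length(g)))
  near_id <- gaussian_smooth(new_spectrum(g, y), 1e-4)
  expect_lt(max(abs(near_id$absorbance - y)), 1e-9)
})

test_that("silica normalization pins the window maximum at one and is scale-invariant", {
  s <- generate_spectrum(default_profiles()$Fungi, default_grid(), seed = 2)
  n1 <- normalize_silica(s)
  sel <- n1$wavenumbers >= 1585 & n1$wavenumbers <= 1645
  expect_equal(max(n1$absorbance[sel]), 1)
  s3 <- s
  s3$absorbance <- 3 * s$absorbance
  n3 <- normalize_silica(s3)
  expect_equal(n1$absorbance, n3$absorbance, tolerance = 1e-14)
  flat <- new_spectrum(default_grid(), rep(0, length(default_grid())))
  expect_error(normalize_silica(flat), "non-positive")
})

test_that("vector normalization yields unit norm, idempotence, preserved signs", {
  g <- seq(1000, 1200, by = 4)
  y <- withr::with_seed(3, rnorm(length(g)))
  v1 <- vector_normalize(new_spectrum(g, y))
  expect_equal(sqrt(sum(v1$absorbance^2)), 1)
  v2 <- vector_normalize(v1)
  expect_equal(v2$absorbance, v1$absorbance, tolerance = 1e-12)
  expect_identical(sign(v1$absorbance), sign(y))
  expect_error(vector_normalize(new_spectrum(g, rep(0, length(g)))), "norm")
})

test_that("Savitzky-Golay derivatives are exact on polynomials and locate band centers", {
  g <- seq(1000, 1400, by = 4)
  s2 <- savitzky_golay(new_spectrum(g, g^2), 9, 2, 2)
  interior <- 6:(length(g) - 5)
  expect_equal(s2$absorbance[interior], rep(2, length(interior)),
               tolerance = 1e-6)
  s1 <- savitzky_golay(new_spectrum(g, 5 * g + 1), 9, 2, 2)
  expect_equal(s1$absorbance[interior], rep(0, length(interior)),
               tolerance = 1e-6)
  band <- exp(-(g - 1200)^2 / (2 * 15^2))
  d2 <- savitzky_golay(new_spectrum(g, band), 9, 2, 2)
  expect_equal(g[which.min(d2$absorbance[interior]) + 5], 1200)
  # deriv 0 reproduces polynomials up to the fitted order at interior points
  s0 <- savitzky_golay(new_spectrum(g, g^2), 9, 2, 0)
  expect_equal(s0$absorbance[interior], (g^2)[interior], tolerance = 1e-6)
  bad <- new_spectrum(c(1000, 1004, 1012, 1020, 1028, 1036, 1044, 1052, 1060),
                      1:9)
  expect_error(savitzky_golay(bad, 5, 2, 2), "uniform")
})

test_that("recipes compose, track history, and enforce step order", {
  ds <- small_two_class(3, 3)
  expect_identical(apply_recipe(ds, list()), ds)
  proc <- apply_recipe(ds, "atr-paper")
  # every spectrum gained one history entry per step
  expect_true(all(vapply(proc$spectra, function(s) length(s$history) == 4L,
                         logical(1))))
  g <- proc$wavenumbers
  expect_true(all(g >= 1445 & g <= 1750 | g >= 2760 & g <= 3000))
  mx <- vapply(proc$spectra, function(s)
    max(s$absorbance[g >= 1585 & g <= 1645]), numeric(1))
  expect_equal(mx, rep(1, length(mx)), tolerance = 1e-12)
  # normalizing after truncating away the silica window must fail
  bad <- list(list(step = "truncate", windows = list(c(2760, 3000))),
              list(step = "normalize_silica"))
  expect_error(apply_recipe(ds, bad), "silica")
  # error annotation carries the sample id
  expect_error(apply_recipe(ds, bad), ds$spectra[[1]]$sample_id)
})
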