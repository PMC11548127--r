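test_that("baseline correction nulls pure polynomials and zero spectra", {
  wn <- seq(698, 3845, by = 4)
  x <- seq(-1, 1, length.out = length(wn))
  base <- 0.3 + 0.2 * x - 0.15 * x^2
  out <- baseline_correct(base, order = 2)
  expect_lt(max(abs(out)), 1e-6 * diff(range(base)))

  expect_equal(baseline_correct(rep(0, length(wn)), order = 2),
               rep(0, length(wn)))
})

test_that("baseline correction recovers a known peak on a quadratic drift", {
  wn <- seq(698, 3845, by = 4)
  x <- seq(-1, 1, length.out = length(wn))
  truth_peak <- gauss(wn, 2920, 0.5, 20)
  spectrum <- truth_peak + (0.4 - 0.25 * x + 0.2 * x^2)
  out <- baseline_correct(spectrum, order = 2)
  b <- default_bands()
  height <- band_intensity(out, wn, b$ch2_asym)
  expect_lt(abs(height - 0.5) / 0.5, 0.02)
})

test_that("baseline correction is idempotent within tolerance", {
  wn <- seq(698, 3845, by = 4)
  x <- seq(-1, 1, length.out = length(wn))
  spectrum <- gauss(wn, 1652, 0.75, 25) + gauss(wn, 2920, 0.3, 17) +
    0.3 + 0.2 * x + 0.1 * x^2
  once <- baseline_correct(spectrum, order = 2, tol = 1e-3)
  twice <- baseline_correct(once, order = 2, tol = 1e-3)
  expect_lt(max(abs(twice - once)), 1e-3 * diff(range(spectrum)))
})

test_that("baseline correction passes NaN channels through and rejects all-NaN", {
  wn <- seq(1000, 1400, by = 8)
  s <- gauss(wn, 1200, 1, 30) + 0.2
  s[c(3, 10)] <- NaN
  out <- baseline_correct(s, order = 1)
  expect_true(all(is.nan(out[c(3, 10)])))
  expect_true(all(is.finite(out[-c(3, 10)])))
  expect_error(baseline_correct(rep(NaN, 10)), "degenerate")
  expect_error(baseline_correct(c(1, 2, NaN), order = 2), "too few")
})

test_that("matrix and single-spectrum baseline paths agree exactly", {
  set.seed(21)
  wn <- seq(698, 3845, by = 16)
  n <- length(wn)
  m <- t(replicate(6, gauss(wn, 1652, runif(1, 0.4, 1), 25) +
                     runif(1, 0, 0.3) + runif(1, -0.1, 0.1) * seq(-1, 1, length.out = n)))
  cube <- make_cube(m, wn, 2, 3)
  pp <- apply_plan(cube, preprocess_plan("poly", "none"))
  got <- matrix(pp$cube$data, 6, n)
  for (i in 1:6) {
    expect_equal(got[i, ], baseline_correct(m[i, ], order = 2, x = wn),
                 tolerance = 1e-12)
  }
})

test_that("area normalization: unit mean, constants, scalar invariance", {
  wn <- seq(1000, 1500, by = 4)
  expect_equal(normalize_area(rep(3.2, length(wn))), rep(1, length(wn)))
  s <- gauss(wn, 1200, 0.8, 25) + 0.05
  ns <- normalize_area(s)
  expect_equal(mean(ns), 1, tolerance = 1e-10)
  expect_equal(normalize_area(3 * s), ns, tolerance = 1e-12)
  expect_error(normalize_area(s - 10), "not positive")
})

test_that("Amide II normalization: unit peak, idempotence, scalar invariance", {
  wn <- seq(698, 3845, by = 4)
  s <- gauss(wn, 1548, 0.5, 22) + gauss(wn, 1652, 0.7, 25)
  b <- default_bands()
  ns <- normalize_amide2(s, wn, b$amide2)
  expect_equal(band_intensity(ns, wn, b$amide2), 1, tolerance = 1e-10)
  expect_equal(max(ns) > max(s), TRUE)  # I(1548) = 0.5 doubles the spectrum
  expect_equal(normalize_amide2(ns, wn, b$amide2), ns, tolerance = 1e-12)
  expect_equal(normalize_amide2(3 * s, wn, b$amide2), ns, tolerance = 1e-12)
  expect_error(normalize_amide2(-s, wn, b$amide2), "not positive")
})

test_that("identity plan returns the cube unchanged", {
  sm <- simulate_map(quick_cfg(seed = 12L))
  pp <- apply_plan(sm$cube, preprocess_plan("none", "none"))
  expect_identical(pp$cube$data, sm$cube$data)
  expect_true(all(pp$valid$grid))
  expect_identical(pp$cube$metadata$plan, "none+none")
})

test_that("homogeneous noiseless cube stays homogeneous through baseline+area", {
  cfg <- quick_cfg(thickness_cv = 0, lipid_cv = 0, baseline_scale = 0,
                   noise_sd = 0, hot_frac = 0, dead_frac = 0,
                   contam_frac = 0, seed = 13L)
  sm <- simulate_map(cfg)
  pp <- apply_plan(sm$cube, preprocess_plan("poly", "area"))
  m <- matrix(pp$cube$data, 256, length(sm$cube$wavenumber))
  spread <- apply(m, 2, function(x) diff(range(x)))
  expect_lt(max(spread), 1e-9 * diff(range(m[1, ])))
})

test_that("six standard plans: distinct band means, raw > baseline-corrected at 2920", {
  sm <- simulate_map(quick_cfg(seed = 14L, hot_frac = 0, dead_frac = 0,
                               contam_frac = 0))
  b <- default_bands()
  plans <- standard_plans()
  expect_length(plans, 6L)
  means <- vapply(plans, function(pl) {
    pp <- apply_plan(sm$cube, pl)
    mean(chemical_map(pp$cube, b$ch2_asym)[pp$valid$grid])
  }, numeric(1))
  expect_identical(anyDuplicated(round(means, 10)), 0L)
  expect_gt(means[["raw"]], means[["baseline"]])
})

test_that("pixels failing normalization are flagged invalid, not dropped silently", {
  wn <- seq(698, 3845, by = 16)
  s <- gauss(wn, 1548, 0.5, 22) + 0.1
  m <- matrix(s, 9, length(wn), byrow = TRUE)
  m[4, ] <- 0            # zero spectrum: area mean and Amide II are 0
  m[7, ] <- NaN          # dead pixel
  cube <- make_cube(m, wn, 3, 3)
  for (norm in c("area", "amide2")) {
    pp <- apply_plan(cube, preprocess_plan("none", norm))
    expect_identical(as.vector(pp$valid$grid), !(seq_len(9) %in% c(4, 7)))
    expect_true(all(is.nan(pp$cube$data[1, 2, ])))  # pixel 4 = (1,2)
  }
})

test_that("band ratios are invariant under scalar normalization but not baseline removal", {
  wn <- seq(698, 3845, by = 4)
  b <- default_bands()
  slope <- 0.25 * (wn - min(wn)) / diff(range(wn))
  s <- gauss(wn, 2920, 0.3, 17) + gauss(wn, 2850, 0.2, 15) + slope + 0.1
  r_raw <- band_ratio(s, wn, b$ch2_asym, b$ch2_sym)
  expect_equal(band_ratio(normalize_area(s), wn, b$ch2_asym, b$ch2_sym),
               r_raw, tolerance = 1e-12)
  expect_equal(band_ratio(normalize_amide2(s, wn, b$amide2), wn,
                          b$ch2_asym, b$ch2_sym),
               r_raw, tolerance = 1e-12)
  r_bl <- band_ratio(baseline_correct(s, order = 2), wn,
                     b$ch2_asym, b$ch2_sym)
  expect_gt(abs(r_bl - r_raw), 0.05)
})

test_that("area normalization cancels multiplicative thickness variation", {
  cfg <- quick_cfg(thickness_cv = 0.20, lipid_cv = 0, baseline_scale = 0,
                   noise_sd = 0, hot_frac = 0, dead_frac = 0,
                   contam_frac = 0, seed = 15L)
  sm <- simulate_map(cfg)
  b <- default_bands()
  cv_raw <- normalized_sd(chemical_map(sm$cube, b$ch2_asym))
  pp <- apply_plan(sm$cube, preprocess_plan("none", "area"))
  cv_norm <- normalized_sd(chemical_map(pp$cube, b$ch2_asym))
  expect_lt(cv_norm, 0.1 * cv_raw)
})
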