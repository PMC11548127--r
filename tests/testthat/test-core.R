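test_that("absorbance/transmittance conversion matches the logarithmic convention", {
  expect_equal(absorbance_from_transmittance(10), 1.0)
  expect_equal(absorbance_from_transmittance(1), 2.0)
  expect_equal(absorbance_from_transmittance(100), 0.0)

  # strictly decreasing in %T, and the inverse round-trips to 1e-12
  pt <- c(0.01, 0.1, 1, 5, 10, 37, 50, 99, 100)
  a <- absorbance_from_transmittance(pt)
  expect_true(all(diff(a) < 0))
  expect_equal(transmittance_from_absorbance(a), pt, tolerance = 1e-12)

  expect_error(absorbance_from_transmittance(0), "positive")
  expect_error(absorbance_from_transmittance(-3), "positive")
})

test_that("nearest_channel finds the closest channel and breaks ties low", {
  axis <- c(1000, 1008, 1016)
  expect_identical(nearest_channel(axis, 1008), 2L)
  expect_identical(nearest_channel(axis, 1004), 1L)  # tie goes to lower wn

  # dense axis: agree with a linear-scan oracle on random targets
  wn <- seq(698, 3845, by = 4)
  set.seed(11)
  for (target in runif(25, 700, 3840)) {
    oracle <- order(abs(wn - target))[1]
    idx <- nearest_channel(wn, target)
    expect_identical(idx, oracle)
    expect_lte(abs(wn[idx] - target), 2)
  }
  expect_error(nearest_channel(axis, 1100), "outside")
  expect_error(nearest_channel(axis, 900), "outside")
})

test_that("spectral_cube validates shape and axis monotonicity", {
  wn <- seq(1000, 1040, by = 8)
  cube <- uniform_cube(gauss(wn, 1020, 1, 10), wn, 3, 5)
  expect_s3_class(cube, "spectral_cube")
  expect_error(spectral_cube(array(0, c(2, 2, 3)), c(1, 2)), "channels")
  expect_error(spectral_cube(array(0, c(2, 2, 3)), c(3, 2, 1)), "increasing")
  expect_error(spectral_cube(matrix(0, 2, 2), c(1, 2)), "3-d")
})

test_that("cube field of view is cols x pixel_pitch", {
  wn <- c(1000, 1008)
  cube <- spectral_cube(array(0, c(128, 128, 2)), wn, pixel_pitch = 2.7)
  fov <- cube_fov(cube)
  expect_equal(unname(fov["width"]), 345.6)
  expect_equal(unname(fov["height"]), 345.6)
})

test_that("masked_mean_spectrum matches a brute-force loop oracle", {
  set.seed(42)
  rows <- 8L; cols <- 8L
  wn <- seq(1000, 1032, by = 8)
  m <- matrix(rnorm(rows * cols * length(wn)), rows * cols, length(wn))
  cube <- make_cube(m, wn, rows, cols)
  grid <- matrix(sample(c(TRUE, FALSE), rows * cols, TRUE, c(0.7, 0.3)),
                 rows, cols)
  mask <- pixel_mask(grid)

  ms <- masked_mean_spectrum(cube, mask)
  for (ch in seq_along(wn)) {
    vals <- c()
    for (r in seq_len(rows)) for (cc in seq_len(cols)) {
      if (grid[r, cc]) vals <- c(vals, cube$data[r, cc, ch])
    }
    expect_equal(ms$mean[ch], mean(vals), tolerance = 1e-10)
    expect_equal(ms$sd[ch], sqrt(mean((vals - mean(vals))^2)),
                 tolerance = 1e-10)
  }
  expect_identical(ms$n_pixels, sum(grid))
})

test_that("masked mean: identity mask, constant cube, and exclusion identity", {
  wn <- seq(1000, 1032, by = 8)
  s <- gauss(wn, 1016, 0.5, 10)
  cube <- uniform_cube(s, wn, 4, 4)

  ms <- masked_mean_spectrum(cube)
  expect_equal(ms$mean, s)
  expect_equal(ms$sd, rep(0, length(wn)))

  all_true <- pixel_mask(matrix(TRUE, 4, 4))
  expect_equal(masked_mean_spectrum(cube, all_true)$mean,
               masked_mean_spectrum(cube)$mean)

  # excluding one pixel shifts the mean by (mean - s_excl) / n_retained
  set.seed(7)
  m <- matrix(rnorm(16 * length(wn)), 16, length(wn))
  rcube <- make_cube(m, wn, 4, 4)
  full <- masked_mean_spectrum(rcube)$mean
  grid <- matrix(TRUE, 4, 4); grid[2, 3] <- FALSE
  part <- masked_mean_spectrum(rcube, pixel_mask(grid))$mean
  s_excl <- rcube$data[2, 3, ]
  expect_equal(part, full + (full - s_excl) / 15, tolerance = 1e-12)

  # fewer than 2 retained pixels is degenerate
  g1 <- matrix(FALSE, 4, 4); g1[1, 1] <- TRUE
  expect_error(masked_mean_spectrum(rcube, pixel_mask(g1)), "degenerate")
})

test_that("NaN (dead) pixels are excluded from channel statistics", {
  wn <- seq(1000, 1032, by = 8)
  s <- rep(2, length(wn))
  cube <- uniform_cube(s, wn, 3, 3)
  cube$data[2, 2, ] <- NaN
  ms <- masked_mean_spectrum(cube)
  expect_equal(ms$mean, s)
  expect_equal(ms$sd, rep(0, length(wn)))
  expect_true(all(ms$n_finite == 8))
})

test_that("cube text container round-trips, including NaN and metadata", {
  set.seed(3)
  wn <- seq(1000, 1032, by = 8)
  m <- matrix(rnorm(12 * length(wn)), 12, length(wn))
  m[5, ] <- NaN
  cube <- make_cube(m, wn, 3, 4, pitch = 2.7)
  cube$metadata$plan <- "none+none"
  path <- withr::local_tempfile(fileext = ".txt")
  write_cube(cube, path)
  back <- read_cube(path)
  expect_equal(back$data, cube$data)
  expect_equal(back$wavenumber, cube$wavenumber)
  expect_equal(back$pixel_pitch, 2.7)
  expect_equal(back$metadata$plan, "none+none")
})

test_that("descending-axis containers are flipped to ascending on read", {
  wn <- seq(1000, 1032, by = 8)
  m <- matrix(seq_len(6 * length(wn)) * 0.1, 6, length(wn))
  cube <- make_cube(m, wn, 2, 3)
  path <- withr::local_tempfile(fileext = ".txt")
  write_cube(cube, path)
  # rewrite the container with a descending axis by editing the text
  lines <- readLines(path)
  lines[2] <- paste(rev(wn), collapse = ",")
  body <- do.call(rbind, lapply(strsplit(lines[-(1:2)], ","), as.numeric))
  body <- body[, rev(seq_len(ncol(body)))]
  writeLines(c(lines[1:2], apply(body, 1, paste, collapse = ",")), path)
  back <- read_cube(path)
  expect_equal(back$data, cube$data)
  expect_equal(back$wavenumber, wn)
  expect_true(isTRUE(back$metadata$axis_flipped))
})

test_that("spectrum CSV export has the documented columns", {
  wn <- seq(1000, 1032, by = 8)
  cube <- uniform_cube(gauss(wn, 1016, 1, 8), wn, 3, 3)
  ms <- masked_mean_spectrum(cube)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum_csv(ms, path)
  df <- utils::read.csv(path, check.names = FALSE)
  expect_identical(names(df), c("wavenumber_cm-1", "absorbance", "sd"))
  expect_equal(df$absorbance, ms$mean)
})
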