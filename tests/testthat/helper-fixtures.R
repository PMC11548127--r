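# Fixtures are built in code; no binary data ships with the package.

gauss <- function(wn, center, height, sigma) {
  height * exp(-0.5 * ((wn - center) / sigma)^2)
}

# Build a cube from a pixels x channels matrix (column-major pixel order).
make_cube <- function(m, wn, rows, cols, pitch = NA_real_) {
  spectral_cube(array(m, dim = c(rows, cols, length(wn))), wn,
                pixel_pitch = pitch)
}

# Every pixel carries the same spectrum.
uniform_cube <- function(spectrum, wn, rows = 4L, cols = 4L) {
  make_cube(matrix(spectrum, rows * cols, length(spectrum), byrow = TRUE),
            wn, rows, cols)
}

# Small, fast simulator config for unit tests.
quick_cfg <- function(...) {
  default_sc_config(rows = 16L, cols = 16L, ...)
}
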