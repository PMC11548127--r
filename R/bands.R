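# Band intensity/integral extraction, band ratios and chemical mapping.

# Channel indices inside a band's peak window; peak_window = 0 degenerates
# to the single nearest channel.
band_window_channels <- function(wavenumber, band) {
  stopifnot(inherits(band, "band_def"))
  if (band$center < min(wavenumber) || band$center > max(wavenumber)) {
    stop(sprintf("band center %.6g cm^-1 outside axis range", band$center))
  }
  if (band$peak_window == 0) {
    return(nearest_channel(wavenumber, band$center))
  }
  idx <- which(abs(wavenumber - band$center) <= band$peak_window)
  if (length(idx) == 0L) idx <- nearest_channel(wavenumber, band$center)
  idx
}

# Row-wise maximum of a matrix ignoring NaN; all-NaN rows give NA.
row_max_finite <- function(m) {
  do.call(pmax, c(lapply(seq_len(ncol(m)), function(j) m[, j]),
                  list(na.rm = TRUE)))
}

# Trapezoidal quadrature weights for an ordered abscissa.
trapz_weights <- function(x) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 channels for integration")
  w <- numeric(n)
  dx <- diff(x)
  w[1] <- dx[1] / 2
  w[n] <- dx[n - 1] / 2
  if (n > 2L) w[2:(n - 1)] <- (dx[-(n - 1)] + dx[-1]) / 2
  w
}

#' Peak intensity of a band
#'
#' Maximum absorbance over the channels within `peak_window` of the band
#' centre; with `peak_window = 0` the value at the nearest channel. Returns
#' `NA` when the window holds no finite value (invalid pixel).
#'
#' @param spectrum numeric absorbance vector.
#' @param wavenumber ascending axis matching `spectrum`.
#' @param band a [band_def()].
#' @return peak absorbance (scalar).
#' @export
band_intensity <- function(spectrum, wavenumber, band) {
  stopifnot(length(spectrum) == length(wavenumber))
  idx <- band_window_channels(wavenumber, band)
  v <- spectrum[idx]
  v <- v[is.finite(v)]
  if (length(v) == 0L) return(NA_real_)
  max(v)
}

#' Trapezoidal band integral
#'
#' Integrates the absorbance over the band's `integral_range` with the
#' trapezoidal rule on the stored channels; no local baseline is
#' subtracted. Returns `NA` if any channel in the range is non-finite.
#'
#' @inheritParams band_intensity
#' @return integrated absorbance in absorbance * cm^-1.
#' @export
band_integral <- function(spectrum, wavenumber, band) {
  stopifnot(inherits(band, "band_def"),
            length(spectrum) == length(wavenumber))
  lo <- band$integral_range[1]; hi <- band$integral_range[2]
  if (lo < min(wavenumber) || hi > max(wavenumber)) {
    stop("integral_range extends beyond the wavenumber axis")
  }
  idx <- which(wavenumber >= lo & wavenumber <= hi)
  if (length(idx) < 2L) stop("integral_range covers fewer than 2 channels")
  sum(spectrum[idx] * trapz_weights(wavenumber[idx]))
}

#' Ratio of two band intensities
#'
#' @inheritParams band_intensity
#' @param numerator,denominator [band_def()] objects.
#' @return dimensionless intensity ratio; `NA` when either intensity is
#'   unavailable or the denominator is zero.
#' @export
band_ratio <- function(spectrum, wavenumber, numerator, denominator) {
  num <- band_intensity(spectrum, wavenumber, numerator)
  den <- band_intensity(spectrum, wavenumber, denominator)
  if (!is.finite(num) || !is.finite(den) || den == 0) return(NA_real_)
  num / den
}

#' Chemical map of a cube
#'
#' Reduces each pixel spectrum to one scalar: a band peak intensity, a band
#' integral, or the total sum of absorbance over all channels (`mode =
#' "total"`, which ignores `band`). Invalid (dead) pixels map to `NA`/`NaN`.
#'
#' @param cube a [spectral_cube()].
#' @param band a [band_def()]; required for modes `"intensity"` and
#'   `"integral"`.
#' @param mode `"intensity"`, `"integral"` or `"total"`.
#' @return numeric matrix with the cube's spatial shape.
#' @export
chemical_map <- function(cube, band = NULL,
                         mode = c("intensity", "integral", "total")) {
  stopifnot(inherits(cube, "spectral_cube"))
  mode <- match.arg(mode)
  m <- cube_matrix(cube)
  d <- dim(cube$data)
  vals <- switch(mode,
    total = rowSums(m),
    intensity = {
      stopifnot(inherits(band, "band_def"))
      idx <- band_window_channels(cube$wavenumber, band)
      row_max_finite(m[, idx, drop = FALSE])
    },
    integral = {
      stopifnot(inherits(band, "band_def"))
      lo <- band$integral_range[1]; hi <- band$integral_range[2]
      if (lo < min(cube$wavenumber) || hi > max(cube$wavenumber)) {
        stop("integral_range extends beyond the wavenumber axis")
      }
      idx <- which(cube$wavenumber >= lo & cube$wavenumber <= hi)
      if (length(idx) < 2L) stop("integral_range covers fewer than 2 channels")
      as.vector(m[, idx, drop = FALSE] %*% trapz_weights(cube$wavenumber[idx]))
    }
  )
  matrix(vals, d[1], d[2])
}
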