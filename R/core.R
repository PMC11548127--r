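# Core domain types and shared statistics for FTIR hyperspectral cubes.
#
# Conventions fixed here and relied on everywhere else:
#  * spatial indexing is (row, col), row 1 at the top of the image;
#  * the wavenumber axis is stored strictly ascending (cm^-1);
#  * dead detector pixels carry NaN absorbance at every channel and are
#    implicitly excluded from all statistics;
#  * standard deviations over a map are population SDs (divide by n) --
#    a map is treated as the full population of the imaged region.

#' Convert percent transmittance to absorbance
#'
#' Absorbance is defined as `2 - log10(%T)`, i.e. `-log10(T)` with the
#' transmittance expressed as a fraction. 10% transmittance corresponds to
#' 1.0 absorbance unit and 1% transmittance to 2.0 absorbance units.
#'
#' @param percent_t numeric vector of percent transmittance values, must be
#'   strictly positive.
#' @return numeric vector of absorbance values.
#' @seealso [transmittance_from_absorbance()]
#' @export
#' @examples
#' absorbance_from_transmittance(c(100, 10, 1))
absorbance_from_transmittance <- function(percent_t) {
  if (!is.numeric(percent_t)) {
    stop("'percent_t' must be numeric")
  }
  if (any(!is.finite(percent_t)) || any(percent_t <= 0)) {
    stop("transmittance must be finite and strictly positive")
  }
  2 - log10(percent_t)
}

#' Convert absorbance to percent transmittance
#'
#' Exact inverse of [absorbance_from_transmittance()].
#'
#' @param absorbance numeric vector of absorbance values.
#' @return numeric vector of percent transmittance values.
#' @export
transmittance_from_absorbance <- function(absorbance) {
  if (!is.numeric(absorbance)) {
    stop("'absorbance' must be numeric")
  }
  10^(2 - absorbance)
}

# Validates a wavenumber axis: numeric, length >= 2, strictly increasing.
validate_axis <- function(wavenumber) {
  if (!is.numeric(wavenumber) || length(wavenumber) < 2) {
    stop("wavenumber axis must be numeric with at least 2 channels")
  }
  if (any(!is.finite(wavenumber))) {
    stop("wavenumber axis must be finite")
  }
  if (any(diff(wavenumber) <= 0)) {
    stop("wavenumber axis must be strictly increasing")
  }
  invisible(as.numeric(wavenumber))
}

#' Nominal channel spacing of a wavenumber axis
#'
#' @param wavenumber ascending numeric wavenumber axis (cm^-1).
#' @return median channel step in cm^-1.
#' @export
axis_spacing <- function(wavenumber) {
  validate_axis(wavenumber)
  stats::median(diff(wavenumber))
}

#' Construct a hyperspectral absorbance cube
#'
#' A `spectral_cube` holds absorbance values on an `rows x cols x channels`
#' grid together with its wavenumber axis and the detector pixel pitch.
#' Dead pixels are represented by NaN at all channels.
#'
#' @param data 3-d numeric array indexed `[row, col, channel]`.
#' @param wavenumber ascending numeric axis (cm^-1), length equal to
#'   `dim(data)[3]`.
#' @param pixel_pitch physical pixel side length in micrometres (default
#'   `NA`, unknown).
#' @param metadata named list of free-form provenance entries.
#' @return object of class `spectral_cube`.
#' @export
spectral_cube <- function(data, wavenumber, pixel_pitch = NA_real_,
                          metadata = list()) {
  if (!is.array(data) || length(dim(data)) != 3) {
    stop("'data' must be a 3-d array [row, col, channel]")
  }
  validate_axis(wavenumber)
  if (dim(data)[3] != length(wavenumber)) {
    stop("number of channels in 'data' must equal length of 'wavenumber'")
  }
  if (!is.list(metadata)) {
    stop("'metadata' must be a list")
  }
  structure(
    list(
      data = data,
      wavenumber = as.numeric(wavenumber),
      pixel_pitch = as.numeric(pixel_pitch),
      metadata = metadata
    ),
    class = "spectral_cube"
  )
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<spectral_cube> %d x %d pixels, %d channels (%.1f-%.1f cm^-1)\n",
    d[1], d[2], d[3], min(x$wavenumber), max(x$wavenumber)
  ))
  if (is.finite(x$pixel_pitch)) {
    fov <- cube_fov(x)
    cat(sprintf("  pixel pitch %.2f um, field of view %.1f x %.1f um\n",
                x$pixel_pitch, fov[["width"]], fov[["height"]]))
  }
  nd <- sum(!is.finite(x$data[, , 1]))
  if (nd > 0) cat(sprintf("  %d non-finite pixels at channel 1\n", nd))
  invisible(x)
}

cube_dims <- function(cube) dim(cube$data)

n_pixels <- function(cube) prod(dim(cube$data)[1:2])

# Flatten to a pixels x channels matrix. Pixels are in column-major order:
# p = row + (col - 1) * rows, so matrix()/array() round-trip exactly.
cube_matrix <- function(cube) {
  d <- dim(cube$data)
  matrix(cube$data, nrow = d[1] * d[2], ncol = d[3])
}

matrix_to_cube <- function(m, template, metadata = template$metadata) {
  d <- dim(template$data)
  spectral_cube(array(m, dim = d), template$wavenumber,
                pixel_pitch = template$pixel_pitch, metadata = metadata)
}

# Index helpers for the flattened pixel order used by cube_matrix().
pixel_row <- function(p, rows) ((p - 1L) %% rows) + 1L
pixel_col <- function(p, rows) ((p - 1L) %/% rows) + 1L

#' Field of view covered by a cube
#'
#' @param cube a [spectral_cube()].
#' @return named vector `c(width, height)` in micrometres
#'   (`cols * pixel_pitch`, `rows * pixel_pitch`).
#' @export
cube_fov <- function(cube) {
  stopifnot(inherits(cube, "spectral_cube"))
  if (!is.finite(cube$pixel_pitch)) {
    stop("cube has no pixel pitch")
  }
  d <- dim(cube$data)
  c(width = d[2] * cube$pixel_pitch, height = d[1] * cube$pixel_pitch)
}

#' Index of the channel nearest to a target wavenumber
#'
#' Ties (a target exactly halfway between two channels) are broken toward the
#' lower wavenumber.
#'
#' @param wavenumber ascending numeric axis (cm^-1).
#' @param target wavenumber to locate (cm^-1); must lie within the axis range
#'   extended by one nominal channel spacing.
#' @return integer channel index.
#' @export
nearest_channel <- function(wavenumber, target) {
  validate_axis(wavenumber)
  stopifnot(is.numeric(target), length(target) == 1L, is.finite(target))
  sp <- axis_spacing(wavenumber)
  if (target < min(wavenumber) - sp || target > max(wavenumber) + sp) {
    stop(sprintf("target %.6g cm^-1 outside axis range [%.6g, %.6g]",
                 target, min(wavenumber), max(wavenumber)))
  }
  # which.min() returns the first minimum; the axis is ascending, so the
  # first of two equidistant channels is the lower wavenumber.
  which.min(abs(wavenumber - target))
}

#' Construct a boolean inlier mask aligned to a cube
#'
#' @param grid logical matrix, `TRUE` marks a retained (inlier) pixel.
#' @param provenance character description of the filter that produced it.
#' @return object of class `pixel_mask`.
#' @export
pixel_mask <- function(grid, provenance = "") {
  if (!is.matrix(grid) || !is.logical(grid)) {
    stop("'grid' must be a logical matrix")
  }
  if (anyNA(grid)) stop("'grid' must not contain NA")
  structure(list(grid = grid, provenance = as.character(provenance)[1]),
            class = "pixel_mask")
}

#' @export
print.pixel_mask <- function(x, ...) {
  cat(sprintf("<pixel_mask> %d x %d, retention %.4f",
              nrow(x$grid), ncol(x$grid), retention(x)))
  if (nzchar(x$provenance)) cat(" [", x$provenance, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Retention fraction of a mask
#'
#' @param mask a [pixel_mask()].
#' @return fraction of pixels retained, in `[0, 1]`.
#' @export
retention <- function(mask) {
  stopifnot(inherits(mask, "pixel_mask"))
  mean(mask$grid)
}

check_mask_cube <- function(mask, cube) {
  d <- dim(cube$data)
  if (!all(dim(mask$grid) == d[1:2])) {
    stop("mask shape does not match cube spatial shape")
  }
  invisible(TRUE)
}

#' Masked mean spectrum and channel-wise dispersion
#'
#' Channel-wise arithmetic mean and population standard deviation over the
#' retained pixels of a cube. Non-finite values (dead pixels) are excluded
#' channel by channel.
#'
#' @param cube a [spectral_cube()].
#' @param mask optional [pixel_mask()]; `NULL` retains every pixel.
#' @return object of class `mean_spectrum`: a list with `wavenumber`, `mean`,
#'   `sd` (population SD), `n_pixels` (retained pixels) and `n_finite`
#'   (finite observations per channel).
#' @export
masked_mean_spectrum <- function(cube, mask = NULL) {
  stopifnot(inherits(cube, "spectral_cube"))
  m <- cube_matrix(cube)
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "pixel_mask"))
    check_mask_cube(mask, cube)
    m <- m[as.vector(mask$grid), , drop = FALSE]
  }
  if (nrow(m) < 2) {
    stop("degenerate mask: fewer than 2 retained pixels")
  }
  fin <- is.finite(m)
  m0 <- m
  m0[!fin] <- 0
  n <- colSums(fin)
  mu <- ifelse(n > 0, colSums(m0) / n, NA_real_)
  msq <- ifelse(n > 0, colSums(m0^2) / n, NA_real_)
  sdv <- sqrt(pmax(msq - mu^2, 0))
  structure(
    list(wavenumber = cube$wavenumber, mean = mu, sd = sdv,
         n_pixels = nrow(m), n_finite = n),
    class = "mean_spectrum"
  )
}

#' @export
print.mean_spectrum <- function(x, ...) {
  cat(sprintf(
    "<mean_spectrum> %d channels, %d pixels; mean absorbance %.4g\n",
    length(x$mean), x$n_pixels, mean(x$mean, na.rm = TRUE)
  ))
  invisible(x)
}

#' Define a spectral band
#'
#' @param name band label (e.g. `"amide1"`).
#' @param center band centre in cm^-1.
#' @param peak_window half-width in cm^-1 of the window used for peak
#'   intensity lookup; `0` means "value at the nearest channel". The default
#'   of 8 cm^-1 is one nominal resolution element, so the local-maximum
#'   lookup tolerates small peak shifts.
#' @param integral_range length-2 numeric `c(lo, hi)` in cm^-1 used by
#'   [band_integral()]; defaults to `center +/- 50` cm^-1.
#' @return object of class `band_def`.
#' @export
band_def <- function(name, center, peak_window = 8, integral_range = NULL) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(center), length(center) == 1L, is.finite(center),
            is.numeric(peak_window), peak_window >= 0)
  if (is.null(integral_range)) {
    integral_range <- c(center - 50, center + 50)
  }
  stopifnot(length(integral_range) == 2L)
  integral_range <- as.numeric(integral_range)
  if (!(integral_range[1] < center && center < integral_range[2])) {
    stop("integral_range must bracket the band center")
  }
  structure(
    list(name = name, center = center, peak_window = peak_window,
         integral_range = integral_range),
    class = "band_def"
  )
}

#' @export
print.band_def <- function(x, ...) {
  cat(sprintf("<band_def> %s: %.0f cm^-1 (window +/-%.0f, integral %.0f-%.0f)\n",
              x$name, x$center, x$peak_window,
              x$integral_range[1], x$integral_range[2]))
  invisible(x)
}

#' Default stratum-corneum band table
#'
#' The four bands conventionally used to track SC state: Amide II
#' (1548 cm^-1) and Amide I (1652 cm^-1) for the keratin backbone, and the
#' CH2 symmetric (2850 cm^-1) and asymmetric (2920 cm^-1) stretches for the
#' lipid alkyl chains. Integration windows are the conventional ones
#' (1500-1590, 1600-1700, 2830-2870 and 2890-2950 cm^-1).
#'
#' @return named list of [band_def()] objects
#'   (`amide2`, `amide1`, `ch2_sym`, `ch2_asym`).
#' @export
default_bands <- function() {
  list(
    amide2   = band_def("amide2",   1548, 8, c(1500, 1590)),
    amide1   = band_def("amide1",   1652, 8, c(1600, 1700)),
    ch2_sym  = band_def("ch2_sym",  2850, 8, c(2830, 2870)),
    ch2_asym = band_def("ch2_asym", 2920, 8, c(2890, 2950))
  )
}
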