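# Outlier-pixel removal: Tukey-fence histogram thresholding on band
# intensity maps, and PCA score-distance filtering on full spectra.
# Dead (all-NaN) pixels are automatic outliers under both protocols.

#' Tukey fences of a sample
#'
#' Returns `[Q1 - k * IQR, Q3 + k * IQR]`; observations inside the closed
#' interval are inliers. Quartiles use the linear-interpolation convention
#' (R's default quantile type 7), fixed here for reproducibility.
#'
#' @param values numeric sample (non-finite values are dropped); at least 4
#'   finite values are required.
#' @param k non-negative fence multiplier; 1.5 flags Tukey's "outliers",
#'   3 his "far out" points, 0 degenerates to `(Q1, Q3)`.
#' @return named numeric vector `c(lo, hi)`.
#' @export
tukey_fences <- function(values, k = 1.5) {
  stopifnot(is.numeric(values), is.numeric(k), length(k) == 1L, k >= 0)
  v <- values[is.finite(values)]
  if (length(v) < 4L) {
    stop("insufficient data: need at least 4 finite values")
  }
  q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  c(lo = q[1] - k * iqr, hi = q[2] + k * iqr)
}

#' Freedman-Diaconis histogram bin width
#'
#' `h = 2 * IQR * n^(-1/3)`. Either pass a sample in `values`, or supply
#' `iqr` and `n` directly. A zero IQR yields `Inf` (the "use a single bin"
#' fallback) with a warning.
#'
#' @param values numeric sample; non-finite values are dropped.
#' @param iqr,n optional explicit interquartile range and observation
#'   count, overriding `values`.
#' @return bin width, same units as the data.
#' @export
fd_bin_width <- function(values = NULL, iqr = NULL, n = NULL) {
  if (is.null(iqr) || is.null(n)) {
    stopifnot(is.numeric(values))
    v <- values[is.finite(values)]
    if (length(v) < 1L) stop("no finite values")
    if (is.null(n)) n <- length(v)
    if (is.null(iqr)) {
      q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
      iqr <- q[2] - q[1]
    }
  }
  stopifnot(iqr >= 0, n >= 1)
  if (iqr == 0) {
    warning("zero IQR: falling back to a single histogram bin")
    return(Inf)
  }
  2 * iqr * n^(-1 / 3)
}

# Histogram summary (FD binning) of one band map, for reporting.
band_histogram <- function(v) {
  v <- v[is.finite(v)]
  h <- fd_bin_width(v)
  if (!is.finite(h)) {
    return(list(bin_width = h, breaks = range(v), counts = length(v)))
  }
  breaks <- seq(min(v), max(v) + h, by = h)
  list(bin_width = h, breaks = breaks,
       counts = tabulate(findInterval(v, breaks, rightmost.closed = TRUE),
                         nbins = length(breaks) - 1L))
}

#' Histogram (Tukey-fence) outlier removal
#'
#' For each requested band, the per-pixel peak intensity distribution is
#' thresholded with Tukey fences at multiplier `k`; per-band outlier sets
#' are then combined by union (a pixel outlying in any band is removed,
#' the default) or intersection. Dead pixels are automatic outliers. The
#' returned mask carries an attribute `"details"` with the per-band fences,
#' medians, IQRs and Freedman-Diaconis histograms.
#'
#' @param cube a [spectral_cube()].
#' @param bands list of [band_def()]; defaults to the three prominent SC
#'   peaks used for histogram screening (Amide II 1548, Amide I 1652 and
#'   CH2 asymmetric 2920 cm^-1).
#' @param k fence multiplier (see [tukey_fences()]).
#' @param combine `"union"` or `"intersection"` of per-band outlier sets.
#' @param maps optional named list of precomputed intensity maps (matrices)
#'   matching `bands`, e.g. maps computed on plan-processed data.
#' @return a [pixel_mask()] (`TRUE` = inlier).
#' @export
histogram_outliers <- function(cube, bands = fence_bands(), k = 1.5,
                               combine = c("union", "intersection"),
                               maps = NULL) {
  stopifnot(inherits(cube, "spectral_cube"))
  combine <- match.arg(combine)
  if (length(bands) < 1L) stop("need at least one band")
  if (inherits(bands, "band_def")) bands <- list(bands)
  if (is.null(maps)) {
    maps <- lapply(bands, function(b) chemical_map(cube, b, "intensity"))
  }
  stopifnot(length(maps) == length(bands))

  d <- dim(cube$data)
  out_comb <- NULL
  details <- list()
  for (i in seq_along(bands)) {
    b <- bands[[i]]
    v <- maps[[i]]
    stopifnot(all(dim(v) == d[1:2]))
    fin <- is.finite(v)
    out_b <- !fin                       # dead / invalid: auto-outlier
    if (sum(fin) < 4L) {
      warning(sprintf("band %s: fewer than 4 finite values; no fence applied",
                      b$name))
    } else {
      f <- tukey_fences(v[fin], k)
      out_b[fin] <- v[fin] < f[["lo"]] | v[fin] > f[["hi"]]
      vf <- v[fin]
      q <- stats::quantile(vf, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      details[[b$name]] <- list(
        fences = f, median = q[2], iqr = q[3] - q[1],
        histogram = suppressWarnings(band_histogram(vf)),
        n_outliers = sum(out_b)
      )
    }
    out_comb <- if (is.null(out_comb)) {
      out_b
    } else if (combine == "union") {
      out_comb | out_b
    } else {
      (out_comb & out_b) | !fin         # dead pixels stay out either way
    }
  }
  mask <- pixel_mask(!out_comb,
                     provenance = sprintf(
                       "histogram k=%g combine=%s bands=%s", k, combine,
                       paste(vapply(bands, `[[`, "", "name"), collapse = ",")))
  attr(mask, "details") <- c(list(k = k, combine = combine), details)
  mask
}

#' Bands used for histogram outlier screening
#'
#' The three prominent SC peaks: Amide II (1548), Amide I (1652) and the
#' CH2 asymmetric stretch (2920 cm^-1).
#'
#' @return list of [band_def()] objects.
#' @export
fence_bands <- function() {
  b <- default_bands()
  list(b$amide2, b$amide1, b$ch2_asym)
}

#' PCA score-distance outlier removal
#'
#' Pixel spectra are decomposed by PCA (channels optionally standardized to
#' zero mean / unit variance so every wavenumber counts equally); for each
#' pixel the Euclidean distance `d_i` of its first `n_components` scores
#' from the component-wise median score is computed, and pixels with
#' `d_i > threshold_c * median(d)` are flagged as outliers. Zero-variance
#' channels are dropped from the decomposition with a notice; dead pixels
#' are automatic outliers.
#'
#' @param cube a [spectral_cube()].
#' @param n_components number of retained components (default 2).
#' @param threshold_c distance threshold as a multiple of the median score
#'   distance (default 3).
#' @param scale_channels standardize each channel before the decomposition
#'   (default `TRUE`).
#' @return list with `mask` (a [pixel_mask()]) and `scores`, a data.frame
#'   with pixel coordinates, the retained PC scores, the distance `dist`
#'   and the `outlier` flag, suitable for score plots.
#' @export
pca_outliers <- function(cube, n_components = 2L, threshold_c = 3,
                         scale_channels = TRUE) {
  stopifnot(inherits(cube, "spectral_cube"),
            n_components >= 1, threshold_c > 0)
  m <- cube_matrix(cube)
  d <- dim(cube$data)
  valid <- rowSums(!is.finite(m)) == 0L
  x <- m[valid, , drop = FALSE]
  if (nrow(x) < n_components + 1) {
    stop("insufficient valid pixels for the requested number of components")
  }
  cv <- colMeans(x^2) - colMeans(x)^2
  keep <- cv > 0
  if (any(!keep)) {
    message(sum(!keep), " zero-variance channel(s) dropped from the PCA")
  }
  if (any(keep)) {
    pr <- stats::prcomp(x[, keep, drop = FALSE], center = TRUE,
                        scale. = scale_channels)
    nc <- min(n_components, ncol(pr$x))
    s <- pr$x[, seq_len(nc), drop = FALSE]
  } else {
    # all spectra identical: zero scores, no outliers
    nc <- n_components
    s <- matrix(0, nrow(x), nc)
  }
  med <- apply(s, 2L, stats::median)
  dist <- sqrt(rowSums(sweep(s, 2L, med)^2))
  thr <- threshold_c * stats::median(dist)
  # absolute floor guards against BLAS rounding jitter when spectra are
  # exactly degenerate (identical pixels => distances should be zero)
  out_valid <- dist > pmax(thr, 1e-8 * max(dist))

  grid <- matrix(FALSE, d[1], d[2])
  grid[which(valid)[!out_valid]] <- TRUE
  mask <- pixel_mask(grid, provenance = sprintf(
    "pca n_components=%d threshold_c=%g scale=%s",
    n_components, threshold_c, scale_channels))

  p <- which(valid)
  scores <- data.frame(row = pixel_row(p, d[1]), col = pixel_col(p, d[1]))
  for (j in seq_len(ncol(s))) scores[[paste0("PC", j)]] <- s[, j]
  scores$dist <- dist
  scores$outlier <- out_valid
  list(mask = mask, scores = scores)
}

#' Specification of an outlier filter
#'
#' A light-weight description of a filter so grids of methods can be
#' compared; see [apply_filter()] and [compare_methods()].
#'
#' @param method `"none"`, `"histogram"` or `"pca"`.
#' @param ... parameters forwarded to [histogram_outliers()] or
#'   [pca_outliers()].
#' @param label optional custom label.
#' @return object of class `filter_spec`.
#' @export
filter_spec <- function(method = c("none", "histogram", "pca"), ...,
                        label = NULL) {
  method <- match.arg(method)
  args <- list(...)
  if (is.null(label)) {
    label <- switch(method,
      none = "none",
      histogram = sprintf("hist_k%g", if (is.null(args$k)) 1.5 else args$k),
      pca = sprintf("pca_c%g", if (is.null(args$threshold_c)) 3
                               else args$threshold_c)
    )
  }
  structure(list(method = method, args = args, label = label),
            class = "filter_spec")
}

#' Apply an outlier filter specification to a cube
#'
#' @param cube a [spectral_cube()].
#' @param spec a [filter_spec()].
#' @return a [pixel_mask()].
#' @export
apply_filter <- function(cube, spec) {
  stopifnot(inherits(cube, "spectral_cube"), inherits(spec, "filter_spec"))
  switch(spec$method,
    none = pixel_mask(matrix(TRUE, dim(cube$data)[1], dim(cube$data)[2]),
                      provenance = "none"),
    histogram = do.call(histogram_outliers, c(list(cube = cube), spec$args)),
    pca = do.call(pca_outliers, c(list(cube = cube), spec$args))$mask
  )
}
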