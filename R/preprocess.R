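# Per-spectrum baseline correction and normalization, composable into the
# six standard pre-processing scenarios (baseline on/off x {none, Amide II,
# area} normalization).

#' Describe a pre-processing plan
#'
#' A plan is the combination of a baseline step and a normalization step.
#' When both are requested the baseline is corrected first and the
#' normalization then uses the corrected intensities.
#'
#' @param baseline `"none"` or `"poly"` (iterative polynomial subtraction,
#'   see [baseline_correct()]).
#' @param normalization `"none"`, `"amide2"` (divide each spectrum by its
#'   Amide II peak intensity) or `"area"` (divide each spectrum by its mean
#'   value over the entire stored spectral range, silent regions included).
#' @param order,max_iter,tol parameters of the iterative polynomial fit.
#' @param amide2_band [band_def()] used by the `"amide2"` normalization.
#' @return object of class `preprocess_plan`.
#' @export
preprocess_plan <- function(baseline = c("none", "poly"),
                            normalization = c("none", "amide2", "area"),
                            order = 2L, max_iter = 100L, tol = 1e-3,
                            amide2_band = default_bands()$amide2) {
  baseline <- match.arg(baseline)
  normalization <- match.arg(normalization)
  stopifnot(order >= 0, max_iter >= 1, tol > 0,
            inherits(amide2_band, "band_def"))
  structure(
    list(baseline = baseline, normalization = normalization,
         order = as.integer(order), max_iter = as.integer(max_iter),
         tol = tol, amide2_band = amide2_band),
    class = "preprocess_plan"
  )
}

#' @export
print.preprocess_plan <- function(x, ...) {
  cat("<preprocess_plan>", plan_label(x), "\n")
  invisible(x)
}

#' Label of a pre-processing plan
#'
#' @param plan a [preprocess_plan()].
#' @return character label such as `"poly2+area"` or `"none+none"`.
#' @export
plan_label <- function(plan) {
  stopifnot(inherits(plan, "preprocess_plan"))
  bl <- if (plan$baseline == "poly") paste0("poly", plan$order) else "none"
  paste0(bl, "+", plan$normalization)
}

#' The six standard pre-processing scenarios
#'
#' Baseline correction on/off crossed with the three normalization options.
#'
#' @param order polynomial order for the baseline variants.
#' @return named list of six [preprocess_plan()] objects.
#' @export
standard_plans <- function(order = 2L) {
  list(
    raw             = preprocess_plan("none", "none"),
    area            = preprocess_plan("none", "area"),
    amide2          = preprocess_plan("none", "amide2"),
    baseline        = preprocess_plan("poly", "none", order = order),
    baseline_area   = preprocess_plan("poly", "area", order = order),
    baseline_amide2 = preprocess_plan("poly", "amide2", order = order)
  )
}

# Iterative polynomial ("modified polyfit") baseline estimation on a matrix
# of fully finite spectra (rows = spectra). Each iteration least-squares
# fits a degree-`order` polynomial, clips the working spectrum to the fit
# from above, and refits; a spectrum converges when the maximum change of
# its fit falls below tol * range(original spectrum). Converged rows are
# frozen so the matrix path is exactly the single-spectrum path.
baseline_fit_matrix <- function(y, x, order, max_iter, tol) {
  xd <- outer(x, 0:order, `^`)
  p <- solve(crossprod(xd), t(xd))            # (order+1) x nchan
  tp <- t(p); txd <- t(xd)
  rng <- apply(y, 1L, function(r) diff(range(r)))
  thr <- tol * pmax(rng, .Machine$double.eps)
  fit <- (y %*% tp) %*% txd
  yw <- y
  active <- seq_len(nrow(y))
  for (it in seq_len(max_iter)) {
    if (length(active) == 0L) break
    yw[active, ] <- pmin(yw[active, , drop = FALSE],
                         fit[active, , drop = FALSE])
    newfit <- (yw[active, , drop = FALSE] %*% tp) %*% txd
    delta <- apply(abs(newfit - fit[active, , drop = FALSE]), 1L, max)
    fit[active, ] <- newfit
    active <- active[delta >= thr[active]]
  }
  fit
}

#' Iterative polynomial baseline correction of one spectrum
#'
#' Modified-polyfit scheme: fit a polynomial of the given order to the
#' spectrum, replace values above the fit by the fit, refit, and stop when
#' the fit changes by less than `tol` times the input range (or after
#' `max_iter` refits). The final fit is subtracted. Non-finite channels are
#' excluded from the fit and passed through unchanged. Negative values in
#' the corrected spectrum are not clipped.
#'
#' @param spectrum numeric absorbance vector.
#' @param order polynomial order (default 2).
#' @param max_iter maximum number of refits.
#' @param tol convergence tolerance, relative to the spectrum range.
#' @param x optional abscissa (e.g. the wavenumber axis); defaults to an
#'   equally spaced grid on `[-1, 1]`.
#' @return baseline-corrected spectrum, same length as the input.
#' @export
baseline_correct <- function(spectrum, order = 2L, max_iter = 100L,
                             tol = 1e-3, x = NULL) {
  stopifnot(is.numeric(spectrum), order >= 0, max_iter >= 1, tol > 0)
  fin <- is.finite(spectrum)
  if (!any(fin)) stop("degenerate input: no finite values in spectrum")
  if (sum(fin) <= order + 1) {
    stop("spectrum has too few finite channels for the polynomial order")
  }
  n <- length(spectrum)
  if (is.null(x)) {
    x <- seq(-1, 1, length.out = n)
  } else {
    stopifnot(length(x) == n)
    x <- 2 * (x - min(x)) / (max(x) - min(x)) - 1
  }
  out <- spectrum
  fit <- baseline_fit_matrix(matrix(spectrum[fin], nrow = 1L), x[fin],
                             order, max_iter, tol)[1L, ]
  out[fin] <- spectrum[fin] - fit
  out
}

#' Area normalization of a spectrum
#'
#' Divides the spectrum by its mean value over the entire stored spectral
#' range (finite channels only), so the output mean is exactly 1.
#'
#' @param spectrum numeric absorbance vector.
#' @return normalized spectrum.
#' @export
normalize_area <- function(spectrum) {
  stopifnot(is.numeric(spectrum))
  m <- mean(spectrum[is.finite(spectrum)])
  if (!is.finite(m) || m <= 0) {
    stop("normalization error: spectrum mean is not positive")
  }
  spectrum / m
}

#' Amide II normalization of a spectrum
#'
#' Divides the spectrum by its Amide II peak intensity (see
#' [band_intensity()]), so the output Amide II intensity is exactly 1.
#'
#' @param spectrum numeric absorbance vector.
#' @param wavenumber axis matching `spectrum`.
#' @param band the Amide II [band_def()] (default: 1548 cm^-1, window
#'   8 cm^-1).
#' @return normalized spectrum.
#' @export
normalize_amide2 <- function(spectrum, wavenumber,
                             band = default_bands()$amide2) {
  i <- band_intensity(spectrum, wavenumber, band)
  if (!is.finite(i) || i <= 0) {
    stop("normalization error: Amide II intensity is not positive")
  }
  spectrum / i
}

#' Apply a pre-processing plan to every pixel of a cube
#'
#' Baseline correction (if requested) runs first, then normalization.
#' Pixels whose normalization fails (non-positive area mean or Amide II
#' intensity, or a dead all-NaN pixel under a normalizing plan) are marked
#' invalid in the returned mask and their spectra set to NaN rather than
#' silently dropped. The plan label is recorded in the cube metadata.
#'
#' @param cube a [spectral_cube()].
#' @param plan a [preprocess_plan()].
#' @return list with `cube` (processed [spectral_cube()]) and `valid`
#'   (a [pixel_mask()], `TRUE` where the plan applied cleanly).
#' @export
apply_plan <- function(cube, plan) {
  stopifnot(inherits(cube, "spectral_cube"), inherits(plan, "preprocess_plan"))
  m <- cube_matrix(cube)
  d <- dim(cube$data)
  npix <- nrow(m)
  valid <- rep(TRUE, npix)

  n_bad_chan <- rowSums(!is.finite(m))
  all_na <- n_bad_chan == ncol(m)

  if (plan$baseline == "poly") {
    x <- 2 * (cube$wavenumber - min(cube$wavenumber)) /
      (max(cube$wavenumber) - min(cube$wavenumber)) - 1
    full <- which(n_bad_chan == 0L)
    if (length(full) > 0) {
      m[full, ] <- m[full, , drop = FALSE] -
        baseline_fit_matrix(m[full, , drop = FALSE], x, plan$order,
                            plan$max_iter, plan$tol)
    }
    partial <- which(n_bad_chan > 0L & !all_na)
    for (p in partial) {
      m[p, ] <- baseline_correct(m[p, ], order = plan$order,
                                 max_iter = plan$max_iter, tol = plan$tol,
                                 x = cube$wavenumber)
    }
    # dead (all-NaN) pixels pass through untouched
  }

  if (plan$normalization == "area") {
    denom <- rowMeans(m, na.rm = TRUE)
    bad <- !is.finite(denom) | denom <= 0
    valid[bad] <- FALSE
    m[bad, ] <- NaN
    ok <- which(!bad)
    m[ok, ] <- m[ok, , drop = FALSE] / denom[ok]
  } else if (plan$normalization == "amide2") {
    band <- plan$amide2_band
    idx <- band_window_channels(cube$wavenumber, band)
    sub <- m[, idx, drop = FALSE]
    denom <- do.call(pmax, c(lapply(seq_len(ncol(sub)), function(j) sub[, j]),
                             list(na.rm = TRUE)))
    bad <- !is.finite(denom) | denom <= 0
    valid[bad] <- FALSE
    m[bad, ] <- NaN
    ok <- which(!bad)
    m[ok, ] <- m[ok, , drop = FALSE] / denom[ok]
  } else if (any(all_na)) {
    # no normalization: dead pixels remain NaN but are not "errors"
  }

  meta <- cube$metadata
  meta$plan <- plan_label(plan)
  out <- matrix_to_cube(m, cube, metadata = meta)
  list(
    cube = out,
    valid = pixel_mask(matrix(valid, d[1], d[2]),
                       provenance = paste0("apply_plan:", plan_label(plan)))
  )
}
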