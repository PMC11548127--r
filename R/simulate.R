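# Seeded simulator of stratum-corneum-like hyperspectral maps.
#
# The generator emulates the heterogeneity sources seen in FPA transmission
# maps of isolated SC: a smooth multiplicative optical-thickness field, a
# smooth lipid-fraction field, a slowly varying positive per-pixel baseline
# (scattering loss), additive detector noise, hot and dead detector pixels,
# and sebum-like contaminant blobs. All stochastic draws come from one
# Mersenne-Twister stream seeded with the config seed, so identical configs
# give bit-identical cubes.

#' Simulator configuration
#'
#' Defaults describe the measurement geometry of an FPA transmission
#' experiment on stratum corneum: a 128 x 128 detector at 2.7 um pixel
#' pitch, wavenumbers 698-3845 cm^-1 sampled every 4 cm^-1 (8 cm^-1
#' nominal resolution), keratin Amide bands at 1548/1652 cm^-1, lipid CH2
#' bands at 2850/2920 cm^-1 and an ester-carbonyl-bearing sebum contaminant.
#'
#' @param rows,cols spatial pixel counts.
#' @param axis_lo,axis_hi,axis_step wavenumber axis range and step (cm^-1).
#' @param band_table data.frame with columns `component` (one of
#'   `"keratin"`, `"lipid"`, `"contaminant"`), `center` (cm^-1), `height`
#'   (absorbance), `width` (cm^-1; Gaussian sigma or Lorentzian half-width),
#'   `shape` (`"gaussian"` or `"lorentzian"`).
#' @param thickness_cv coefficient of variation of the multiplicative
#'   thickness field (unitless).
#' @param thickness_corr_len correlation length of the smooth fields, in
#'   pixels (moving-average window).
#' @param lipid_cv coefficient of variation of the lipid weight field --
#'   the genuine chemical heterogeneity that survives normalization.
#' @param baseline_order polynomial order of the per-pixel baseline drift.
#' @param baseline_scale maximum absolute contribution of each polynomial
#'   coefficient, in absorbance units. The constant term is drawn positive
#'   (scattering baselines raise the absorbance floor), higher orders are
#'   symmetric around zero.
#' @param noise_sd additive Gaussian noise SD, absorbance units.
#' @param hot_frac,dead_frac fractions of hot (+10 absorbance spike) and
#'   dead (NaN) detector pixels.
#' @param contam_frac target fraction of pixels covered by contaminant
#'   blobs.
#' @param n_blobs maximum number of contaminant disks placed while filling
#'   `contam_frac`.
#' @param pixel_pitch detector pixel side, micrometres.
#' @param seed integer seed driving every stochastic draw.
#' @return object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(rows = 128L, cols = 128L,
                       axis_lo = 698, axis_hi = 3845, axis_step = 4,
                       band_table = default_band_table(),
                       thickness_cv = 0.20, thickness_corr_len = 8L,
                       lipid_cv = 0.10,
                       baseline_order = 2L, baseline_scale = 0.15,
                       noise_sd = 0.005,
                       hot_frac = 0.002, dead_frac = 0.002,
                       contam_frac = 0.02, n_blobs = 16L,
                       pixel_pitch = 2.7, seed = 1L) {
  cfg <- list(
    rows = as.integer(rows), cols = as.integer(cols),
    axis_lo = axis_lo, axis_hi = axis_hi, axis_step = axis_step,
    band_table = band_table,
    thickness_cv = thickness_cv, thickness_corr_len = as.integer(thickness_corr_len),
    lipid_cv = lipid_cv,
    baseline_order = as.integer(baseline_order), baseline_scale = baseline_scale,
    noise_sd = noise_sd,
    hot_frac = hot_frac, dead_frac = dead_frac,
    contam_frac = contam_frac, n_blobs = as.integer(n_blobs),
    pixel_pitch = pixel_pitch, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$rows >= 1, cfg$cols >= 1, cfg$axis_step > 0,
            cfg$axis_hi > cfg$axis_lo,
            cfg$thickness_cv >= 0, cfg$lipid_cv >= 0,
            cfg$thickness_corr_len >= 1,
            cfg$baseline_order >= 0, cfg$baseline_scale >= 0,
            cfg$noise_sd >= 0, cfg$n_blobs >= 0)
  fr <- c(cfg$hot_frac, cfg$dead_frac, cfg$contam_frac)
  if (any(fr < 0) || any(fr >= 1) || sum(fr) >= 0.5) {
    stop("artifact fractions must lie in [0, 1) and sum to less than 0.5")
  }
  bt <- cfg$band_table
  need <- c("component", "center", "height", "width", "shape")
  if (!is.data.frame(bt) || !all(need %in% names(bt))) {
    stop("band_table must be a data.frame with columns ",
         paste(need, collapse = ", "))
  }
  if (!all(bt$shape %in% c("gaussian", "lorentzian"))) {
    stop("band shapes must be 'gaussian' or 'lorentzian'")
  }
  if (!all(bt$component %in% c("keratin", "lipid", "contaminant"))) {
    stop("band components must be keratin, lipid or contaminant")
  }
  invisible(cfg)
}

#' Default component band table
#'
#' Keratin carries the Amide I (1652 cm^-1, the tallest SC peak) and
#' Amide II (1548 cm^-1) bands; lipid carries the CH2 asymmetric
#' (2920 cm^-1) and symmetric (2850 cm^-1) stretches. The contaminant is
#' sebum-like: an ester carbonyl at 1740 cm^-1 plus strong CH2 stretches,
#' as expected for residual sebaceous lipids.
#'
#' @return data.frame usable as `band_table` in [sim_config()].
#' @export
default_band_table <- function() {
  data.frame(
    component = c("keratin", "keratin", "lipid", "lipid",
                  "contaminant", "contaminant", "contaminant"),
    center = c(1652, 1548, 2920, 2850, 1740, 2920, 2850),
    height = c(0.75, 0.55, 0.30, 0.20, 0.50, 0.60, 0.40),
    width  = c(25, 22, 17, 15, 18, 17, 15),
    shape  = "gaussian",
    stringsAsFactors = FALSE
  )
}

#' Default stratum-corneum simulation configuration
#'
#' Convenience wrapper around [sim_config()]; any argument of
#' [sim_config()] can be overridden.
#'
#' @param ... overrides passed to [sim_config()].
#' @return a `sim_config`.
#' @export
default_sc_config <- function(...) sim_config(...)

peak_profile <- function(wn, center, height, width, shape) {
  switch(shape,
    gaussian   = height * exp(-0.5 * ((wn - center) / width)^2),
    lorentzian = height / (1 + ((wn - center) / width)^2),
    stop("unknown peak shape: ", shape)
  )
}

component_basis <- function(wn, band_table, component) {
  rows <- band_table[band_table$component == component, , drop = FALSE]
  out <- numeric(length(wn))
  for (i in seq_len(nrow(rows))) {
    out <- out + peak_profile(wn, rows$center[i], rows$height[i],
                              rows$width[i], rows$shape[i])
  }
  out
}

# Truncated (edge-renormalized) centred moving average of a vector.
box_blur_vec <- function(x, len) {
  n <- length(x)
  half <- len %/% 2L
  cs <- cumsum(x)
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi] - c(0, cs)[lo]) / (hi - lo + 1)
}

box_blur <- function(m, len) {
  m <- apply(m, 2L, box_blur_vec, len = len)
  t(apply(m, 1L, box_blur_vec, len = len))
}

# Smooth unit-mean random field with exactly the requested CV: low-pass
# filtered white noise, standardized, then affinely mapped to mean 1, SD cv.
smooth_unit_field <- function(rows, cols, corr_len, cv, floor = 0.05) {
  z <- matrix(stats::rnorm(rows * cols), rows, cols)
  if (cv == 0) return(matrix(1, rows, cols))
  if (corr_len > 1L && rows > 1L && cols > 1L) z <- box_blur(z, corr_len)
  s <- stats::sd(as.vector(z))
  f <- 1 + cv * (z - mean(z)) / s
  f[f < floor] <- floor
  f
}

place_blobs <- function(rows, cols, target_px, n_blobs) {
  mask <- matrix(FALSE, rows, cols)
  if (target_px <= 0 || n_blobs < 1) return(mask)
  rc <- matrix(seq_len(rows), rows, cols)
  cc <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  placed <- 0L
  while (sum(mask) < target_px && placed < n_blobs) {
    remaining <- target_px - sum(mask)
    r <- sample(2:6, 1L)
    r <- min(r, max(2L, as.integer(round(sqrt(remaining / pi)))))
    cy <- sample.int(rows, 1L)
    cx <- sample.int(cols, 1L)
    mask <- mask | ((rc - cy)^2 + (cc - cx)^2 <= r^2)
    placed <- placed + 1L
  }
  mask
}

#' Simulate a stratum-corneum-like hyperspectral map
#'
#' Each pixel spectrum is
#' `thickness * (keratin + lipid_weight * lipid) + baseline + noise`;
#' contaminant blobs additionally gain the (thickness-independent)
#' contaminant spectrum, hot pixels are offset by +10 absorbance at every
#' channel, and dead pixels are NaN throughout. Identical config and seed
#' give bit-identical output; the caller's RNG state is left untouched.
#'
#' @param config a [sim_config()].
#' @param seed optional seed overriding `config$seed`.
#' @return list with elements `cube` (a [spectral_cube()]) and `truth`, a
#'   `sim_truth` list carrying `artifact_mask` (hot or dead),
#'   `hot_mask`, `dead_mask`, `contam_mask`, `thickness_field`,
#'   `lipid_field` and `config_echo`.
#' @export
simulate_map <- function(config = default_sc_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)

  wn <- seq(config$axis_lo, config$axis_hi, by = config$axis_step)
  if (length(wn) < 2) stop("axis must have at least 2 channels")
  if (any(config$band_table$center < min(wn) |
          config$band_table$center > max(wn))) {
    stop("axis does not cover all band centers")
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  rows <- config$rows; cols <- config$cols
  npix <- rows * cols
  nchan <- length(wn)

  keratin <- component_basis(wn, config$band_table, "keratin")
  lipid <- component_basis(wn, config$band_table, "lipid")
  contam <- component_basis(wn, config$band_table, "contaminant")

  thickness <- smooth_unit_field(rows, cols, config$thickness_corr_len,
                                 config$thickness_cv)
  lipid_w <- smooth_unit_field(rows, cols, config$thickness_corr_len,
                               config$lipid_cv)

  tvec <- as.vector(thickness)
  wvec <- as.vector(lipid_w)
  m <- outer(tvec, keratin) + outer(tvec * wvec, lipid)

  if (config$baseline_order >= 0 && config$baseline_scale > 0) {
    x <- 2 * (wn - min(wn)) / (max(wn) - min(wn)) - 1
    xb <- outer(x, 0:config$baseline_order, `^`)   # nchan x (order+1)
    coefs <- rbind(
      stats::runif(npix, 0, 2 * config$baseline_scale),
      matrix(stats::runif(npix * config$baseline_order,
                          -config$baseline_scale, config$baseline_scale),
             nrow = config$baseline_order)
    )[seq_len(config$baseline_order + 1L), , drop = FALSE]
    m <- m + t(xb %*% coefs)
  }

  if (config$noise_sd > 0) {
    m <- m + matrix(stats::rnorm(npix * nchan, sd = config$noise_sd),
                    npix, nchan)
  }

  contam_mask <- place_blobs(rows, cols, round(config$contam_frac * npix),
                             config$n_blobs)
  cpix <- which(as.vector(contam_mask))
  if (length(cpix) > 0) {
    m[cpix, ] <- m[cpix, ] + matrix(contam, length(cpix), nchan, byrow = TRUE)
  }

  n_hot <- round(config$hot_frac * npix)
  n_dead <- round(config$dead_frac * npix)
  hot_mask <- dead_mask <- matrix(FALSE, rows, cols)
  if (n_hot + n_dead > 0) {
    pool <- sample.int(npix, n_hot + n_dead)
    hot <- pool[seq_len(n_hot)]
    dead <- pool[n_hot + seq_len(n_dead)]
    if (n_hot > 0) {
      m[hot, ] <- m[hot, ] + 10
      hot_mask[hot] <- TRUE
    }
    if (n_dead > 0) {
      m[dead, ] <- NaN
      dead_mask[dead] <- TRUE
    }
  }

  cube <- spectral_cube(
    array(m, dim = c(rows, cols, nchan)), wn,
    pixel_pitch = config$pixel_pitch,
    metadata = list(simulated = TRUE, seed = config$seed)
  )
  truth <- structure(
    list(artifact_mask = hot_mask | dead_mask,
         hot_mask = hot_mask, dead_mask = dead_mask,
         contam_mask = contam_mask,
         thickness_field = thickness, lipid_field = lipid_w,
         config_echo = config),
    class = "sim_truth"
  )
  list(cube = cube, truth = truth)
}
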