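# Dispersion, retention and compactness metrics used to compare
# pre-processing plans and outlier filters, plus report generation.

#' Normalized standard deviation (coefficient of variation)
#'
#' Population SD divided by the mean, over the retained finite values.
#'
#' @param values numeric vector or matrix (e.g. a chemical map).
#' @param mask optional logical vector/matrix or [pixel_mask()] selecting
#'   retained values.
#' @return the CV; `NA` with a warning when the mean is not positive.
#' @export
normalized_sd <- function(values, mask = NULL) {
  v <- as.vector(values)
  if (!is.null(mask)) {
    g <- if (inherits(mask, "pixel_mask")) mask$grid else mask
    stopifnot(length(g) == length(v))
    v <- v[as.vector(g)]
  }
  v <- v[is.finite(v)]
  if (length(v) < 2L) stop("need at least 2 retained finite values")
  m <- mean(v)
  if (m <= 0) {
    warning("undefined CV: mean is not positive")
    return(NA_real_)
  }
  sqrt(mean((v - m)^2)) / m
}

#' Compactness of an inlier mask
#'
#' Fraction of all inlier pixels belonging to the largest 4-connected
#' inlier component. 1 means the retained region is a single connected
#' patch; a checkerboard of isolated pixels gives `1 / n_inliers`.
#'
#' @param mask a [pixel_mask()] or logical matrix.
#' @return compactness in `(0, 1]`.
#' @export
compactness <- function(mask) {
  g <- if (inherits(mask, "pixel_mask")) mask$grid else mask
  stopifnot(is.matrix(g), is.logical(g))
  n_in <- sum(g)
  if (n_in == 0L) stop("empty mask: no inlier pixels")
  rows <- nrow(g); cols <- ncol(g)
  labels <- matrix(0L, rows, cols)
  largest <- 0L
  stack <- integer(n_in)
  for (start in which(g)) {
    if (labels[start] != 0L) next
    labels[start] <- 1L
    stack[1L] <- start
    top <- 1L
    size <- 0L
    while (top > 0L) {
      p <- stack[top]; top <- top - 1L
      size <- size + 1L
      r <- ((p - 1L) %% rows) + 1L
      cc <- ((p - 1L) %/% rows) + 1L
      for (q in c(if (r > 1L) p - 1L,
                  if (r < rows) p + 1L,
                  if (cc > 1L) p - rows,
                  if (cc < cols) p + rows)) {
        if (g[q] && labels[q] == 0L) {
          labels[q] <- 1L
          top <- top + 1L
          stack[top] <- q
        }
      }
    }
    if (size > largest) largest <- size
  }
  largest / n_in
}

#' Sensitivity and specificity of an outlier filter against ground truth
#'
#' @param mask a [pixel_mask()] produced by a filter (`TRUE` = inlier).
#' @param truth logical matrix, `TRUE` where the simulator injected an
#'   artifact/contaminant pixel.
#' @return list with `sensitivity` (flagged fraction of true artifact
#'   pixels) and `specificity` (retained fraction of clean pixels).
#' @export
outlier_recovery <- function(mask, truth) {
  g <- if (inherits(mask, "pixel_mask")) mask$grid else mask
  stopifnot(is.matrix(truth), is.logical(truth), all(dim(g) == dim(truth)))
  flagged <- !g
  list(
    sensitivity = if (any(truth)) mean(flagged[truth]) else NA_real_,
    specificity = if (any(!truth)) mean(!flagged[!truth]) else NA_real_
  )
}

#' Per-map quality-control report
#'
#' Summarizes one (optionally masked) cube: masked mean spectrum, per-band
#' mean / population SD / CV of the peak intensities, the Amide I / Amide II
#' and CH2 asymmetric / symmetric ratios read from the mean spectrum,
#' retention and compactness of the mask.
#'
#' @param cube a [spectral_cube()] (typically plan-processed).
#' @param mask optional [pixel_mask()]; `NULL` retains all pixels.
#' @param bands named list of [band_def()] (default [default_bands()]).
#' @return object of class `qc_report`.
#' @export
qc_report <- function(cube, mask = NULL, bands = default_bands()) {
  stopifnot(inherits(cube, "spectral_cube"))
  if (is.null(mask)) {
    mask <- pixel_mask(matrix(TRUE, dim(cube$data)[1], dim(cube$data)[2]),
                       provenance = "none")
  }
  ms <- masked_mean_spectrum(cube, mask)
  band_stats <- do.call(rbind, lapply(bands, function(b) {
    v <- chemical_map(cube, b, "intensity")
    v <- v[mask$grid & is.finite(v)]
    data.frame(band = b$name, center = b$center,
               mean = mean(v), sd = sqrt(mean((v - mean(v))^2)),
               cv = normalized_sd(v), n = length(v))
  }))
  rownames(band_stats) <- NULL
  ratios <- c(
    amide1_amide2 = band_ratio(ms$mean, ms$wavenumber,
                               bands$amide1, bands$amide2),
    ch2_asym_sym = band_ratio(ms$mean, ms$wavenumber,
                              bands$ch2_asym, bands$ch2_sym)
  )
  structure(
    list(mean_spectrum = ms, band_stats = band_stats, ratios = ratios,
         retention = retention(mask), compactness = compactness(mask),
         plan = if (is.null(cube$metadata$plan)) "none" else cube$metadata$plan,
         filter = mask$provenance),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> plan=%s filter=%s\n", x$plan, x$filter))
  cat(sprintf("  retention %.4f, compactness %.4f\n",
              x$retention, x$compactness))
  print(x$band_stats, digits = 4)
  cat(sprintf("  Amide I/II ratio %.4f, CH2 asym/sym ratio %.4f\n",
              x$ratios[["amide1_amide2"]], x$ratios[["ch2_asym_sym"]]))
  invisible(x)
}

#' Write a QC report to CSV files
#'
#' Emits `report.csv` (the long-format band table plus retention and
#' compactness) and `mean_spectrum.csv` into a directory.
#'
#' @param report a [qc_report()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_qc_report <- function(report, dir) {
  stopifnot(inherits(report, "qc_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tab <- report$band_stats
  tab$retention <- report$retention
  tab$compactness <- report$compactness
  tab$plan <- report$plan
  tab$filter <- report$filter
  utils::write.csv(tab, file.path(dir, "report.csv"), row.names = FALSE)
  write_spectrum_csv(report$mean_spectrum, file.path(dir, "mean_spectrum.csv"))
  invisible(dir)
}

#' Compare pre-processing plans and outlier filters on one map
#'
#' Runs every plan / filter combination on a cube and tabulates, for each
#' band, the mean intensity, population SD and CV over the retained valid
#' pixels, together with the retention fraction and mask compactness.
#' Filters may be evaluated on the raw cube (`filter_stage = "raw"`,
#' the default: artifact detection happens before correction) or on the
#' plan-processed cube (`"processed"`). Rows are returned in a canonical
#' order (plan, filter, band), so the output is invariant to the order in
#' which plans and filters are supplied.
#'
#' @param cube a [spectral_cube()] (raw).
#' @param plans named list of [preprocess_plan()] objects.
#' @param filters named list of [filter_spec()] objects (include
#'   `filter_spec("none")` for the unfiltered reference).
#' @param bands named list of [band_def()].
#' @param filter_stage `"raw"` or `"processed"`.
#' @param map_id identifier copied into the output rows.
#' @return long-format data.frame with columns `map_id, plan, filter, band,
#'   mean, sd, cv, retention, compactness, n_px`.
#' @export
compare_methods <- function(cube, plans = standard_plans(),
                            filters = list(none = filter_spec("none")),
                            bands = default_bands(),
                            filter_stage = c("raw", "processed"),
                            map_id = "map") {
  stopifnot(inherits(cube, "spectral_cube"),
            length(plans) >= 1L, length(filters) >= 1L)
  filter_stage <- match.arg(filter_stage)
  rows <- list()
  for (pl in plans) {
    stopifnot(inherits(pl, "preprocess_plan"))
    pp <- apply_plan(cube, pl)
    maps <- lapply(bands, function(b) chemical_map(pp$cube, b, "intensity"))
    names(maps) <- vapply(bands, `[[`, "", "name")
    for (fs in filters) {
      stopifnot(inherits(fs, "filter_spec"))
      fmask <- tryCatch(
        apply_filter(if (filter_stage == "raw") cube else pp$cube, fs),
        error = function(e) NULL
      )
      if (is.null(fmask)) {
        rows[[length(rows) + 1L]] <- data.frame(
          map_id = map_id, plan = plan_label(pl), filter = fs$label,
          band = NA_character_, mean = NA_real_, sd = NA_real_,
          cv = NA_real_, retention = NA_real_, compactness = NA_real_,
          n_px = 0L, error = "filter_failed")
        next
      }
      grid <- fmask$grid & pp$valid$grid
      ret <- mean(grid)
      comp <- if (any(grid)) compactness(grid) else NA_real_
      for (b in bands) {
        v <- maps[[b$name]]
        keep <- grid & is.finite(v)
        vv <- v[keep]
        ok <- length(vv) >= 2L && mean(vv) > 0
        rows[[length(rows) + 1L]] <- data.frame(
          map_id = map_id, plan = plan_label(pl), filter = fs$label,
          band = b$name,
          mean = if (length(vv) > 0) mean(vv) else NA_real_,
          sd = if (length(vv) > 1) sqrt(mean((vv - mean(vv))^2)) else NA_real_,
          cv = if (ok) sqrt(mean((vv - mean(vv))^2)) / mean(vv) else NA_real_,
          retention = ret, compactness = comp, n_px = length(vv),
          error = if (ok) "" else "degenerate_cell")
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$plan, out$filter, out$band), , drop = FALSE]
  rownames(out) <- NULL
  out
}
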