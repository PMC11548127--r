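# Plain-text cube container and CSV exports.
#
# The cube container is a single self-describing text file:
#   line 1: "#ircube " + JSON header (rows, cols, channels, pixel pitch,
#           absorbance flag, metadata)
#   line 2: comma-separated wavenumber axis (cm^-1, ascending)
#   lines 3...: one pixel per line, comma-separated absorbance values,
#           pixels in column-major order (p = row + (col - 1) * rows).
# NaN encodes dead pixels.

#' Write a cube to a plain-text container
#'
#' @param cube a [spectral_cube()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_cube()]
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "spectral_cube"))
  d <- dim(cube$data)
  hdr <- jsonlite::toJSON(
    list(format = "ircube-text", version = 1L,
         rows = d[1], cols = d[2], channels = d[3],
         pixel_pitch_um = cube$pixel_pitch, absorbance = TRUE,
         metadata = cube$metadata),
    auto_unbox = TRUE, digits = NA, null = "null", na = "null"
  )
  con <- file(path, open = "w")
  writeLines(paste0("#ircube ", hdr), con)
  writeLines(paste(format(cube$wavenumber, digits = 15, trim = TRUE,
                          scientific = FALSE),
                   collapse = ","), con)
  close(con)
  data.table::fwrite(data.table::as.data.table(cube_matrix(cube)), path,
                     append = TRUE, col.names = FALSE, sep = ",", na = "NaN")
  invisible(path)
}

#' Read a cube from a plain-text container
#'
#' Cubes stored with a descending wavenumber axis are reordered to ascending
#' on read and the flip is recorded in `metadata$axis_flipped`.
#'
#' @param path file written by [write_cube()].
#' @return a [spectral_cube()].
#' @export
read_cube <- function(path) {
  head2 <- readLines(path, n = 2L)
  if (length(head2) < 2L || !startsWith(head2[1], "#ircube ")) {
    stop("not an ircube text container: ", path)
  }
  hdr <- jsonlite::fromJSON(sub("^#ircube ", "", head2[1]))
  wn <- as.numeric(strsplit(head2[2], ",", fixed = TRUE)[[1]])
  dt <- data.table::fread(path, skip = 2L, header = FALSE, sep = ",",
                          na.strings = c("NA", "NaN"))
  m <- as.matrix(dt)
  m[is.na(m)] <- NaN
  dimnames(m) <- NULL
  if (nrow(m) != hdr$rows * hdr$cols || ncol(m) != hdr$channels ||
      length(wn) != hdr$channels) {
    stop("container dimensions are inconsistent with its header")
  }
  meta <- hdr$metadata
  if (is.null(meta) || length(meta) == 0) meta <- list()
  if (!is.list(meta)) meta <- as.list(meta)
  if (all(diff(wn) < 0)) {
    wn <- rev(wn)
    m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
    meta$axis_flipped <- TRUE
  }
  pitch <- hdr$pixel_pitch_um
  if (is.null(pitch)) pitch <- NA_real_
  spectral_cube(array(m, dim = c(hdr$rows, hdr$cols, hdr$channels)), wn,
                pixel_pitch = pitch, metadata = meta)
}

#' Export a mean spectrum as CSV
#'
#' Writes two columns `wavenumber_cm-1, absorbance` and, when the input
#' carries per-channel dispersion, a third column `sd`.
#'
#' @param x a `mean_spectrum` (from [masked_mean_spectrum()]) or a numeric
#'   spectrum vector.
#' @param path output CSV path.
#' @param wavenumber axis, required when `x` is a bare numeric vector.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(x, path, wavenumber = NULL) {
  if (inherits(x, "mean_spectrum")) {
    df <- data.frame(wn = x$wavenumber, absorbance = x$mean, sd = x$sd)
    names(df) <- c("wavenumber_cm-1", "absorbance", "sd")
  } else {
    stopifnot(is.numeric(x), !is.null(wavenumber),
              length(x) == length(wavenumber))
    df <- data.frame(wn = wavenumber, absorbance = x)
    names(df) <- c("wavenumber_cm-1", "absorbance")
  }
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a 2-d value grid (chemical map or mask) as CSV
#'
#' @param grid numeric or logical matrix.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(grid, path) {
  stopifnot(is.matrix(grid))
  utils::write.table(grid, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
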