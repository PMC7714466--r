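#' Calibrated image stack
#'
#' A 3D (single- or multi-channel) intensity grid with physical voxel sizes.
#' Arrays are indexed `[x, y, z]`; the calibration gives the voxel edge
#' lengths in micrometres along x, y and z.
#'
#' @param data a 3D numeric array, or a named list of 3D arrays (one per
#'   channel, identical dimensions).
#' @param calibration numeric length-3, voxel size in um for (x, y, z).
#' @param channels optional channel names when `data` is a single array or an
#'   unnamed list.
#' @return An object of class `calibrated_stack`: a list with elements
#'   `channels` (named list of arrays) and `calibration`.
#' @examples
#' s <- calibrated_stack(array(0, c(8, 8, 4)), c(0.103, 0.103, 0.2))
#' dim(s)
#' @export
calibrated_stack <- function(data, calibration = c(1, 1, 1), channels = NULL) {
  if (is.array(data) && length(dim(data)) == 3) data <- list(data)
  if (!is.list(data)) stopf("data must be a 3D array or a list of 3D arrays")
  if (!is.null(channels)) names(data) <- channels
  if (is.null(names(data))) names(data) <- paste0("ch", seq_along(data) - 1)
  dims <- lapply(data, dim)
  if (any(vapply(dims, length, 1L) != 3))
    stopf("every channel must be a 3D array")
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1)
    stopf("all channels must share dimensions")
  structure(list(channels = data, calibration = check_calibration(calibration)),
            class = "calibrated_stack")
}

#' @export
dim.calibrated_stack <- function(x) dim(x$channels[[1]])

#' @export
print.calibrated_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("calibrated_stack: %d x %d x %d voxels, %d channel(s) [%s]\n",
              d[1], d[2], d[3], length(x$channels),
              paste(names(x$channels), collapse = ", ")))
  cat(sprintf("  calibration (um): x=%.4g y=%.4g z=%.4g\n",
              x$calibration[1], x$calibration[2], x$calibration[3]))
  invisible(x)
}

# First (reference) channel as a plain array.
stack_array <- function(stack, channel = 1) {
  if (is.array(stack)) return(stack)
  stack$channels[[channel]]
}

#' Read a multi-page TIFF as a calibrated stack
#'
#' One TIFF file per channel; every page is one Z slice. Voxel calibration is
#' taken from the ImageJ-style description tag when present, otherwise from
#' the `calibration` argument (with a warning when neither is available).
#'
#' @param paths character vector of TIFF paths (one per channel).
#' @param calibration fallback voxel size (x, y, z) in um.
#' @param channels optional channel names (defaults to file stems).
#' @return a [calibrated_stack()].
#' @export
read_stack <- function(paths, calibration = NULL, channels = NULL) {
  chans <- list()
  meta_cal <- NULL
  for (p in paths) {
    if (!file.exists(p)) stopf("cannot read TIFF: %s", p)
    pages <- tiff::readTIFF(p, all = TRUE, as.is = TRUE, info = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (is.null(meta_cal)) meta_cal <- parse_tiff_calibration(attributes(pages[[1]]))
    arr <- vapply(pages, function(m) t(m), matrix(0, ncol(pages[[1]]),
                                                  nrow(pages[[1]])))
    chans[[length(chans) + 1]] <- arr
  }
  names(chans) <- channels %||% sub("\\.tiff?$", "", basename(paths),
                                    ignore.case = TRUE)
  cal <- meta_cal %||% calibration
  if (is.null(cal)) {
    warnf("no voxel calibration in TIFF metadata and none supplied; assuming 1 um voxels")
    cal <- c(1, 1, 1)
  }
  calibrated_stack(chans, cal)
}

# Best-effort extraction of voxel sizes from readTIFF attributes
# (ImageJ writes "spacing=<z>" in the description and XResolution in
# pixels per unit).
parse_tiff_calibration <- function(att) {
  xy <- NULL
  z <- NULL
  if (!is.null(att$x.resolution) && is.finite(att$x.resolution) &&
      att$x.resolution > 0)
    xy <- 1 / att$x.resolution
  if (!is.null(att$description) && is.character(att$description)) {
    m <- regmatches(att$description,
                    regexec("spacing=([0-9.eE+-]+)", att$description))[[1]]
    if (length(m) == 2) z <- as.numeric(m[2])
  }
  if (is.null(xy) || is.null(z)) return(NULL)
  c(xy, xy, z)
}

#' Write a calibrated stack as multi-page TIFF
#'
#' Channels are written as separate files (suffix `_<channel>` when more than
#' one). Intensities must be integers in `[0, 2^bits - 1]`; masks should be
#' written via `bits = 8` after scaling to 0/255.
#'
#' @param stack a [calibrated_stack()] or 3D array.
#' @param path output file path (`.tif`).
#' @param bits bits per sample, 8 or 16.
#' @return invisibly, the written path(s).
#' @export
write_stack <- function(stack, path, bits = 16) {
  chans <- if (is.array(stack)) list(stack) else stack$channels
  maxval <- 2^bits - 1
  out <- character(0)
  for (i in seq_along(chans)) {
    p <- path
    if (length(chans) > 1)
      p <- sub("(\\.tiff?)$", sprintf("_%s\\1", names(chans)[i]), path,
               ignore.case = TRUE)
    arr <- chans[[i]]
    if (min(arr) < 0 || max(arr) > maxval)
      stopf("intensities out of range for %d-bit TIFF", bits)
    pages <- lapply(seq_len(dim(arr)[3]), function(z) t(arr[, , z]) / maxval)
    tiff::writeTIFF(pages, p, bits.per.sample = bits, compression = "none")
    out <- c(out, p)
  }
  invisible(out)
}

write_mask_tiff <- function(mask, path) {
  mask <- as_mask_array(mask)
  write_stack(array(ifelse(mask, 255, 0), dim(mask)), path, bits = 8)
}

#' Pipeline configuration
#'
#' All tunable parameters of the autocrop / segmentation / surface / domain
#' pipeline with their defaults. Values can be overridden by arguments or by
#' a flat `key=value` text file (see [read_config()]).
#'
#' @param ... named overrides of the defaults listed below.
#' @return a named list of class `nucmorph_config`.
#' @details Defaults: voxel calibration `x_cal_um = y_cal_um = 0.103`,
#'   `z_cal_um = 0.2` (wide-field acquisition); autocrop `padding_voxels =
#'   20`, `min_volume_um3 = 1`, `merge_boxes = TRUE`, `merge_fraction = 0.5`;
#'   segmentation `threshold_window = 20` (of 256 grey bins),
#'   `seg_min_volume_um3 = 0.5`, `seg_max_volume_um3 = 2000`; surface
#'   `surfel_iterations = 0` (on-surface normal smoothing passes used by the
#'   area estimate); domains `cc_contrast = 1.5`, `fish_contrast = 2`,
#'   `domain_min_volume_um3 = 0.02`, `domain_smooth_sigma = 1` voxel,
#'   `domain_merge_h = 0.15`.
#' @export
nucmorph_config <- function(...) {
  cfg <- list(
    x_cal_um = 0.103, y_cal_um = 0.103, z_cal_um = 0.2,
    padding_voxels = 20, min_volume_um3 = 1,
    merge_boxes = TRUE, merge_fraction = 0.5,
    threshold_window = 20,
    seg_min_volume_um3 = 0.5, seg_max_volume_um3 = 2000,
    surfel_iterations = 0,
    cc_contrast = 1.5, fish_contrast = 2,
    domain_min_volume_um3 = 0.02, domain_smooth_sigma = 1,
    domain_merge_h = 0.15,
    seed = 1
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stopf("unknown config key(s): %s", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "nucmorph_config")
}

config_calibration <- function(cfg) {
  check_calibration(c(cfg$x_cal_um, cfg$y_cal_um, cfg$z_cal_um))
}

#' Read / write a flat key=value configuration file
#'
#' @param path text file with one `key=value` pair per line; `#` comments and
#'   blank lines are ignored.
#' @return [read_config()] returns a `nucmorph_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(vapply(kv, length, 1L) != 2))
    stopf("malformed config line in %s", path)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, `[`, "", 2))
  parsed <- lapply(vals, function(v) {
    if (toupper(v) %in% c("TRUE", "FALSE")) return(as.logical(v))
    n <- suppressWarnings(as.numeric(v))
    if (!is.na(n)) n else v
  })
  names(parsed) <- keys
  do.call(nucmorph_config, parsed)
}

#' @rdname read_config
#' @param config a `nucmorph_config`.
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    sprintf("%s=%s", k, format(config[[k]], scientific = FALSE))
  }, "")
  writeLines(lines, path)
  invisible(path)
}
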