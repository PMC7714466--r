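#' Otsu threshold of an intensity image or histogram
#'
#' The threshold maximizing the between-class variance of a 256-bin
#' histogram. Intensities are binned over their full range regardless of bit
#' depth, so thresholds are comparable across acquisitions; binarization is
#' `value > threshold` = object.
#'
#' @param x a numeric array/vector of intensities, or a list with elements
#'   `counts` and `mids` (a precomputed histogram).
#' @param levels number of histogram bins when `x` is an intensity array.
#' @return the threshold, on the intensity scale of `x`.
#' @examples
#' otsu_threshold(c(rep(10, 50), rep(200, 50)))
#' @export
otsu_threshold <- function(x, levels = 256) {
  if (is.list(x) && !is.null(x$counts)) {
    counts <- as.numeric(x$counts)
    mids <- as.numeric(x$mids)
  } else {
    v <- as.numeric(x)
    rng <- range(v)
    if (!all(is.finite(rng))) stopf("non-finite intensities")
    if (rng[1] == rng[2])
      stop(structure(class = c("nucmorph_single_class", "error", "condition"),
                     list(message = "constant image: no Otsu threshold exists",
                          call = sys.call(-1))))
    breaks <- seq(rng[1], rng[2], length.out = levels + 1)
    counts <- tabulate(pmin(findInterval(v, breaks, all.inside = TRUE),
                            levels), nbins = levels)
    mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  }
  counts <- as.numeric(counts)
  if (sum(counts > 0) < 2)
    stop(structure(class = c("nucmorph_single_class", "error", "condition"),
                   list(message = "histogram has fewer than two occupied bins",
                        call = sys.call(-1))))
  n <- sum(counts)
  w <- cumsum(counts)
  mu <- cumsum(counts * mids)
  mu_t <- mu[length(mu)]
  # between-class variance for a cut after bin k
  k <- seq_len(length(counts) - 1)
  bcv <- (n * mu[k] - mu_t * w[k])^2 / (w[k] * (n - w[k]))
  bcv[!is.finite(bcv)] <- -Inf
  cut <- which.max(bcv)
  # threshold at the upper edge of the cut bin (<= threshold is background)
  (mids[cut] + mids[cut + 1]) / 2
}

#' Connected components of a 3D binary grid with physical volumes
#'
#' 26-connected (default) component labelling; the physical volume of each
#' component is its voxel count times the voxel volume.
#'
#' @param binary logical 3D array.
#' @param calibration voxel size (x, y, z) um.
#' @param connectivity 26 or 6.
#' @return list with `labels` (integer array) and `table` (data frame:
#'   label, n_voxels, volume_um3, and the tight 0-based inclusive bounds
#'   x0..z1).
#' @export
find_components <- function(binary, calibration = c(1, 1, 1),
                            connectivity = 26) {
  calibration <- check_calibration(calibration)
  binary <- as_mask_array(binary)
  labels <- cpp_label3d(binary, dim(binary), as.integer(connectivity))
  nlab <- max(labels)
  if (nlab == 0) {
    tab <- data.frame(label = integer(0), n_voxels = integer(0),
                      volume_um3 = numeric(0), x0 = integer(0), x1 = integer(0),
                      y0 = integer(0), y1 = integer(0), z0 = integer(0),
                      z1 = integer(0))
    return(list(labels = labels, table = tab, calibration = calibration))
  }
  st <- cpp_component_stats(labels, dim(binary), nlab)
  tab <- data.frame(label = seq_len(nlab), n_voxels = st[, 1],
                    volume_um3 = st[, 1] * voxel_volume(calibration),
                    x0 = st[, 2], x1 = st[, 3], y0 = st[, 4], y1 = st[, 5],
                    z0 = st[, 6], z1 = st[, 7])
  list(labels = labels, table = tab, calibration = calibration)
}

#' Filter components by physical volume
#'
#' Retains components with volume strictly above `min_volume_um3` (default
#' 1 um^3, the size filter that removes debris and autofluorescent
#' organelles from the detection).
#'
#' @param components result of [find_components()].
#' @param min_volume_um3 retention threshold, um^3.
#' @return `components` with the table subset (labels array unchanged).
#' @export
filter_components <- function(components, min_volume_um3 = 1) {
  if (min_volume_um3 < 0) stopf("min_volume_um3 must be >= 0")
  keep <- components$table$volume_um3 > min_volume_um3
  dropped <- sum(!keep)
  if (dropped > 0)
    message(sprintf("filter_components: discarded %d component(s) <= %g um^3",
                    dropped, min_volume_um3))
  components$table <- components$table[keep, , drop = FALSE]
  components
}

#' Padded bounding box of one component
#'
#' The tight voxel bounding box expanded by `padding_voxels` in every
#' direction and clamped to the stack bounds. Coordinates are 0-based with
#' inclusive voxel extents.
#'
#' @param bounds either a component-table row from [find_components()] or a
#'   logical mask array.
#' @param padding_voxels voxels added on every side (default 20).
#' @param dim_voxels stack dimensions.
#' @return data frame row: id, x0, y0, z0, width, height, depth.
#' @export
component_to_box <- function(bounds, padding_voxels = 20, dim_voxels) {
  if (padding_voxels < 0) stopf("padding_voxels must be >= 0")
  if (is.array(bounds)) {
    idx <- which(bounds, arr.ind = TRUE)
    if (nrow(idx) == 0) stopf("empty component")
    bounds <- data.frame(x0 = min(idx[, 1]) - 1, x1 = max(idx[, 1]) - 1,
                         y0 = min(idx[, 2]) - 1, y1 = max(idx[, 2]) - 1,
                         z0 = min(idx[, 3]) - 1, z1 = max(idx[, 3]) - 1)
  }
  lo <- pmax(0, c(bounds$x0, bounds$y0, bounds$z0) - padding_voxels)
  hi <- pmin(dim_voxels - 1,
             c(bounds$x1, bounds$y1, bounds$z1) + padding_voxels)
  data.frame(id = 0L, x0 = lo[1], y0 = lo[2], z0 = lo[3],
             width = hi[1] - lo[1] + 1, height = hi[2] - lo[2] + 1,
             depth = hi[3] - lo[3] + 1)
}

box_volume <- function(b) b$width * b$height * b$depth

box_overlap <- function(a, b) {
  w <- min(a$x0 + a$width, b$x0 + b$width) - max(a$x0, b$x0)
  h <- min(a$y0 + a$height, b$y0 + b$height) - max(a$y0, b$y0)
  d <- min(a$z0 + a$depth, b$z0 + b$depth) - max(a$z0, b$z0)
  if (w <= 0 || h <= 0 || d <= 0) return(0)
  w * h * d
}

#' Merge overlapping bounding boxes
#'
#' Iteratively unions any pair of boxes whose shared voxel volume is at least
#' `overlap_fraction` of the smaller box, until no pair qualifies; ids are
#' renumbered from 0. This limits multiple boxes over a single large nucleus.
#'
#' @param boxes data frame of boxes (as from [component_to_box()]).
#' @param overlap_fraction required shared fraction in (0, 1].
#' @return merged boxes.
#' @export
merge_boxes <- function(boxes, overlap_fraction = 0.5) {
  if (overlap_fraction <= 0 || overlap_fraction > 1)
    stopf("overlap_fraction must be in (0, 1]")
  repeat {
    n <- nrow(boxes)
    if (n < 2) break
    merged <- FALSE
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        ov <- box_overlap(boxes[i, ], boxes[j, ])
        if (ov >= overlap_fraction * min(box_volume(boxes[i, ]),
                                         box_volume(boxes[j, ]))) {
          a <- boxes[i, ]; b <- boxes[j, ]
          u <- data.frame(id = a$id,
                          x0 = min(a$x0, b$x0), y0 = min(a$y0, b$y0),
                          z0 = min(a$z0, b$z0))
          u$width <- max(a$x0 + a$width, b$x0 + b$width) - u$x0
          u$height <- max(a$y0 + a$height, b$y0 + b$height) - u$y0
          u$depth <- max(a$z0 + a$depth, b$z0 + b$depth) - u$z0
          boxes <- rbind(u, boxes[-c(i, j), , drop = FALSE])
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  if (nrow(boxes)) boxes$id <- seq_len(nrow(boxes)) - 1L
  rownames(boxes) <- NULL
  boxes
}

crop_box <- function(stack, box) {
  xs <- (box$x0 + 1):(box$x0 + box$width)
  ys <- (box$y0 + 1):(box$y0 + box$height)
  zs <- (box$z0 + 1):(box$z0 + box$depth)
  chans <- lapply(stack$channels, function(a) a[xs, ys, zs, drop = FALSE])
  calibrated_stack(chans, stack$calibration)
}

#' Automatic 3D crop of every nucleus-sized object in a wide-field stack
#'
#' Pipeline: Otsu threshold of the whole stack, 26-connected components,
#' volume filter, padded bounding boxes, optional overlap merging, cropping.
#' Also produces an inverted maximum-intensity Z-projection with numbered
#' box outlines.
#'
#' @param stack a [calibrated_stack()] (first channel is used for
#'   detection).
#' @param config a [nucmorph_config()].
#' @param file_name source name recorded in the coordinate table.
#' @return list with `table` (coordinate table data frame: FileName, id,
#'   XStart, YStart, ZStart, width, height, depth), `crops` (list of
#'   [calibrated_stack()], all channels), `projection` (2D matrix), and
#'   `threshold`. A constant stack yields zero crops with a warning.
#' @export
autocrop_stack <- function(stack, config = nucmorph_config(),
                           file_name = "stack") {
  arr <- stack_array(stack)
  thr <- tryCatch(otsu_threshold(arr), nucmorph_single_class = function(e) NA)
  empty <- data.frame(FileName = character(0), id = integer(0),
                      XStart = integer(0), YStart = integer(0),
                      ZStart = integer(0), width = integer(0),
                      height = integer(0), depth = integer(0))
  if (is.na(thr)) {
    warnf("constant image %s: no objects detected", file_name)
    return(list(table = empty, crops = list(),
                projection = make_projection(arr, empty), threshold = NA))
  }
  comp <- find_components(arr > thr, stack$calibration)
  comp <- filter_components(comp, config$min_volume_um3)
  if (nrow(comp$table) == 0) {
    warnf("no components above %g um^3 in %s", config$min_volume_um3,
          file_name)
    return(list(table = empty, crops = list(),
                projection = make_projection(arr, empty), threshold = thr))
  }
  boxes <- do.call(rbind, lapply(seq_len(nrow(comp$table)), function(i) {
    component_to_box(comp$table[i, ], config$padding_voxels, dim(arr))
  }))
  boxes$id <- seq_len(nrow(boxes)) - 1L
  if (isTRUE(config$merge_boxes))
    boxes <- merge_boxes(boxes, config$merge_fraction)
  crops <- lapply(seq_len(nrow(boxes)), function(i) crop_box(stack, boxes[i, ]))
  table <- data.frame(FileName = file_name, id = boxes$id,
                      XStart = boxes$x0, YStart = boxes$y0, ZStart = boxes$z0,
                      width = boxes$width, height = boxes$height,
                      depth = boxes$depth)
  list(table = table, crops = crops,
       projection = make_projection(arr, table), threshold = thr)
}

#' Re-crop other channels with an existing coordinate table
#'
#' Applies voxel-identical box geometry to additional channels (e.g. FISH
#' probe wavelengths) so that crops align across channels.
#'
#' @param table a coordinate table (from [autocrop_stack()] or
#'   [read_coordinate_table()]).
#' @param stack a [calibrated_stack()] holding the other channel(s); must
#'   share dimensions with the reference channel.
#' @param reference_dim dimensions of the stack the table was computed on
#'   (defaults to `dim(stack)`, i.e. only internal consistency is checked).
#' @return named list (by channel) of lists of crops.
#' @export
crop_other_channels <- function(table, stack, reference_dim = dim(stack)) {
  if (!identical(as.integer(dim(stack)), as.integer(reference_dim)))
    stopf("channel dimensions %s do not match reference %s",
          paste(dim(stack), collapse = "x"),
          paste(reference_dim, collapse = "x"))
  if (nrow(table) == 0) return(stats::setNames(
    lapply(names(stack$channels), function(ch) list()),
    names(stack$channels)))
  out <- lapply(names(stack$channels), function(ch) {
    sub <- calibrated_stack(stack$channels[ch], stack$calibration)
    lapply(seq_len(nrow(table)), function(i) {
      b <- data.frame(x0 = table$XStart[i], y0 = table$YStart[i],
                      z0 = table$ZStart[i], width = table$width[i],
                      height = table$height[i], depth = table$depth[i])
      crop_box(sub, b)
    })
  })
  stats::setNames(out, names(stack$channels))
}

#' Read / write coordinate tables
#'
#' Tab-separated text with header FileName, id, XStart, YStart, ZStart,
#' width, height, depth; round-trips losslessly.
#'
#' @param table coordinate table data frame.
#' @param path file path.
#' @export
write_coordinate_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_coordinate_table
#' @export
read_coordinate_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

# 3x5 digit bitmaps for box numbering on projections.
digit_font <- function() {
  raw <- c("111101101101111", "010110010010111", "111001111100111",
           "111001111001111", "101101111001001", "111100111001111",
           "111100111101111", "111001010010010", "111101111101111",
           "111101111001111")
  lapply(raw, function(s) matrix(as.integer(strsplit(s, "")[[1]]) == 1,
                                 nrow = 3, byrow = FALSE))
}

# Inverted maximum-intensity Z-projection with numbered box outlines.
make_projection <- function(arr, table) {
  proj <- apply(arr, c(1, 2), max)
  proj <- max(proj) - proj                      # inverted lookup
  lo <- 0
  hi <- max(proj)
  font <- digit_font()
  for (i in seq_len(nrow(table))) {
    x0 <- table$XStart[i] + 1; y0 <- table$YStart[i] + 1
    x1 <- x0 + table$width[i] - 1; y1 <- y0 + table$height[i] - 1
    proj[c(x0, x1), y0:y1] <- lo
    proj[x0:x1, c(y0, y1)] <- lo
    # draw the id above-left of the box (scaled 2x)
    digits <- strsplit(as.character(table$id[i]), "")[[1]]
    cx <- x0
    for (d in digits) {
      glyph <- font[[as.integer(d) + 1]]
      gx <- kronecker(glyph, matrix(TRUE, 2, 2))
      xs <- cx + seq_len(nrow(gx)) - 1
      ys <- max(1, y0 - 2 * 5 - 2) + seq_len(ncol(gx)) - 1
      ok <- xs <= nrow(proj) & xs >= 1
      ok2 <- ys <= ncol(proj) & ys >= 1
      sub <- proj[xs[ok], ys[ok2], drop = FALSE]
      sub[gx[ok, ok2, drop = FALSE]] <- lo
      proj[xs[ok], ys[ok2]] <- sub
      cx <- cx + nrow(gx) + 2
    }
  }
  proj
}
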