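#' Nucleus volume
#'
#' Voxel count times the physical voxel volume.
#'
#' @param mask a [nucleus_mask()] or logical array.
#' @param calibration voxel size when `mask` is a plain array.
#' @return volume in um^3 (0 for an empty mask).
#' @export
nucleus_volume <- function(mask, calibration = NULL) {
  cal <- if (inherits(mask, "nucleus_mask")) mask$calibration
  else check_calibration(calibration %||% c(1, 1, 1))
  sum(as_mask_array(mask)) * voxel_volume(cal)
}

#' Flatness and elongation from the equivalent ellipsoid
#'
#' Eigenvalues `l1 >= l2 >= l3` of the covariance of the calibrated
#' foreground voxel coordinates give the equivalent-ellipsoid radius ratios:
#' elongation = sqrt(l1/l2) (largest/middle) and flatness = sqrt(l2/l3)
#' (middle/smallest). Both are 1 for a sphere and >= 1 in general.
#'
#' @inheritParams nucleus_volume
#' @return named numeric: flatness, elongation.
#' @export
flatness_elongation <- function(mask, calibration = NULL) {
  cal <- if (inherits(mask, "nucleus_mask")) mask$calibration
  else check_calibration(calibration %||% c(1, 1, 1))
  m <- as_mask_array(mask)
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) < 4)
    stopf("degenerate mask: need at least 4 voxels for an ellipsoid fit")
  pts <- sweep(idx - 1, 2, cal, `*`)
  ev <- sort(eigen(stats::cov(pts), symmetric = TRUE,
                   only.values = TRUE)$values, decreasing = TRUE)
  if (ev[3] <= .Machine$double.eps * ev[1])
    stopf("degenerate mask: voxels are coplanar or collinear")
  c(flatness = sqrt(ev[2] / ev[3]), elongation = sqrt(ev[1] / ev[2]))
}

#' Shape metrics of one segmented nucleus
#'
#' Volume, both surface-area estimates, flatness, elongation, equivalent
#' radius and sphericity (36 pi V^2 / S^3; 1 for a perfect sphere). The
#' headline sphericity uses the surfel surface area; the exposed-face
#' variant is reported alongside for comparison.
#'
#' @param mask a [nucleus_mask()].
#' @param raw optional raw crop for the gradient of the surfel estimator.
#' @param config a [nucmorph_config()] (`surfel_iterations`).
#' @return one-row data frame; a `bad_crop` mask yields NA metrics with the
#'   tag.
#' @export
shape_metrics <- function(mask, raw = NULL, config = nucmorph_config()) {
  base <- data.frame(crop_id = as.character(mask$crop_id %||% NA),
                     method = mask$method, stringsAsFactors = FALSE)
  if (is_bad_crop(mask) || !any(mask$mask)) {
    return(cbind(base, data.frame(volume_um3 = NA_real_,
                                  equivalent_radius_um = NA_real_,
                                  surface_area_initial_um2 = NA_real_,
                                  surface_area_new_um2 = NA_real_,
                                  flatness = NA_real_, elongation = NA_real_,
                                  sphericity = NA_real_,
                                  sphericity_initial = NA_real_)))
  }
  v <- nucleus_volume(mask)
  s_init <- surface_area_naive(mask)
  s_new <- surface_area_surfel(mask, raw = raw,
                               iterations = config$surfel_iterations)
  fe <- tryCatch(flatness_elongation(mask),
                 error = function(e) c(flatness = NA_real_,
                                       elongation = NA_real_))
  cbind(base, data.frame(volume_um3 = v,
                         equivalent_radius_um = equivalent_radius(v),
                         surface_area_initial_um2 = s_init,
                         surface_area_new_um2 = s_new,
                         flatness = unname(fe["flatness"]),
                         elongation = unname(fe["elongation"]),
                         sphericity = 36 * pi * v^2 / s_new^3,
                         sphericity_initial = 36 * pi * v^2 / s_init^3))
}

#' Compile per-nucleus shape metrics into one table
#'
#' @param masks list of [nucleus_mask()] (mixed methods allowed).
#' @param raws optional list of raw crops matching `masks`.
#' @param config a [nucmorph_config()].
#' @return data frame, one row per (nucleus, method); `bad_crop` rows carry
#'   NA metrics.
#' @export
compile_metrics <- function(masks, raws = NULL, config = nucmorph_config()) {
  if (length(masks) == 0) {
    return(shape_metrics(nucleus_mask(array(FALSE, c(1, 1, 1)), c(1, 1, 1),
                                      "bad_crop"),
                         config = config)[0, ])
  }
  rows <- lapply(seq_along(masks), function(i) {
    shape_metrics(masks[[i]], raw = if (is.null(raws)) NULL else raws[[i]],
                  config = config)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname compile_metrics
#' @param metrics data frame from `compile_metrics()`.
#' @param path output TSV path.
#' @export
write_metrics <- function(metrics, path) {
  write.table(metrics, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
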