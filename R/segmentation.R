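#' Single-nucleus segmentation mask
#'
#' @param mask logical 3D array aligned to its crop.
#' @param calibration voxel size (x, y, z) um.
#' @param method one of `"otsu"`, `"gift"`, `"bad_crop"`.
#' @param crop_id identifier of the source crop.
#' @param ... extra provenance fields (threshold, reason, ...).
#' @return object of class `nucleus_mask`.
#' @export
nucleus_mask <- function(mask, calibration, method, crop_id = NA, ...) {
  structure(list(mask = as_mask_array(mask),
                 calibration = check_calibration(calibration),
                 method = method, crop_id = crop_id, ...),
            class = "nucleus_mask")
}

#' @export
print.nucleus_mask <- function(x, ...) {
  if (x$method == "bad_crop") {
    cat(sprintf("nucleus_mask [bad_crop] crop=%s: %s\n", x$crop_id,
                x$reason %||% "unsegmentable"))
  } else {
    cat(sprintf("nucleus_mask [%s] crop=%s: %d voxels, %.3g um^3\n",
                x$method, x$crop_id, sum(x$mask), nucleus_volume(x)))
  }
  invisible(x)
}

is_bad_crop <- function(mask) {
  inherits(mask, "nucleus_mask") && identical(mask$method, "bad_crop")
}

#' Equivalent-sphere radius and gift-wrapping threshold distance
#'
#' `equivalent_radius()` is the radius of the sphere with the object's
#' volume, `r = (3V / 4 pi)^(1/3)`. The restricted-hull threshold distance
#' `td` is half that radius, computed from the segmented volume of the
#' object being wrapped.
#'
#' @param volume_um3 object volume (> 0), um^3.
#' @return radius (um).
#' @examples
#' equivalent_radius(4 / 3 * pi * 8^3)  # 8
#' @export
equivalent_radius <- function(volume_um3) {
  if (any(volume_um3 <= 0)) stopf("volume must be > 0")
  (3 * volume_um3 / (4 * pi))^(1 / 3)
}

#' @rdname equivalent_radius
#' @param mask a `nucleus_mask` (or logical array with unit calibration).
#' @export
compute_td <- function(mask) {
  v <- if (inherits(mask, "nucleus_mask")) nucleus_volume(mask)
  else sum(as_mask_array(mask))
  equivalent_radius(v) / 2
}

#' Modified Otsu segmentation of a single-nucleus crop
#'
#' Scans candidate thresholds in a window around the plain Otsu value; for
#' each, keeps the largest 26-connected component, fills interior holes
#' (slice-wise and in 3D), and scores the component by sphericity
#' (36 pi V^2 / S^3 with the exposed-face area). The mask at the
#' sphericity-maximizing threshold is returned. Crops where no threshold
#' yields a component within the plausible volume bounds, or where the
#' component spans two opposing crop faces, are tagged `bad_crop`.
#'
#' @param crop a [calibrated_stack()] (first channel used) or 3D array.
#' @param config a [nucmorph_config()]; `threshold_window` (grey bins of
#'   256), `seg_min_volume_um3` / `seg_max_volume_um3` bounds.
#' @param crop_id identifier recorded in the result.
#' @return a [nucleus_mask()] tagged `otsu` (or `bad_crop`).
#' @export
modified_otsu_segment <- function(crop, config = nucmorph_config(),
                                  crop_id = NA) {
  if (inherits(crop, "digitized_sphere")) crop <- sphere_as_stack(crop)
  cal <- if (is.array(crop)) config_calibration(config) else crop$calibration
  arr <- stack_array(crop)
  vv <- voxel_volume(cal)
  bad <- function(reason) nucleus_mask(array(FALSE, dim(arr)), cal, "bad_crop",
                                       crop_id, reason = reason)
  t0 <- tryCatch(otsu_threshold(arr),
                 nucmorph_single_class = function(e) NA)
  if (is.na(t0)) return(bad("constant intensity"))
  rng <- range(arr)
  binw <- (rng[2] - rng[1]) / 256
  cand <- t0 + (-config$threshold_window:config$threshold_window) * binw
  cand <- cand[cand > rng[1] & cand < rng[2]]

  best <- NULL
  best_score <- -Inf
  seen <- integer(0)
  for (t in cand) {
    n_above <- sum(arr > t)
    if (n_above == 0 || n_above %in% seen) next
    seen <- c(seen, n_above)
    bin <- arr > t
    lab <- cpp_label3d(bin, dim(bin), 26L)
    if (max(lab) == 0) next
    largest <- which.max(tabulate(lab[lab > 0]))
    m <- array(lab == largest, dim(bin))
    m <- cpp_fill_holes_slices(m, dim(m))
    m <- cpp_fill_holes3d(m, dim(m))
    vol <- sum(m) * vv
    if (vol < config$seg_min_volume_um3 || vol > config$seg_max_volume_um3)
      next
    s <- surface_area_naive(m, cal)
    score <- 36 * pi * vol^2 / s^3
    if (score > best_score) {
      best_score <- score
      best <- list(mask = m, threshold = t)
    }
  }
  if (is.null(best))
    return(bad(sprintf("no threshold gives a component in [%g, %g] um^3",
                       config$seg_min_volume_um3, config$seg_max_volume_um3)))
  if (touches_opposing_faces(best$mask))
    return(bad("object truncated by the crop (touches opposing faces)"))
  nucleus_mask(best$mask, cal, "otsu", crop_id, threshold = best$threshold,
               sphericity_score = best_score)
}

#' Restricted convex hull of a 2D slice (gift wrapping with bounded edges)
#'
#' A Jarvis-march walk over the foreground boundary in which a hull edge is
#' accepted only when its physical length does not exceed `td`; where the
#' hull jump would be longer, the walk follows the object boundary instead.
#' The filled walk polygon is united with the input, so the output is a
#' superset of the foreground and a subset of its filled convex hull:
#' concavities with mouth width below `td` are bridged, wider ones are
#' preserved.
#'
#' @param slice logical matrix.
#' @param td maximal edge length, in physical units.
#' @param calibration in-plane pixel size (two values).
#' @return logical matrix.
#' @export
restricted_hull_2d <- function(slice, td, calibration = c(1, 1)) {
  if (td <= 0) stopf("td must be > 0")
  storage.mode(slice) <- "logical"
  if (!any(slice)) return(slice)
  cpp_restricted_hull_slice(slice, calibration[1], calibration[2], td)
}

#' @rdname restricted_hull_2d
#' @param points an n x 2 matrix of point coordinates; with `td = Inf` the
#'   walk reduces to the exact convex hull.
#' @return `restricted_hull_points()`: integer indices of the walk polygon
#'   vertices, in counter-clockwise order.
#' @export
restricted_hull_points <- function(points, td = Inf) {
  points <- as.matrix(points)
  if (ncol(points) != 2) stopf("points must be n x 2")
  cpp_hull_walk(points, td)
}

#' 3D gift-wrapping segmentation
#'
#' Edge-based closure of an initial (modified-Otsu) mask: the restricted
#' hull is applied to every slice in each of the three orientations XY, XZ
#' and YZ with `td` = half the equivalent-sphere radius of the initial mask,
#' the three reconstructions are united, the largest 26-connected component
#' kept and residual cavities filled. Masks that end up touching two
#' opposing crop faces are classified `bad_crop` (object truncated).
#'
#' @param crop the raw crop (kept for provenance; the wrap operates on the
#'   mask). May be NULL.
#' @param initial_mask a [nucleus_mask()] from [modified_otsu_segment()].
#' @param td override the threshold distance (um); default from the mask.
#' @return a [nucleus_mask()] tagged `gift` (or `bad_crop`).
#' @export
gift_wrap_segment <- function(crop = NULL, initial_mask, td = NULL) {
  if (is_bad_crop(initial_mask)) return(initial_mask)
  m <- initial_mask$mask
  cal <- initial_mask$calibration
  td <- td %||% compute_td(initial_mask)
  d <- dim(m)

  out <- array(FALSE, d)
  # XY slices
  for (z in seq_len(d[3])) {
    sl <- m[, , z]
    if (any(sl)) out[, , z] <-
        cpp_restricted_hull_slice(sl, cal[1], cal[2], td)
  }
  # XZ slices
  for (y in seq_len(d[2])) {
    sl <- m[, y, ]
    if (any(sl)) out[, y, ] <- out[, y, ] |
        cpp_restricted_hull_slice(sl, cal[1], cal[3], td)
  }
  # YZ slices
  for (x in seq_len(d[1])) {
    sl <- m[x, , ]
    if (any(sl)) out[x, , ] <- out[x, , ] |
        cpp_restricted_hull_slice(sl, cal[2], cal[3], td)
  }
  lab <- cpp_label3d(out, d, 26L)
  if (max(lab) > 0) {
    largest <- which.max(tabulate(lab[lab > 0]))
    out <- array(lab == largest, d)
  }
  out <- cpp_fill_holes3d(out, d)
  if (touches_opposing_faces(out))
    return(nucleus_mask(array(FALSE, d), cal, "bad_crop",
                        initial_mask$crop_id,
                        reason = "object truncated by the crop (touches opposing faces)"))
  nucleus_mask(out, cal, "gift", initial_mask$crop_id, td = td)
}
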