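#' Exposed-face surface area
#'
#' The classical estimator: the sum of the physical areas of all voxel faces
#' exposed to the background (6-connectivity). Systematically over-estimates
#' curved surfaces (a digital sphere's exposed-face area tends to 1.5 times
#' the true area), which motivates the surfel estimator.
#'
#' @param mask a [nucleus_mask()] or logical 3D array.
#' @param calibration voxel size (x, y, z) um (taken from the mask when
#'   available).
#' @return area in um^2 (0 for an empty mask).
#' @examples
#' surface_area_naive(array(TRUE, c(1, 1, 1)), c(1, 1, 1))  # 6
#' @export
surface_area_naive <- function(mask, calibration = NULL) {
  cal <- if (inherits(mask, "nucleus_mask")) mask$calibration
  else check_calibration(calibration %||% c(1, 1, 1))
  m <- as_mask_array(mask)
  if (!any(m)) return(0)
  counts <- cpp_exposed_faces(array(as.integer(m), dim(m)), dim(m))
  face <- c(cal[2] * cal[3], cal[1] * cal[3], cal[1] * cal[2])
  sum(counts * face)
}

#' Boundary normal field from the image gradient
#'
#' Outward unit normals at every boundary voxel (foreground voxels with an
#' exposed face), estimated from central finite differences of the raw
#' image scaled by the anisotropic calibration, then smoothed by `iterations`
#' passes of on-surface averaging over 26-adjacent boundary voxels and
#' normalized. Where the gradient vanishes the normal falls back to the mean
#' exposed-face direction.
#'
#' @param mask a [nucleus_mask()] or logical array.
#' @param raw the raw intensity crop (array or [calibrated_stack()]); when
#'   absent the binary mask itself is differentiated.
#' @param iterations smoothing passes (default 2; smoothing improves
#'   per-voxel normal accuracy).
#' @param calibration voxel size when `mask` is a plain array.
#' @return list of class `boundary_normals`: `index` (n x 3 voxel
#'   coordinates), `normals` (n x 3 unit vectors), `calibration`.
#' @export
estimate_normals <- function(mask, raw = NULL, iterations = 2,
                             calibration = NULL) {
  cal <- if (inherits(mask, "nucleus_mask")) mask$calibration
  else check_calibration(calibration %||% c(1, 1, 1))
  m <- as_mask_array(mask)
  if (!any(m)) stopf("empty mask")
  f <- if (is.null(raw)) array(as.double(m), dim(m))
  else array(as.double(stack_array(raw)), dim(m))
  res <- cpp_surfel(array(as.integer(m), dim(m)), f, dim(m), cal,
                    as.integer(iterations))
  idx <- arrayInd(res$index, dim(m))
  structure(list(index = idx, normals = res$normals, calibration = cal,
                 area = res$area),
            class = "boundary_normals")
}

#' Surfel (gradient-projected) surface area
#'
#' The corrected estimator: every exposed voxel face contributes its
#' physical area scaled by the dot product of the local outward unit normal
#' with the face direction, clamped at zero. With normals along the true
#' surface this removes the staircase over-count of the exposed-face sum
#' (each contribution is scaled by a factor <= 1, so the surfel area never
#' exceeds the naive area).
#'
#' By default the normals are the raw anisotropic finite-difference
#' gradients (`iterations = 0`), the calibration for which digitized-sphere
#' areas land a few percent above the truth, matching the estimator's
#' reference behaviour; see the methods vignette for why additional
#' smoothing is not applied on the area path.
#'
#' @inheritParams estimate_normals
#' @param normals optionally a precomputed [estimate_normals()] result.
#' @return area in um^2 (0 for an empty mask).
#' @export
surface_area_surfel <- function(mask, raw = NULL, normals = NULL,
                                iterations = 0, calibration = NULL) {
  cal <- if (inherits(mask, "nucleus_mask")) mask$calibration
  else check_calibration(calibration %||% c(1, 1, 1))
  m <- as_mask_array(mask)
  if (!any(m)) return(0)
  if (!is.null(normals)) {
    if (!inherits(normals, "boundary_normals"))
      stopf("normals must come from estimate_normals()")
    return(surfel_area_from_normals(m, normals, cal))
  }
  f <- if (is.null(raw)) array(as.double(m), dim(m))
  else array(as.double(stack_array(raw)), dim(m))
  res <- cpp_surfel(array(as.integer(m), dim(m)), f, dim(m), cal,
                    as.integer(iterations))
  res$area
}

# Area from an explicit normal field (R-side; must match the C++ rule).
surfel_area_from_normals <- function(m, normals, cal) {
  d <- dim(m)
  face <- c(cal[2] * cal[3], cal[1] * cal[3], cal[1] * cal[2])
  idx <- normals$index
  nv <- normals$normals
  # degenerate zero normals fall back to full per-face contributions
  degen <- rowSums(nv^2) == 0
  nv[degen, ] <- NA  # handled below by counting exposed faces in full
  padded <- array(FALSE, d + 2)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  area <- 0
  for (axis in 1:3) {
    for (dir in c(-1, 1)) {
      off <- c(0, 0, 0)
      off[axis] <- dir
      nb <- padded[cbind(idx[, 1] + 1 + off[1], idx[, 2] + 1 + off[2],
                         idx[, 3] + 1 + off[3])]
      exposed <- !nb
      contrib <- pmax(0, dir * nv[exposed, axis])
      contrib[is.na(contrib)] <- 1
      area <- area + unname(face[axis]) * sum(contrib)
    }
  }
  area
}
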