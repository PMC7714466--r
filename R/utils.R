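`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

check_calibration <- function(calibration) {
  calibration <- as.numeric(calibration)
  if (length(calibration) != 3 || any(!is.finite(calibration)) ||
      any(calibration <= 0))
    stopf("calibration must be three strictly positive voxel sizes (x, y, z)")
  names(calibration) <- c("x", "y", "z")
  calibration
}

voxel_volume <- function(calibration) prod(check_calibration(calibration))

as_mask_array <- function(mask) {
  if (is.list(mask) && !is.null(mask$mask)) mask <- mask$mask
  storage.mode(mask) <- "logical"
  mask
}

# TRUE when the mask reaches two opposing faces of its crop along any axis
# (the object is truncated by the field of view).
touches_opposing_faces <- function(mask) {
  mask <- as_mask_array(mask)
  d <- dim(mask)
  (any(mask[1, , ]) && any(mask[d[1], , ])) ||
    (any(mask[, 1, ]) && any(mask[, d[2], ])) ||
    (any(mask[, , 1]) && any(mask[, , d[3]]))
}
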