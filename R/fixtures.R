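#' Digitized sphere
#'
#' Binary ball on an isotropic unit-voxel grid: a voxel belongs to the sphere
#' when its centre lies within `radius_voxels` of the sphere centre. The grid
#' keeps at least two voxels of background margin on every face.
#'
#' @param radius_voxels positive integer radius, in voxels.
#' @param margin background margin (voxels) around the ball, minimum 2.
#' @return An object of class `digitized_sphere`: list with `grid` (logical
#'   3D array), `center` (voxel index triple), `radius_voxels`, and
#'   `n_foreground` (voxel count).
#' @examples
#' s <- make_digitized_sphere(5)
#' s$n_foreground  # 515 lattice points within distance 5
#' @export
make_digitized_sphere <- function(radius_voxels, margin = 3) {
  if (length(radius_voxels) != 1 || !is.finite(radius_voxels) ||
      radius_voxels < 1 || radius_voxels != round(radius_voxels))
    stopf("radius_voxels must be a positive integer")
  margin <- max(2, margin)
  n <- 2 * radius_voxels + 2 * margin + 1
  cc <- radius_voxels + margin + 1
  ax2 <- (seq_len(n) - cc)^2
  grid <- array(FALSE, c(n, n, n))
  r2 <- radius_voxels^2
  for (z in seq_len(n)) {
    pl <- outer(ax2, ax2, `+`) + ax2[z]
    grid[, , z] <- pl <= r2
  }
  structure(list(grid = grid, center = c(cc, cc, cc),
                 radius_voxels = radius_voxels,
                 n_foreground = sum(grid)),
            class = "digitized_sphere")
}

#' @export
print.digitized_sphere <- function(x, ...) {
  cat(sprintf("digitized_sphere: r = %d voxels, %d foreground voxels (%.1f%% of (4/3)pi r^3)\n",
              x$radius_voxels, x$n_foreground,
              100 * x$n_foreground / (4 / 3 * pi * x$radius_voxels^3)))
  invisible(x)
}

# Digitized sphere as a unit-calibrated intensity crop (0 / 255).
sphere_as_stack <- function(sphere) {
  calibrated_stack(array(ifelse(sphere$grid, 255, 0), dim(sphere$grid)),
                   c(1, 1, 1), channels = "dna")
}

# Rasterize a rotated ellipsoid into an existing logical array.
# center (um), semi_axes (um, length 3), rot 3x3 rotation matrix.
rasterize_ellipsoid <- function(dim_voxels, calibration, center, semi_axes,
                                rot = diag(3)) {
  rad <- max(semi_axes)
  lo <- pmax(1, floor((center - rad) / calibration) + 1 - 1)
  hi <- pmin(dim_voxels, ceiling((center + rad) / calibration) + 1 + 1)
  xs <- seq(lo[1], hi[1]); ys <- seq(lo[2], hi[2]); zs <- seq(lo[3], hi[3])
  px <- (xs - 1) * calibration[1] - center[1]
  py <- (ys - 1) * calibration[2] - center[2]
  pz <- (zs - 1) * calibration[3] - center[3]
  # u = D^-1 R^T p, inside iff |u| <= 1
  q <- array(0, c(length(xs), length(ys), length(zs)))
  for (k in 1:3) {
    uk <- (outer(px * rot[1, k], py * rot[2, k], `+`) %o% rep(1, length(zs))) +
      rep(pz * rot[3, k], each = length(xs) * length(ys))
    q <- q + (uk / semi_axes[k])^2
  }
  list(lo = lo, hi = hi, inside = q <= 1)
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed
  m <- matrix(rnorm(9), 3)
  qr_ <- qr(m)
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

random_unit_vector <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

#' Synthetic multi-nucleus wide-field stack with ground truth
#'
#' Builds a calibrated 3D stack emulating a wide-field acquisition of
#' DNA-stained nuclei: ellipsoidal nuclei with per-nucleus intensity scaling,
#' optional bright chromocenter blobs, an optional dark nucleolus
#' (an intensity well at a fraction of the nucleoplasm level, optionally
#' tangent to the nuclear envelope), optional FISH probe channels,
#' anisotropic Gaussian blur and additive noise. Ground-truth nucleus and
#' domain label arrays are returned alongside.
#'
#' Nuclei are placed on a jittered grid (`placement = "grid"`, deterministic
#' count) or at random with bounded retries (`placement = "random"`).
#' Identical seed and parameters yield a bit-identical stack.
#'
#' @param n_nuclei number of nuclei (>= 1).
#' @param dim_voxels stack dimensions (x, y, z) in voxels.
#' @param calibration voxel size (x, y, z) in um.
#' @param radius_um range of the nucleus mean radius (geometric mean of the
#'   semi-axes), um.
#' @param elongation_range,flatness_range ranges of the ellipsoid axis ratios
#'   a/b and b/c (1 = sphere).
#' @param rotate randomly orient each ellipsoid.
#' @param n_chromocenters chromocenters per nucleus.
#' @param cc_intensity_ratio chromocenter intensity relative to nucleoplasm.
#' @param cc_radius_um chromocenter radius range, um.
#' @param cc_radial_fraction radial position of chromocenters as a fraction
#'   of the nuclear radius (NULL = random in [0, 0.7]).
#' @param nucleolus add a dark spherical nucleolus to each nucleus.
#' @param nucleolus_fraction nucleolus radius as a fraction of the nucleus
#'   mean radius.
#' @param nucleolus_intensity nucleolus intensity relative to nucleoplasm.
#' @param nucleolus_tangent place the nucleolus tangent to the envelope
#'   (reproducing the border-indentation failure mode of DNA-dye imaging).
#' @param nucleolus_overlap fraction of the nucleolus radius by which the
#'   tangent nucleolus truncates the envelope (sets the indentation mouth
#'   width).
#' @param nucleolus_direction fixed tangency direction (length-3 vector), or
#'   NULL for a random one. An in-plane direction (zero z component) keeps
#'   the border indentation laterally resolvable; axial tangency is smeared
#'   by the axial sampling and blur.
#' @param fish_channels character vector of probe channel names (e.g.
#'   `c("cy3", "cy5")`); each receives `fish_spots` bright spots per nucleus.
#' @param fish_spots,fish_radius_um,fish_radial_fraction FISH spot count,
#'   radius (um) and radial position fraction.
#' @param blur_sigma_um Gaussian blur sigma (x, y, z) in um (anisotropic PSF
#'   stand-in); 0 disables.
#' @param noise_sd additive Gaussian noise, as a fraction of the nucleoplasm
#'   intensity; 0 disables.
#' @param intensity nucleoplasm grey level (16-bit scale).
#' @param intensity_jitter per-nucleus intensity scale range.
#' @param background background grey level.
#' @param placement `"grid"` or `"random"`.
#' @param min_separation_um minimum surface-to-surface distance for random
#'   placement, um.
#' @param max_retries placement retries before failing.
#' @param seed integer RNG seed; all randomness flows from it.
#' @return An object of class `synthetic_field`: list with `stack`
#'   ([calibrated_stack()], channel `dna` plus any FISH channels), `truth`
#'   (list: `nucleus_labels`, `domain_labels`, per-channel `fish_labels`,
#'   `nuclei` data frame), and `params`.
#' @export
make_synthetic_field <- function(n_nuclei = 9,
                                 dim_voxels = c(256, 256, 48),
                                 calibration = c(0.103, 0.103, 0.2),
                                 radius_um = c(1.2, 2),
                                 elongation_range = c(1, 1),
                                 flatness_range = c(1, 1),
                                 rotate = TRUE,
                                 n_chromocenters = 0,
                                 cc_intensity_ratio = 3,
                                 cc_radius_um = c(0.25, 0.4),
                                 cc_radial_fraction = NULL,
                                 nucleolus = FALSE,
                                 nucleolus_fraction = 0.4,
                                 nucleolus_intensity = 0.2,
                                 nucleolus_tangent = TRUE,
                                 nucleolus_overlap = 0.05,
                                 nucleolus_direction = NULL,
                                 fish_channels = character(0),
                                 fish_spots = 1,
                                 fish_radius_um = 0.2,
                                 fish_radial_fraction = 0.5,
                                 blur_sigma_um = c(0.1, 0.1, 0.3),
                                 noise_sd = 0.05,
                                 intensity = 100,
                                 intensity_jitter = c(0.8, 1.2),
                                 background = 10,
                                 placement = c("grid", "random"),
                                 min_separation_um = 0.5,
                                 max_retries = 200,
                                 seed = 1) {
  if (n_nuclei < 1) stopf("n_nuclei must be >= 1")
  calibration <- check_calibration(calibration)
  blur_sigma_um <- rep_len(blur_sigma_um, 3)
  if (any(blur_sigma_um < 0) || noise_sd < 0)
    stopf("blur sigmas and noise_sd must be >= 0")
  placement <- match.arg(placement)
  params <- as.list(environment())
  params$placement <- placement

  with_seed(seed, {
    extent_um <- (dim_voxels - 1) * calibration

    # sample every nucleus geometry first, then place with its own margins
    geom <- lapply(seq_len(n_nuclei), function(i) {
      r <- runif(1, radius_um[1], radius_um[2])
      E <- runif(1, elongation_range[1], elongation_range[2])
      Fl <- runif(1, flatness_range[1], flatness_range[2])
      b <- r * (Fl / E)^(1 / 3)
      semi <- c(E * b, b, b / Fl)                    # a >= b >= c
      rot <- if (rotate) random_rotation() else diag(3)
      # half-extent of the rotated ellipsoid along each grid axis
      half <- sqrt(rowSums((rot %*% diag(semi))^2))
      list(r = r, E = E, Fl = Fl, semi = semi, rot = rot, half = half,
           scale = runif(1, intensity_jitter[1], intensity_jitter[2]))
    })
    margins <- t(vapply(geom, function(g)
      g$half + 3 * blur_sigma_um + calibration, numeric(3)))
    if (any(2 * margins > rep(extent_um, each = n_nuclei)))
      stopf(paste0("stack of %s voxels is too small for nuclei of radius ",
                   "[%g, %g] um with elongation up to %g"),
            paste(dim_voxels, collapse = "x"), radius_um[1], radius_um[2],
            max(elongation_range))

    bound_r <- vapply(geom, function(g) max(g$semi), 0)
    centers <- matrix(NA_real_, n_nuclei, 3)
    if (placement == "grid") {
      ng <- ceiling(sqrt(n_nuclei))
      jit <- calibration[1] * 5
      mx <- max(margins[, 1]) + jit; my <- max(margins[, 2]) + jit
      gx <- seq(mx, extent_um[1] - mx, length.out = ng)
      gy <- seq(my, extent_um[2] - my, length.out = ng)
      slots <- expand.grid(x = gx, y = gy)[seq_len(n_nuclei), ]
      if (ng > 1) jit <- min(jit, (gx[2] - gx[1]) / 10)
      for (i in seq_len(n_nuclei)) {
        centers[i, ] <- c(slots$x[i] + runif(1, -jit, jit),
                          slots$y[i] + runif(1, -jit, jit),
                          runif(1, margins[i, 3], extent_um[3] - margins[i, 3]))
      }
    } else {
      for (i in seq_len(n_nuclei)) {
        placed <- FALSE
        for (try in seq_len(max_retries)) {
          p <- c(runif(1, margins[i, 1], extent_um[1] - margins[i, 1]),
                 runif(1, margins[i, 2], extent_um[2] - margins[i, 2]),
                 runif(1, margins[i, 3], extent_um[3] - margins[i, 3]))
          prev <- seq_len(i - 1)
          if (i == 1 || all(sqrt(rowSums(sweep(centers[prev, , drop = FALSE],
                                               2, p)^2)) >
                            bound_r[prev] + bound_r[i] + min_separation_um)) {
            centers[i, ] <- p
            placed <- TRUE
            break
          }
        }
        if (!placed)
          stopf(paste0("could not place nucleus %d without overlap ",
                       "(n_nuclei=%d, radius_um=[%g,%g], min_separation_um=%g, ",
                       "dim_voxels=%s)"), i, n_nuclei, radius_um[1],
                radius_um[2], min_separation_um,
                paste(dim_voxels, collapse = "x"))
      }
    }

    dna <- array(0, dim_voxels)
    nucleus_labels <- array(0L, dim_voxels)
    domain_labels <- array(0L, dim_voxels)
    fish_arrays <- lapply(fish_channels, function(ch) array(0, dim_voxels))
    names(fish_arrays) <- fish_channels
    fish_labels <- lapply(fish_channels, function(ch) array(0L, dim_voxels))
    names(fish_labels) <- fish_channels
    next_domain <- 0L
    info <- list()

    for (i in seq_len(n_nuclei)) {
      g <- geom[[i]]
      r <- g$r; E <- g$E; Fl <- g$Fl
      semi <- g$semi
      rot <- g$rot
      scale_i <- g$scale
      base <- intensity * scale_i
      ras <- rasterize_ellipsoid(dim_voxels, calibration, centers[i, ], semi, rot)
      sub <- ras$lo[1]:ras$hi[1]
      sub2 <- ras$lo[2]:ras$hi[2]
      sub3 <- ras$lo[3]:ras$hi[3]
      lab_sub <- nucleus_labels[sub, sub2, sub3]
      if (any(lab_sub[ras$inside] != 0))
        stopf(paste0("nucleus %d overlaps a previously placed nucleus; ",
                     "reduce n_nuclei or radius_um"), i)
      lab_sub[ras$inside] <- i
      nucleus_labels[sub, sub2, sub3] <- lab_sub
      img_sub <- dna[sub, sub2, sub3]
      img_sub[ras$inside] <- base
      dna[sub, sub2, sub3] <- img_sub

      # chromocenters: bright isotropic blobs at a radial position
      n_cc_i <- n_chromocenters
      cc_pos <- matrix(NA_real_, 0, 3)
      if (n_cc_i > 0) {
        for (k in seq_len(n_cc_i)) {
          placed_cc <- FALSE
          for (try in seq_len(max_retries)) {
            rc <- runif(1, cc_radius_um[1], cc_radius_um[2])
            f <- cc_radial_fraction %||% runif(1, 0.15, 0.7)
            f <- min(f, 1 - rc / min(semi) - 0.05)
            u <- random_unit_vector()
            pc <- centers[i, ] + as.numeric(rot %*% (semi * (f * u)))
            if (nrow(cc_pos) == 0 ||
                all(sqrt(rowSums(sweep(cc_pos, 2, pc)^2)) > 2 * rc)) {
              placed_cc <- TRUE
              break
            }
          }
          if (!placed_cc)
            stopf(paste0("could not place chromocenter %d of nucleus %d ",
                         "without overlap (n_chromocenters=%d, ",
                         "cc_radius_um=[%g,%g])"), k, i, n_chromocenters,
                  cc_radius_um[1], cc_radius_um[2])
          cc_pos <- rbind(cc_pos, pc)
          cras <- rasterize_ellipsoid(dim_voxels, calibration, pc, rep(rc, 3))
          cs1 <- cras$lo[1]:cras$hi[1]; cs2 <- cras$lo[2]:cras$hi[2]
          cs3 <- cras$lo[3]:cras$hi[3]
          keep <- cras$inside & nucleus_labels[cs1, cs2, cs3] == i
          img_sub <- dna[cs1, cs2, cs3]
          img_sub[keep] <- cc_intensity_ratio * base
          dna[cs1, cs2, cs3] <- img_sub
          next_domain <- next_domain + 1L
          dl <- domain_labels[cs1, cs2, cs3]
          dl[keep] <- next_domain
          domain_labels[cs1, cs2, cs3] <- dl
        }
      }

      # nucleolus: dark spherical well, optionally tangent to the envelope
      nucleolus_info <- c(NA_real_, NA_real_, NA_real_, NA_real_)
      if (nucleolus) {
        rn <- nucleolus_fraction * r
        dir <- if (is.null(nucleolus_direction)) random_unit_vector()
        else nucleolus_direction / sqrt(sum(nucleolus_direction^2))
        # tangent placement carries a small envelope overlap so the dark
        # well truncates the border with an open mouth (the observable
        # indentation); exact internal tangency has a zero-width mouth that
        # blur seals and hole filling removes
        fpos <- if (nucleolus_tangent)
          1 - rn * (1 - nucleolus_overlap) / r else
          runif(1, 0, 1 - rn / min(semi) - 0.05)
        if (is.null(nucleolus_direction)) {
          pn <- centers[i, ] + as.numeric(rot %*% (semi * (fpos * dir)))
        } else {
          # a fixed direction is meant in grid coordinates: walk along it to
          # the fractional ellipsoid radius in that direction
          u <- as.numeric(t(rot) %*% dir)
          rho <- 1 / sqrt(sum((u / semi)^2))
          pn <- centers[i, ] + fpos * rho * dir
        }
        nras <- rasterize_ellipsoid(dim_voxels, calibration, pn, rep(rn, 3))
        ns1 <- nras$lo[1]:nras$hi[1]; ns2 <- nras$lo[2]:nras$hi[2]
        ns3 <- nras$lo[3]:nras$hi[3]
        keep <- nras$inside & nucleus_labels[ns1, ns2, ns3] == i
        img_sub <- dna[ns1, ns2, ns3]
        img_sub[keep] <- nucleolus_intensity * base
        dna[ns1, ns2, ns3] <- img_sub
        nucleolus_info <- c(pn, rn)
      }

      # FISH probe spots (per probe channel)
      for (ch in fish_channels) {
        for (k in seq_len(fish_spots)) {
          u <- random_unit_vector()
          pf <- centers[i, ] +
            as.numeric(rot %*% (semi * (fish_radial_fraction * u)))
          fras <- rasterize_ellipsoid(dim_voxels, calibration, pf,
                                      rep(fish_radius_um, 3))
          fs1 <- fras$lo[1]:fras$hi[1]; fs2 <- fras$lo[2]:fras$hi[2]
          fs3 <- fras$lo[3]:fras$hi[3]
          keep <- fras$inside & nucleus_labels[fs1, fs2, fs3] == i
          img_sub <- fish_arrays[[ch]][fs1, fs2, fs3]
          img_sub[keep] <- 150 * scale_i
          fish_arrays[[ch]][fs1, fs2, fs3] <- img_sub
          fl <- fish_labels[[ch]][fs1, fs2, fs3]
          fl[keep] <- (i - 1L) * fish_spots + k
          fish_labels[[ch]][fs1, fs2, fs3] <- fl
        }
      }

      info[[i]] <- data.frame(id = i, cx_um = centers[i, 1],
                              cy_um = centers[i, 2], cz_um = centers[i, 3],
                              a_um = semi[1], b_um = semi[2], c_um = semi[3],
                              elongation = E, flatness = Fl,
                              intensity_scale = scale_i,
                              n_chromocenters = n_chromocenters,
                              nucleolus_x_um = nucleolus_info[1],
                              nucleolus_y_um = nucleolus_info[2],
                              nucleolus_z_um = nucleolus_info[3],
                              nucleolus_r_um = nucleolus_info[4])
    }

    finish_channel <- function(arr) {
      arr <- arr + background
      if (any(blur_sigma_um > 0))
        arr <- cpp_gauss_blur(arr, dim(arr), blur_sigma_um / calibration)
      if (noise_sd > 0)
        arr <- arr + rnorm(length(arr), 0, noise_sd * intensity)
      arr <- round(pmin(pmax(arr, 0), 65535))
      array(arr, dim_voxels)
    }
    chans <- c(list(dna = finish_channel(dna)),
               lapply(fish_arrays, finish_channel))
    stack <- calibrated_stack(chans, calibration)

    structure(list(stack = stack,
                   truth = list(nucleus_labels = nucleus_labels,
                                domain_labels = domain_labels,
                                fish_labels = fish_labels,
                                nuclei = do.call(rbind, info)),
                   params = params),
              class = "synthetic_field")
  })
}

#' @export
print.synthetic_field <- function(x, ...) {
  d <- dim(x$stack)
  cat(sprintf("synthetic_field: %d nuclei in a %d x %d x %d stack (seed %s)\n",
              nrow(x$truth$nuclei), d[1], d[2], d[3], x$params$seed))
  invisible(x)
}

#' Synthetic fluorescent microsphere (bead) stack
#'
#' Homogeneous-intensity spheres of a given physical diameter rasterized on
#' an anisotropic voxel grid, lightly blurred and placed without contact;
#' emulates standard calibration microspheres. The theoretical sphere volume
#' is reported in the metadata.
#'
#' @param diameter_um bead diameter, um (> 0).
#' @param calibration voxel size (x, y, z) in um.
#' @param n_beads number of beads.
#' @param seed RNG seed.
#' @param dim_voxels stack size; chosen automatically when NULL.
#' @param channels channel names (all channels image the same beads; more
#'   than one emulates multi-band fluorophores).
#' @inheritParams make_synthetic_field
#' @return A `synthetic_field` whose `params$theoretical_volume_um3` holds
#'   (4/3) pi (d/2)^3.
#' @export
make_bead_stack <- function(diameter_um, calibration = c(0.103, 0.103, 0.2),
                            n_beads = 7, seed = 1, dim_voxels = NULL,
                            channels = "dapi",
                            blur_sigma_um = c(0.05, 0.05, 0.1),
                            noise_sd = 0.02, intensity = 200,
                            background = 5) {
  if (diameter_um <= 0) stopf("diameter_um must be > 0")
  calibration <- check_calibration(calibration)
  r <- diameter_um / 2
  if (is.null(dim_voxels)) {
    ng <- ceiling(sqrt(n_beads))
    pitch <- ceiling((2 * r + 2) / calibration[1])
    nxy <- max(64, ng * pitch + 20)
    nz <- max(24, ceiling((2 * r + 2.4) / calibration[3]))
    dim_voxels <- c(nxy, nxy, nz)
  }
  if (any(2 * r >= (dim_voxels - 4) * calibration))
    stopf("bead of %g um does not fit a %s-voxel stack", diameter_um,
          paste(dim_voxels, collapse = "x"))

  with_seed(seed, {
    extent_um <- (dim_voxels - 1) * calibration
    margin <- r + 3 * blur_sigma_um + calibration
    ng <- ceiling(sqrt(n_beads))
    gx <- seq(margin[1], extent_um[1] - margin[1], length.out = max(ng, 2))
    gy <- seq(margin[2], extent_um[2] - margin[2], length.out = max(ng, 2))
    slots <- expand.grid(x = gx, y = gy)[seq_len(n_beads), ]
    arr <- array(0, dim_voxels)
    labels <- array(0L, dim_voxels)
    info <- list()
    for (i in seq_len(n_beads)) {
      p <- c(slots$x[i], slots$y[i],
             runif(1, margin[3], extent_um[3] - margin[3]))
      ras <- rasterize_ellipsoid(dim_voxels, calibration, p, rep(r, 3))
      s1 <- ras$lo[1]:ras$hi[1]; s2 <- ras$lo[2]:ras$hi[2]
      s3 <- ras$lo[3]:ras$hi[3]
      a <- arr[s1, s2, s3]; a[ras$inside] <- intensity
      arr[s1, s2, s3] <- a
      l <- labels[s1, s2, s3]; l[ras$inside] <- i
      labels[s1, s2, s3] <- l
      info[[i]] <- data.frame(id = i, cx_um = p[1], cy_um = p[2], cz_um = p[3],
                              radius_um = r)
    }
    finish <- function(a) {
      a <- a + background
      if (any(blur_sigma_um > 0))
        a <- cpp_gauss_blur(a, dim(a), blur_sigma_um / calibration)
      if (noise_sd > 0) a <- a + rnorm(length(a), 0, noise_sd * intensity)
      array(round(pmin(pmax(a, 0), 65535)), dim_voxels)
    }
    chans <- lapply(channels, function(ch) finish(arr))
    names(chans) <- channels
    params <- list(diameter_um = diameter_um, n_beads = n_beads, seed = seed,
                   theoretical_volume_um3 = 4 / 3 * pi * r^3,
                   theoretical_area_um2 = 4 * pi * r^2,
                   intensity = intensity, background = background)
    structure(list(stack = calibrated_stack(chans, calibration),
                   truth = list(nucleus_labels = labels,
                                nuclei = do.call(rbind, info)),
                   params = params),
              class = "synthetic_field")
  })
}

#' Write a synthetic field (stack, ground truth, manifest) to disk
#'
#' The intensity stack is written one TIFF per channel, the ground-truth
#' nucleus labels as an 8-bit label TIFF, and the per-nucleus parameters as a
#' tab-separated manifest.
#'
#' @param field a `synthetic_field`.
#' @param dir output directory (created if needed).
#' @param stem file name stem.
#' @return invisibly, the written paths.
#' @export
write_synthetic_field <- function(field, dir, stem = "field") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- write_stack(field$stack, file.path(dir, paste0(stem, ".tif")))
  lab <- field$truth$nucleus_labels
  labp <- file.path(dir, paste0(stem, "_labels.tif"))
  write_stack(array(pmin(lab, 255), dim(lab)), labp, bits = 8)
  man <- file.path(dir, paste0(stem, "_manifest.tsv"))
  write.table(field$truth$nuclei, man, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(paths, labp, man))
}
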