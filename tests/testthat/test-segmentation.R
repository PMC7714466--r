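test_that("equivalent radius and td follow the closed form and scale", {
  expect_equal(equivalent_radius(4 / 3 * pi * 8^3), 8, tolerance = 1e-12)
  expect_equal(equivalent_radius(4.18879), 1, tolerance = 1e-4)
  expect_error(equivalent_radius(0), "volume")

  s <- make_digitized_sphere(6)
  m1 <- nucleus_mask(s$grid, c(1, 1, 1), "otsu")
  # scaling the voxel size doubles every length: 8x volume, 2x td
  m2 <- nucleus_mask(s$grid, c(2, 2, 2), "otsu")
  expect_equal(compute_td(m2), 2 * compute_td(m1), tolerance = 1e-12)
  expect_equal(compute_td(m1), equivalent_radius(sum(s$grid)) / 2)
})

test_that("modified Otsu recovers binary objects exactly and fills holes", {
  f <- make_synthetic_field(n_nuclei = 1, dim_voxels = c(96, 96, 40),
                            blur_sigma_um = c(0, 0, 0), noise_sd = 0,
                            seed = 3)
  ac <- autocrop_stack(f$stack, nucmorph_config())
  mo <- modified_otsu_segment(ac$crops[[1]], crop_id = 0)
  b <- ac$table[1, ]
  truth <- f$truth$nucleus_labels[(b$XStart + 1):(b$XStart + b$width),
                                  (b$YStart + 1):(b$YStart + b$height),
                                  (b$ZStart + 1):(b$ZStart + b$depth)] > 0
  expect_identical(unname(mo$mask), unname(truth))
  expect_equal(mo$method, "otsu")

  # digitized sphere crop: any threshold recovers the sphere voxels exactly
  s <- make_digitized_sphere(10)
  mos <- modified_otsu_segment(s, nucmorph_config(seg_max_volume_um3 = Inf))
  expect_identical(unname(mos$mask), unname(s$grid))

  # an interior dark cavity not touching the border is filled
  cav <- s$grid
  cav[(s$center[1] - 2):(s$center[1] + 2),
      (s$center[2] - 2):(s$center[2] + 2),
      (s$center[3] - 2):(s$center[3] + 2)] <- FALSE
  crop <- calibrated_stack(array(ifelse(cav, 200, 0), dim(cav)), c(1, 1, 1))
  moc <- modified_otsu_segment(crop, nucmorph_config(seg_max_volume_um3 = Inf))
  expect_identical(unname(moc$mask), unname(s$grid))
  expect_true(is_hole_free(moc))
})

test_that("implausible or truncated crops are classified bad_crop", {
  s <- make_digitized_sphere(8)
  # default volume bounds are for calibrated nuclei; 2145 unit voxels exceed
  # the 2000 um^3 ceiling
  mo <- modified_otsu_segment(s, nucmorph_config())
  expect_equal(mo$method, "bad_crop")
  expect_match(mo$reason, "no threshold")

  flat <- calibrated_stack(array(5, c(12, 12, 8)), c(1, 1, 1))
  expect_equal(modified_otsu_segment(flat)$method, "bad_crop")

  # a slab spanning the whole crop touches opposing faces -> truncated
  slab <- array(0, c(20, 20, 10))
  slab[, 8:12, ] <- 150
  mo2 <- modified_otsu_segment(calibrated_stack(slab, c(1, 1, 1)),
                               nucmorph_config(seg_max_volume_um3 = Inf))
  expect_equal(mo2$method, "bad_crop")
  expect_match(mo2$reason, "opposing")
})

test_that("the restricted hull fills narrow mouths and keeps wide ones", {
  nn <- 41; cx <- 21; r <- 15
  disc <- matrix(FALSE, nn, nn)
  for (j in seq_len(nn)) disc[, j] <- ((seq_len(nn)) - cx)^2 + (j - cx)^2 <= r^2
  # convex disc: no growth beyond (or inside) its own hull rasterization
  expect_identical(restricted_hull_2d(disc, td = 100), disc)

  notch <- disc
  notch[(cx - 2):(cx + 2), 1:cx] <- FALSE   # radial slot, mouth 5 px wide
  # td twice the mouth: the notch is bridged; compare against the convex
  # hull oracle restricted to the notch region
  filled <- restricted_hull_2d(notch, td = 10)
  expect_true(all(filled[notch]))                       # growth-only
  hull_region <- restricted_hull_2d(notch, td = Inf)    # unrestricted = hull
  expect_true(all(hull_region[filled]))                 # subset of hull
  notch_region <- disc & !notch
  expect_gt(sum(filled & notch_region) / sum(notch_region), 0.9)

  # td a third of the mouth: the walk follows the notch boundary
  kept <- restricted_hull_2d(notch, td = 5 / 3)
  expect_equal(sum(kept & notch_region), 0)

  expect_identical(restricted_hull_2d(matrix(FALSE, 5, 5), td = 2),
                   matrix(FALSE, 5, 5))
})

test_that("the td = Inf walk equals the brute-force convex hull", {
  set.seed(123)
  for (rep in 1:100) {
    n <- sample(3:12, 1)
    pts <- matrix(runif(2 * n), ncol = 2)
    expect_setequal(as.integer(restricted_hull_points(pts, Inf)),
                    brute_hull_vertices(pts))
  }
})

test_that("gift wrapping is growth-only, hull-bounded and idempotent on spheres", {
  cfg <- nucmorph_config(seg_max_volume_um3 = Inf)
  s <- make_digitized_sphere(12)
  mo <- modified_otsu_segment(s, cfg)
  gw <- gift_wrap_segment(NULL, mo)
  expect_true(all(gw$mask >= mo$mask))          # contains the input
  expect_equal(gw$method, "gift")
  gw2 <- gift_wrap_segment(NULL, gw)
  expect_identical(gw2$mask, gw$mask)           # idempotent on convex input

  # wrapped sphere stays within the convex hull of the input voxel centres:
  # for a digitized ball no background centre lies in the hull, so the wrap
  # is exactly the input
  expect_identical(unname(gw$mask), unname(s$grid))
})

test_that("the envelope-tangent nucleolus artifact is repaired by the wrap", {
  f <- make_synthetic_field(n_nuclei = 1, dim_voxels = c(96, 96, 44),
                            radius_um = c(1.6, 2), nucleolus = TRUE,
                            nucleolus_direction = c(1, 0.2, 0), seed = 2)
  ac <- autocrop_stack(f$stack, nucmorph_config())
  mo <- modified_otsu_segment(ac$crops[[1]])
  gw <- gift_wrap_segment(ac$crops[[1]], mo)
  td <- compute_td(mo)
  # the Otsu mask carries the artefactual indentation at the nucleolus
  expect_gt(concavity_depth(mo), td)
  # the wrapped mask is hole-free with no indentation deeper than td
  expect_true(is_hole_free(gw))
  expect_lte(concavity_depth(gw), td)
})

test_that("both methods agree on microsphere-like convex objects", {
  b <- make_bead_stack(2.5, n_beads = 2, seed = 6)
  ac <- autocrop_stack(b$stack, nucmorph_config())
  for (crop in ac$crops) {
    mo <- modified_otsu_segment(crop)
    gw <- gift_wrap_segment(crop, mo)
    vo <- nucleus_volume(mo); vg <- nucleus_volume(gw)
    expect_gte(vg, vo)                      # the wrap only grows the object
    expect_lt((vg - vo) / vo, 0.1)          # within 10% on convex objects
  }
})
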