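test_that("watershed recovers planted blob counts and splits dumbbells", {
  # three well-separated blobs at 3x the nucleoplasm level
  bc <- blob_crop(radius = 12, nucleoplasm = 20,
                  blobs = list(list(at = c(6, 0, 0), amp = 40, sigma = 2),
                               list(at = c(-5, 4, 0), amp = 40, sigma = 2),
                               list(at = c(0, -6, 2), amp = 40, sigma = 2)))
  dom <- watershed_domains(bc$img, bc$nucleus, contrast = 1.5,
                           min_volume_um3 = 1, smooth_sigma = 0)
  expect_equal(nrow(dom$table), 3)

  # uniform intensity: no contrast, no domains
  du <- watershed_domains(bc$mask * 20, bc$nucleus, contrast = 1.5)
  expect_equal(nrow(du$table), 0)

  # dumbbell: one super-threshold component with two maxima splits at the neck
  db <- blob_crop(radius = 12, nucleoplasm = 20,
                  blobs = list(list(at = c(4, 0, 0), amp = 40, sigma = 2.5),
                               list(at = c(-4, 0, 0), amp = 40, sigma = 2.5)))
  region <- db$img >= 1.5 * mean(db$img[db$mask & db$img < 1.5 * mean(db$img[db$mask])])
  expect_equal(max(nucmorph:::cpp_label3d(region & db$mask, dim(db$img), 26L)),
               1)  # genuinely merged into one component
  dd <- watershed_domains(db$img, db$nucleus, contrast = 1.5,
                          min_volume_um3 = 1, smooth_sigma = 0)
  expect_equal(nrow(dd$table), 2)
})

test_that("watershed labels partition the region and keep seed labels", {
  bc <- blob_crop(radius = 10, nucleoplasm = 20,
                  blobs = list(list(at = c(4, 0, 0), amp = 40, sigma = 2),
                               list(at = c(-4, 2, 0), amp = 40, sigma = 2)))
  dom <- watershed_domains(bc$img, bc$nucleus, contrast = 1.5,
                           min_volume_um3 = 0.5, smooth_sigma = 0)
  expect_gte(nrow(dom$table), 2)
  # labels live inside the mask, volumes sum exactly
  expect_true(all(bc$mask[dom$labels > 0]))
  expect_equal(sum(dom$table$volume_um3),
               sum(dom$labels > 0) * 1)
  expect_lte(sum(dom$table$volume_um3), nucleus_volume(bc$nucleus))
})

test_that("envelope distances are geometric and border <= barycenter", {
  # single-voxel domain at the centre of a digitized sphere r = 10
  s <- make_digitized_sphere(10)
  img <- array(20, dim(s$grid)) * s$grid
  img[s$center[1], s$center[2], s$center[3]] <- 100
  nm <- nucleus_mask(s$grid, c(1, 1, 1), "otsu", "s10")
  dom <- watershed_domains(img, nm, contrast = 1.5, min_volume_um3 = 0.5,
                           smooth_sigma = 0)
  expect_equal(nrow(dom$table), 1)
  dom <- envelope_distances(dom, nm)
  expect_lt(abs(dom$table$d_border_ne_um - 10), 1)
  expect_lt(abs(dom$table$d_barycenter_ne_um - 10), 1)

  # domain touching the envelope: border distance below one voxel spacing
  img2 <- array(20, dim(s$grid)) * s$grid
  edge <- s$center + c(9, 0, 0)
  img2[edge[1]:(edge[1] + 1), edge[2], edge[3]] <- 100
  dom2 <- watershed_domains(img2, nm, contrast = 1.5, min_volume_um3 = 0.5,
                            smooth_sigma = 0)
  dom2 <- envelope_distances(dom2, nm)
  expect_lte(min(dom2$table$d_border_ne_um), sqrt(2))

  # property over a synthetic fixture: border <= barycenter for every label
  f <- make_synthetic_field(n_nuclei = 1, dim_voxels = c(96, 96, 40),
                            n_chromocenters = 3, seed = 13)
  ac <- autocrop_stack(f$stack, nucmorph_config())
  mo <- modified_otsu_segment(ac$crops[[1]])
  dom3 <- envelope_distances(watershed_domains(ac$crops[[1]], mo), mo)
  expect_true(all(dom3$table$d_border_ne_um <=
                    dom3$table$d_barycenter_ne_um + 1e-9))

  # a domain outside the mask is an invariant violation
  bad <- dom3
  bad$labels[1, 1, 1] <- 99L
  expect_error(envelope_distances(bad, mo), "outside")
})

test_that("the distance transform respects anisotropy and the mask extent", {
  box <- array(FALSE, c(30, 20, 12))
  box[3:28, 3:18, 3:10] <- TRUE
  cal <- c(0.1, 0.1, 0.25)
  edt <- nucmorph:::cpp_edt(box, dim(box), cal)
  # interior distances never exceed the half-extent of the cheapest axis
  half_min <- min((c(26, 16, 8) / 2 + 0.5) * cal)
  expect_lte(max(edt), half_min + 1e-9)
  expect_equal(max(edt[!box]), 0)
})

test_that("domain summaries aggregate volumes and distances", {
  d <- structure(list(
    labels = array(0L, c(2, 2, 2)),
    table = data.frame(label = 1:3, n_voxels = c(2, 3, 5),
                       volume_um3 = c(0.2, 0.3, 0.5),
                       bx_um = 0, by_um = 0, bz_um = 0,
                       d_border_ne_um = c(0.5, 0.7, 0.9),
                       d_barycenter_ne_um = c(0.8, 1, 1.2)),
    channel = "chromocenter", calibration = c(x = 1, y = 1, z = 1)),
    class = "domain_set")
  s <- domain_summary(d)
  expect_equal(s$n_domains, 3)
  expect_equal(s$volume_mean_um3, 1 / 3, tolerance = 1e-9)
  expect_equal(s$volume_total_um3, 1)

  d1 <- d; d1$table <- d1$table[1, ]
  s1 <- domain_summary(d1)
  expect_equal(s1$volume_mean_um3, s1$volume_total_um3)

  d0 <- d; d0$table <- d0$table[0, ]
  s0 <- domain_summary(d0)
  expect_equal(s0$n_domains, 0)
  expect_equal(s0$volume_total_um3, 0)
})
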