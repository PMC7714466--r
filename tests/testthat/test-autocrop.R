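test_that("Otsu threshold separates the classes it should", {
  # perfectly bimodal image
  x <- c(rep(10, 400), rep(200, 100))
  thr <- otsu_threshold(x)
  expect_true(all(x[x > thr] == 200) && all(x[x <= thr] == 10))

  # noise-free synthetic field: foreground equals the ground-truth union
  f <- make_synthetic_field(n_nuclei = 2, dim_voxels = c(96, 96, 40),
                            blur_sigma_um = c(0, 0, 0), noise_sd = 0,
                            seed = 5)
  arr <- f$stack$channels$dna
  expect_identical(arr > otsu_threshold(arr), f$truth$nucleus_labels > 0)

  expect_error(otsu_threshold(rep(7, 100)), class = "nucmorph_single_class")
})

test_that("Otsu matches exhaustive between-class-variance maximization", {
  set.seed(99)
  x <- round(pmin(pmax(c(rnorm(1e5, 30, 10), rnorm(1e5, 180, 10)), 0), 255))
  thr <- otsu_threshold(x)
  # brute-force scan over all 256 integer thresholds
  n <- length(x)
  bcv <- vapply(0:254, function(t) {
    w0 <- sum(x <= t)
    if (w0 == 0 || w0 == n) return(-Inf)
    (w0 / n) * (1 - w0 / n) * (mean(x[x <= t]) - mean(x[x > t]))^2
  }, 0)
  best <- which.max(bcv) - 1
  expect_lt(abs(thr - best), 3)
})

test_that("connected components follow 26-connectivity and physical volume", {
  m <- array(FALSE, c(4, 4, 4))
  m[1, 1, 1] <- TRUE
  m[2, 2, 2] <- TRUE  # touching at a corner
  expect_equal(nrow(find_components(m)$table), 1)
  expect_equal(nrow(find_components(m, connectivity = 6)$table), 2)

  m2 <- array(FALSE, c(5, 1, 1))
  m2[c(1, 3), 1, 1] <- TRUE  # separated by one background voxel
  expect_equal(nrow(find_components(m2)$table), 2)

  s <- make_digitized_sphere(5)
  comp <- find_components(s$grid, c(0.1, 0.1, 0.1))
  expect_equal(comp$table$volume_um3, 0.515, tolerance = 1e-9)

  expect_equal(nrow(find_components(array(FALSE, c(3, 3, 3)))$table), 0)
})

test_that("the volume filter keeps components above the threshold only", {
  m <- array(FALSE, c(30, 10, 10))
  m[1:8, 1:8, 1:8] <- TRUE            # 512 voxels
  m[20:22, 1:3, 1:3] <- TRUE          # 27 voxels
  comp <- find_components(m, c(0.1, 0.1, 0.1))  # volumes 0.512 and 0.027
  expect_message(kept <- filter_components(comp, 0.1), "discarded 1")
  expect_equal(nrow(kept$table), 1)
  # a 0.5 um^3 component is discarded by the default 1 um^3 filter
  expect_equal(nrow(filter_components(comp, 1)$table), 0)
  # threshold 0 keeps everything
  expect_equal(nrow(filter_components(comp, 0)$table), 2)
})

test_that("padded boxes clamp to the stack and pad 0 is the tight box", {
  b <- component_to_box(data.frame(x0 = 5, x1 = 10, y0 = 40, y1 = 50,
                                   z0 = 40, z1 = 50),
                        padding_voxels = 20, dim_voxels = c(100, 100, 100))
  expect_equal(b$x0, 0)
  expect_equal(b$width, 31)           # clamp at 0; 10 + 20 = 30 inclusive

  b2 <- component_to_box(data.frame(x0 = 40, x1 = 60, y0 = 40, y1 = 60,
                                    z0 = 40, z1 = 60),
                         padding_voxels = 20, dim_voxels = c(100, 100, 100))
  expect_equal(b2$x0, 20)
  expect_equal(b2$width, 61)

  m <- array(FALSE, c(20, 20, 20))
  m[4:9, 5:6, 7:11] <- TRUE
  b3 <- component_to_box(m, padding_voxels = 0, dim_voxels = dim(m))
  expect_equal(unlist(b3[c("x0", "y0", "z0", "width", "height", "depth")]),
               c(x0 = 3, y0 = 4, z0 = 6, width = 6, height = 2, depth = 5))
})

test_that("box merging unions pairs sharing half the smaller volume", {
  box <- function(x0, w) data.frame(id = 0L, x0 = x0, y0 = 0, z0 = 0,
                                    width = w, height = 10, depth = 10)
  expect_equal(nrow(merge_boxes(rbind(box(0, 10), box(0, 10)))), 1)
  expect_equal(nrow(merge_boxes(rbind(box(0, 10), box(50, 10)))), 2)
  # 10x10x10 boxes sharing a 5x10x10 slab (exactly 50% of the smaller)
  m <- merge_boxes(rbind(box(0, 10), box(5, 10)))
  expect_equal(nrow(m), 1)
  expect_equal(c(m$x0, m$width), c(0, 15))
  # just below the fraction: no merge
  expect_equal(nrow(merge_boxes(rbind(box(0, 10), box(6, 10)))), 2)
  expect_equal(merge_boxes(rbind(box(0, 10), box(3, 10), box(6, 10)))$id, 0L)
})

test_that("autocrop recovers every nucleus and crops are verbatim subgrids", {
  f <- make_synthetic_field(n_nuclei = 9, blur_sigma_um = c(0, 0, 0),
                            noise_sd = 0, seed = 42)
  ac <- autocrop_stack(f$stack, nucmorph_config(), file_name = "field9")
  expect_equal(nrow(ac$table), 9)
  expect_equal(ac$table$id, 0:8)

  lab <- f$truth$nucleus_labels
  contained <- vapply(1:9, function(i) {
    idx <- which(lab == i, arr.ind = TRUE) - 1
    any(vapply(seq_len(nrow(ac$table)), function(j) {
      b <- ac$table[j, ]
      all(idx[, 1] >= b$XStart & idx[, 1] < b$XStart + b$width &
            idx[, 2] >= b$YStart & idx[, 2] < b$YStart + b$height &
            idx[, 3] >= b$ZStart & idx[, 3] < b$ZStart + b$depth)
    }, TRUE))
  }, TRUE)
  expect_true(all(contained))

  # re-inserting all crops at their origins reproduces the source bit-exactly
  src <- f$stack$channels$dna
  rebuilt <- array(NA_real_, dim(src))
  for (j in seq_len(nrow(ac$table))) {
    b <- ac$table[j, ]
    rebuilt[(b$XStart + 1):(b$XStart + b$width),
            (b$YStart + 1):(b$YStart + b$height),
            (b$ZStart + 1):(b$ZStart + b$depth)] <-
      ac$crops[[j]]$channels$dna
  }
  inside <- !is.na(rebuilt)
  expect_true(any(inside))
  expect_identical(rebuilt[inside], src[inside])

  # a constant stack warns and yields zero crops
  flat <- calibrated_stack(array(3, c(16, 16, 8)), c(1, 1, 1))
  expect_warning(res <- autocrop_stack(flat, nucmorph_config()), "constant")
  expect_equal(nrow(res$table), 0)
})

test_that("a seven-bead field yields ids 0 to 6", {
  b <- make_bead_stack(2.5, n_beads = 7, seed = 4)
  ac <- autocrop_stack(b$stack, nucmorph_config(), file_name = "beads")
  expect_equal(ac$table$id, 0:6)
})

test_that("coordinate tables re-crop other channels voxel-identically", {
  f <- make_synthetic_field(n_nuclei = 2, dim_voxels = c(128, 128, 40),
                            fish_channels = c("cy3", "cy5"), seed = 9)
  ac <- autocrop_stack(f$stack, nucmorph_config())
  other <- calibrated_stack(f$stack$channels[c("cy3", "cy5")],
                            f$stack$calibration)
  crops <- crop_other_channels(ac$table, other)
  expect_named(crops, c("cy3", "cy5"))
  for (ch in names(crops)) {
    expect_length(crops[[ch]], nrow(ac$table))
    for (j in seq_along(crops[[ch]]))
      expect_identical(dim(crops[[ch]][[j]]), dim(ac$crops[[j]]))
  }

  small <- calibrated_stack(array(0, c(10, 10, 5)), f$stack$calibration)
  expect_error(crop_other_channels(ac$table, small,
                                   reference_dim = dim(f$stack)),
               "do not match")

  empty <- ac$table[0, ]
  expect_identical(crop_other_channels(empty, other),
                   list(cy3 = list(), cy5 = list()))
})

test_that("coordinate tables and configs round-trip through their files", {
  tab <- data.frame(FileName = "a.tif", id = 0:2, XStart = c(0L, 5L, 9L),
                    YStart = c(1L, 2L, 3L), ZStart = c(0L, 0L, 1L),
                    width = c(10L, 11L, 12L), height = c(9L, 8L, 7L),
                    depth = c(5L, 5L, 5L))
  p <- tempfile(fileext = ".tsv")
  write_coordinate_table(tab, p)
  expect_identical(read_coordinate_table(p), tab)

  cfg <- nucmorph_config(padding_voxels = 12, merge_boxes = FALSE,
                         z_cal_um = 0.25)
  pc <- tempfile(fileext = ".cfg")
  write_config(cfg, pc)
  back <- read_config(pc)
  expect_equal(back[order(names(back))], cfg[order(names(cfg))],
               ignore_attr = TRUE)
})

test_that("stacks written as TIFF read back bit-exactly with all pages", {
  arr <- array(sample(0:65535, 24 * 20 * 6, replace = TRUE), c(24, 20, 6))
  s <- calibrated_stack(arr, c(0.103, 0.103, 0.2))
  p <- tempfile(fileext = ".tif")
  write_stack(s, p)
  back <- read_stack(p, calibration = c(0.103, 0.103, 0.2))
  expect_equal(dim(back), c(24, 20, 6))
  expect_identical(as.numeric(back$channels[[1]]), as.numeric(arr))
})
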