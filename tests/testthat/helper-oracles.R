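# Independent oracles and shared fixture builders for the test suite.

# Brute-force O(n^3) convex hull: an ordered pair (i, j) is a hull edge when
# every other point lies strictly on one side. Returns sorted vertex indices.
brute_hull_vertices <- function(pts) {
  n <- nrow(pts)
  verts <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      rest <- setdiff(seq_len(n), c(i, j))
      if (length(rest) == 0) { verts[c(i, j)] <- TRUE; next }
      cr <- (pts[j, 1] - pts[i, 1]) * (pts[rest, 2] - pts[i, 2]) -
        (pts[j, 2] - pts[i, 2]) * (pts[rest, 1] - pts[i, 1])
      if (all(cr > 0) || all(cr < 0)) verts[c(i, j)] <- TRUE
    }
  }
  which(verts)
}

# Batched 3D convex-hull membership via scipy's Delaunay triangulation
# (qhull), used as the independent oracle for hull-boundedness. `pairs` is a
# list of list(base = n x 3 matrix, query = m x 3 matrix); returns for each
# pair the number of query points inside the hull and the query count.
scipy_hull_containment <- function(pairs) {
  dir <- tempfile("hull")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  for (k in seq_along(pairs)) {
    write.table(pairs[[k]]$base, file.path(dir, sprintf("base%04d.csv", k)),
                sep = ",", row.names = FALSE, col.names = FALSE)
    write.table(pairs[[k]]$query, file.path(dir, sprintf("query%04d.csv", k)),
                sep = ",", row.names = FALSE, col.names = FALSE)
  }
  script <- file.path(dir, "check.py")
  writeLines(c(
    "import glob, os, sys",
    "import numpy as np",
    "from scipy.spatial import Delaunay",
    sprintf("d = %s", deparse(dir)),
    "for bf in sorted(glob.glob(os.path.join(d, 'base*.csv'))):",
    "    qf = bf.replace('base', 'query')",
    "    base = np.loadtxt(bf, delimiter=',')",
    "    query = np.loadtxt(qf, delimiter=',')",
    "    if query.size == 0:",
    "        print(0, 0); continue",
    "    if query.ndim == 1: query = query.reshape(1, -1)",
    "    tri = Delaunay(base)",
    "    print(int((tri.find_simplex(query) >= 0).sum()), len(query))"
  ), script)
  out <- system2("python", script, stdout = TRUE)
  do.call(rbind, lapply(strsplit(out, " "), as.integer))
}

# Voxel-cell corners of a mask in physical coordinates (for hull oracles the
# solid voxel set is the union of cells, whose hull is the hull of corners).
voxel_centers_um <- function(mask, calibration) {
  sweep(which(mask, arr.ind = TRUE) - 1, 2, calibration, `*`)
}

# Concavity depth of a mask: the slice-hull closure (unrestricted wrap) minus
# the mask, measured by the closure's interior distance transform.
concavity_depth <- function(nmask) {
  closure <- gift_wrap_segment(NULL, nmask, td = Inf)$mask
  gap <- closure & !nmask$mask
  if (!any(gap)) return(0)
  edt <- nucmorph:::cpp_edt(closure, dim(closure), nmask$calibration)
  max(edt[gap])
}

is_hole_free <- function(mask) {
  m <- if (is.list(mask)) mask$mask else mask
  filled <- nucmorph:::cpp_fill_holes3d(m, dim(m))
  all(filled == m)
}

# A 3D intensity crop with a spherical "nucleus" and analytic domain blobs,
# for watershed tests that need exact control of peaks and necks.
blob_crop <- function(radius = 12, nucleoplasm = 20,
                      blobs = NULL, calibration = c(1, 1, 1)) {
  n <- 2 * radius + 7
  cc <- radius + 4
  ax2 <- (seq_len(n) - cc)^2
  mask <- array(FALSE, c(n, n, n))
  for (z in seq_len(n)) mask[, , z] <- outer(ax2, ax2, `+`) + ax2[z] <= radius^2
  img <- array(0, c(n, n, n))
  img[mask] <- nucleoplasm
  if (!is.null(blobs)) {
    co <- which(array(TRUE, dim(img)), arr.ind = TRUE)
    for (b in blobs) {
      d2 <- (co[, 1] - cc - b$at[1])^2 + (co[, 2] - cc - b$at[2])^2 +
        (co[, 3] - cc - b$at[3])^2
      img <- img + array(b$amp * exp(-d2 / (2 * b$sigma^2)), dim(img)) *
        ifelse(mask, 1, 0)
    }
  }
  list(img = img, mask = mask, center = cc,
       nucleus = nucleus_mask(mask, calibration, "otsu", "blob"))
}
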