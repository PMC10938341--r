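make_ellipsoid_volume <- function(semi = c(60, 80, 50), vox = 2,
                                  dims = c(80, 96, 64), value = 100) {
  aff <- diag(c(vox, vox, vox, 1))
  aff[1:3, 4] <- -vox * (dims - 1) / 2
  ii <- seq_len(dims[1]) - 1; jj <- seq_len(dims[2]) - 1
  kk <- seq_len(dims[3]) - 1
  wx <- vox * ii + aff[1, 4]; wy <- vox * jj + aff[2, 4]
  wz <- vox * kk + aff[3, 4]
  q <- outer(outer((wx / semi[1])^2, (wy / semi[2])^2, "+"),
             (wz / semi[3])^2, "+")
  qc_volume(array(ifelse(q <= 1, value, 0), dim = dims), aff)
}

test_that("brain bounding box recovers ellipsoid semi-axes and degenerates sanely", {
  vol <- make_ellipsoid_volume()
  box <- brain_bounding_box(vol, 0.1)
  half <- box$extent / 2
  expect_true(all(abs(half - c(60, 80, 50)) <= 2 + 1e-9)) # one voxel
  expect_true(all(abs((box$min + box$max) / 2) <= 2))

  zero <- qc_volume(array(0, dim = c(8, 8, 8)))
  expect_error(brain_bounding_box(zero, 0.1), "threshold")

  pos <- qc_volume(array(5, dim = c(8, 8, 8)))
  full <- brain_bounding_box(pos, 0)
  expect_equal(full$extent, c(7, 7, 7)) # full field of view
})

test_that("default plane selection yields 10 planes split 3/3/4 at the documented fractions", {
  box <- list(min = c(-50, -50, -50), max = c(50, 50, 50),
              extent = c(100, 100, 100))
  planes <- select_slice_planes(box)
  expect_length(planes, 10L)
  ax <- vapply(planes, function(p) p$axis, character(1))
  expect_identical(as.integer(table(ax)[c("axial", "coronal", "sagittal")]),
                   c(3L, 3L, 4L))
  axial_coords <- vapply(planes[ax == "axial"], function(p) p$coord,
                         numeric(1))
  expect_equal(axial_coords, c(-20, 0, 20))
  sag <- vapply(planes[ax == "sagittal"], function(p) p$coord,
                numeric(1))
  expect_false(any(abs(sag) < 1e-9)) # no midline sagittal slice
  expect_true(all(diff(sag) > 0))

  # per-axis positions strictly inside the box
  for (p in planes) {
    k <- c(sagittal = 1, coronal = 2, axial = 3)[[p$axis]]
    expect_gt(p$coord, box$min[k]); expect_lt(p$coord, box$max[k])
  }

  planes20 <- select_slice_planes(box, snapshot_fractions(6, 6, 8))
  expect_length(planes20, 20L)

  expect_error(snapshot_fractions(0, 3, 4), "counts")
  expect_error(
    select_slice_planes(box, list(axial = c(0, 0.5), coronal = 0.5,
                                  sagittal = 0.5)),
    "strictly inside")
})

test_that("icosphere equatorial contour is one closed loop with the analytic perimeter", {
  ico <- make_icosphere(4, radius = 50)
  ct <- slice_contours(ico, slice_plane("axial", 0))
  expect_length(ct, 1L)
  expect_true(ct[[1]]$closed)
  expect_lt(abs(contour_length(ct) - 2 * pi * 50) / (2 * pi * 50), 0.01)
})

test_that("torus symmetry plane gives two closed loops at the analytic radii", {
  tor <- make_torus(30, 10, 64, 32)
  ct <- slice_contours(tor, slice_plane("axial", 0))
  expect_length(ct, 2L)
  expect_true(all(vapply(ct, function(x) x$closed, logical(1))))
  radii <- sort(vapply(ct, function(x)
    mean(sqrt(rowSums(x$points^2))), numeric(1)))
  expect_equal(radii, c(20, 40), tolerance = 0.02)
})

test_that("plane outside the mesh yields no contours", {
  expect_length(slice_contours(make_icosphere(2, radius = 10),
                               slice_plane("axial", 50)), 0L)
})

test_that("chained contour length matches brute-force segment enumeration on random pairs", {
  set.seed(101)
  for (rep in 1:100) {
    mesh <- random_mesh()
    plane <- random_plane(mesh)
    chained <- contour_length(slice_contours(mesh, plane))
    brute <- brute_contour_length(mesh, plane)
    expect_lt(abs(chained - brute), 1e-9)
  }
})

test_that("closed meshes give closed polylines, invariant to vertex permutation", {
  set.seed(102)
  for (rep in 1:10) {
    mesh <- random_mesh()
    plane <- random_plane(mesh)
    ct <- slice_contours(mesh, plane)
    expect_true(all(vapply(ct, function(x) x$closed, logical(1))))
    perm <- sample(nrow(mesh$vertices))
    inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
    m2 <- tri_mesh(mesh$vertices[perm, , drop = FALSE],
                   matrix(inv[mesh$faces], ncol = 3L))
    ct2 <- slice_contours(m2, plane)
    expect_identical(length(ct2), length(ct))
    expect_equal(contour_length(ct2), contour_length(ct),
                 tolerance = 1e-9)
  }
})

test_that("nearest-neighbour slice sampling preserves raw values and scales with pixel size", {
  vol <- make_ellipsoid_volume(semi = c(40, 40, 40), vox = 2,
                               dims = c(64, 64, 64), value = 100)
  pl <- slice_plane("axial", 0)
  s1 <- extract_slice_image(vol, pl, pixel_size = 2)
  expect_setequal(unique(as.vector(s1$image)), c(0, 100))
  s2 <- extract_slice_image(vol, pl, pixel_size = 1)
  expect_true(all(abs(dim(s2$image) - 2 * dim(s1$image)) <= 2))
  s3 <- extract_slice_image(vol, pl, pixel_size = 2)
  expect_identical(s1$image, s3$image)
  # plane beyond the volume flags empty
  far <- extract_slice_image(vol, slice_plane("axial", 500), 2)
  expect_true(far$empty)
})

test_that("snapshot rendering is deterministic and handles empty contours", {
  vol <- make_ellipsoid_volume(semi = c(40, 40, 40), vox = 2,
                               dims = c(64, 64, 64))
  pl <- slice_plane("axial", 0)
  s <- extract_slice_image(vol, pl, 2)
  ct <- list(pial = slice_contours(make_icosphere(3, radius = 40), pl))
  p1 <- withr_local_file("r1.png"); p2 <- withr_local_file("r2.png")
  render_snapshot(s, ct, p1)
  render_snapshot(s, ct, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  p3 <- withr_local_file("plain.png")
  render_snapshot(s, list(), p3)
  expect_true(file.exists(p3))
})

test_that("phantom subject produces exactly 10 snapshots (20 in the doubled config)", {
  ph <- make_phantom_subject(phantom_config(
    grid_size = c(48, 56, 48), voxel_size = 4, subdivisions = 2L))
  d1 <- withr_local_file("snaps10"); dir.create(d1, showWarnings = FALSE)
  rows <- generate_subject_snapshots(ph$bundle, d1, pixel_size = 4)
  expect_identical(nrow(rows), 10L)
  expect_identical(as.integer(table(rows$axis)[c("axial", "coronal",
                                             "sagittal")]),
                   c(3L, 3L, 4L))
  expect_true(all(file.exists(file.path(d1, rows$filename))))

  d2 <- withr_local_file("snaps20"); dir.create(d2, showWarnings = FALSE)
  rows20 <- generate_subject_snapshots(
    ph$bundle, d2, fractions = snapshot_fractions(6, 6, 8),
    pixel_size = 4)
  expect_identical(nrow(rows20), 20L)
})

test_that("a plane missing every surface still renders, flagged in the manifest", {
  # bright slab fills the top of the volume; meshes sit far below
  dims <- c(32, 32, 32)
  aff <- diag(c(2, 2, 2, 1)); aff[1:3, 4] <- -c(31, 31, 31)
  dat <- array(100, dim = dims)
  vol <- qc_volume(dat, aff)
  tiny <- make_icosphere(1, radius = 3, center = c(0, 0, -25))
  bundle <- subject_bundle("edge01", vol,
                           list(lh_white = tiny, lh_pial = tiny,
                                rh_white = tiny, rh_pial = tiny))
  d <- withr_local_file("snaps_edge"); dir.create(d, showWarnings = FALSE)
  rows <- generate_subject_snapshots(bundle, d, pixel_size = 4,
                                     intensity_fraction = 0)
  expect_identical(nrow(rows), 10L)
  expect_true(any(rows$no_contour_flag))
})

test_that("anonymization is a seeded, salted, reversible bijection", {
  rows <- data.frame(
    subject_id = rep(sprintf("s%02d", 1:3), each = 10),
    axis = "axial", slice_index = 1:10, world_coord = 0,
    filename = sprintf("s%02d_ax_%02d.png", rep(1:3, each = 10), 1:10),
    n_contours = 1L, no_contour_flag = FALSE, stringsAsFactors = FALSE)
  m1 <- anonymize_and_shuffle(rows, seed = 99, salt = "abc")
  m2 <- anonymize_and_shuffle(rows, seed = 99, salt = "abc")
  expect_identical(m1$shuffle_position, m2$shuffle_position)
  expect_identical(m1$image_hash, m2$image_hash)
  expect_true(all(grepl("^[0-9a-f]{32}$", m1$image_hash)))
  expect_identical(sort(m1$shuffle_position), 1:30)
  # bijection: inverse lookup of every row
  expect_identical(deanonymize(m1, m1$image_hash), m1$filename)
  expect_false(anyDuplicated(m1$image_hash) > 0)
  # different salt changes every hash
  m3 <- anonymize_and_shuffle(rows, seed = 99, salt = "other")
  expect_false(any(m3$image_hash == m1$image_hash))
  # manifest round trip
  p <- withr_local_file("manifest.json")
  write_manifest(m1, p)
  back <- read_manifest(p)
  expect_identical(back$image_hash, m1$image_hash)
  expect_identical(attr(back, "salt"), "abc")
})
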