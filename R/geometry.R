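#' Axis-aligned world-mm bounding box of the bright tissue
#'
#' The tightest axis-aligned box (in world mm) containing every voxel
#' whose intensity exceeds `intensity_fraction` times the volume maximum.
#' Used to place slice planes relative to the brain rather than the
#' field of view, so views avoid the edges of the head.
#'
#' @param vol A [qc_volume]; must be non-constant.
#' @param intensity_fraction Threshold as a fraction of the maximum
#'   intensity, in `[0, 1)`. Default 0.1.
#' @return List with `min` and `max` (length-3 world mm) and `extent`.
#' @export
brain_bounding_box <- function(vol, intensity_fraction = 0.1) {
  mx <- max(vol$data)
  thr <- intensity_fraction * mx
  idx <- which(vol$data > thr, arr.ind = TRUE)
  if (!nrow(idx))
    stop("no voxel exceeds the intensity threshold (fraction ",
         intensity_fraction, ")", call. = FALSE)
  w <- voxel_to_world(vol, idx - 1L)
  lo <- apply(w, 2L, min)
  hi <- apply(w, 2L, max)
  list(min = lo, max = hi, extent = hi - lo)
}

PLANE_AXES <- c(axial = 3L, coronal = 2L, sagittal = 1L)

#' Construct a slice plane
#'
#' Axis-aligned cutting plane with an in-plane orthonormal basis. Plane
#' coordinates of a world point P are `((P - origin) . u, (P - origin) . v)`
#' in mm.
#'
#' @param axis `"axial"` (z normal), `"coronal"` (y) or `"sagittal"` (x).
#' @param world_coordinate Position along the axis normal, mm.
#' @param origin Length-3 world point on the plane where plane
#'   coordinates are (0, 0); its normal component is forced to
#'   `world_coordinate`.
#' @return An object of class `slice_plane` with fields `axis`, `coord`,
#'   `normal`, `u`, `v`, `origin`.
#' @export
slice_plane <- function(axis, world_coordinate, origin = c(0, 0, 0)) {
  axis <- match.arg(axis, names(PLANE_AXES))
  k <- PLANE_AXES[[axis]]
  normal <- numeric(3L); normal[k] <- 1
  basis <- switch(axis,
    axial = list(u = c(1, 0, 0), v = c(0, 1, 0)),
    coronal = list(u = c(1, 0, 0), v = c(0, 0, 1)),
    sagittal = list(u = c(0, 1, 0), v = c(0, 0, 1)))
  origin <- as.numeric(origin)
  origin[k] <- world_coordinate
  structure(list(axis = axis, coord = world_coordinate, normal = normal,
                 u = basis$u, v = basis$v, origin = origin),
            class = "slice_plane")
}

#' Select the snapshot slice planes inside a brain bounding box
#'
#' The default yields 10 planes: 3 axial and 3 coronal at fractions
#' 0.30/0.50/0.70 of the box extent, and 4 sagittal at
#' 0.25/0.40/0.60/0.75 (two per hemisphere, avoiding the midline).
#' Fractions must lie strictly inside (0, 1) so no plane touches the box
#' edge.
#'
#' @param box Bounding box from [brain_bounding_box()].
#' @param fractions Named list of per-axis fraction vectors; defaults to
#'   `snapshot_fractions()`.
#' @return List of [slice_plane]s ordered axial, coronal, sagittal.
#' @export
select_slice_planes <- function(box, fractions = snapshot_fractions()) {
  if (any(box$extent <= 0)) stop("degenerate bounding box", call. = FALSE)
  planes <- list()
  for (axis in c("axial", "coronal", "sagittal")) {
    fr <- fractions[[axis]]
    if (is.null(fr) || length(fr) < 1L)
      stop("fractions must provide at least one position per axis",
           call. = FALSE)
    if (any(fr <= 0 | fr >= 1))
      stop("slice fractions must lie strictly inside (0, 1)",
           call. = FALSE)
    fr <- sort(fr)
    k <- PLANE_AXES[[axis]]
    coords <- box$min[k] + fr * box$extent[k]
    for (w in coords)
      planes[[length(planes) + 1L]] <- slice_plane(axis, w,
                                                   origin = box$min)
  }
  planes
}

#' Default per-axis slice fractions
#'
#' @param n_axial,n_coronal,n_sagittal Per-axis slice counts. The
#'   defaults (3/3/4) reproduce the standard 10-view set; other counts
#'   space slices evenly inside (0.2, 0.8), sagittal positions skipping
#'   the midline.
#' @export
snapshot_fractions <- function(n_axial = 3L, n_coronal = 3L,
                               n_sagittal = 4L) {
  if (n_axial < 1L || n_coronal < 1L || n_sagittal < 1L)
    stop("slice counts must be >= 1", call. = FALSE)
  even <- function(n) seq(0.2, 0.8, length.out = n + 2L)[-c(1L, n + 2L)]
  ax <- if (n_axial == 3L) c(0.30, 0.50, 0.70) else even(n_axial)
  co <- if (n_coronal == 3L) c(0.30, 0.50, 0.70) else even(n_coronal)
  sa <- if (n_sagittal == 4L) c(0.25, 0.40, 0.60, 0.75) else {
    # avoid the midline: half the positions on each side of 0.5
    nl <- ceiling(n_sagittal / 2); nr <- n_sagittal - nl
    c(seq(0.2, 0.45, length.out = nl), seq(0.55, 0.8, length.out = max(nr, 1L))[seq_len(nr)])
  }
  list(axial = ax, coronal = co, sagittal = sa)
}

#' Intersect a triangle mesh with a plane and chain the contours
#'
#' For every triangle whose vertices straddle the plane, the
#' intersection segment is obtained by linear interpolation of signed
#' vertex distances along the two crossing edges. Each intersection
#' point lies on a unique mesh edge, and edges are keyed canonically
#' (smaller vertex index first) so that triangles sharing an edge
#' produce bit-identical endpoints; segments are then chained into
#' maximal polylines by walking shared edge keys. Vertices lying exactly
#' on the plane (|distance| < 1e-9 mm) are nudged by +1e-9 mm, a
#' simulation-of-simplicity perturbation avoiding degenerate cases.
#'
#' @param mesh A [tri_mesh].
#' @param plane A [slice_plane].
#' @param tol Chaining tolerance in mm (endpoints are matched exactly
#'   through edge keys; `tol` only governs the closed-polyline check).
#' @return List of polylines; each is a list with `points` (k x 2 matrix
#'   of plane-mm coordinates, first point repeated at the end when
#'   closed) and `closed` (logical). Empty list when no intersection.
#' @export
slice_contours <- function(mesh, plane, tol = 1e-6) {
  stopifnot(tol > 0)
  k <- PLANE_AXES[[plane$axis]]
  d <- mesh$vertices[, k] - plane$coord
  d[abs(d) < 1e-9] <- 1e-9
  f <- mesh$faces
  s <- d > 0
  cross_tri <- which(!(s[f[, 1]] & s[f[, 2]] & s[f[, 3]]) &
                       (s[f[, 1]] | s[f[, 2]] | s[f[, 3]]))
  if (!length(cross_tri)) return(list())
  ft <- f[cross_tri, , drop = FALSE]
  n_v <- nrow(mesh$vertices)
  edge_key <- function(a, b) {
    lo <- pmin(a, b); hi <- pmax(a, b)
    (as.numeric(lo) - 1) * n_v + as.numeric(hi)
  }
  # per triangle: the two crossing edges among (1,2),(2,3),(3,1)
  ek <- matrix(NA_real_, nrow = length(cross_tri), ncol = 2L)
  pair <- cbind(c(1L, 2L, 3L), c(2L, 3L, 1L))
  for (i in seq_len(nrow(ft))) {
    tri <- ft[i, ]
    crossing <- which(s[tri[pair[, 1]]] != s[tri[pair[, 2]]])
    ek[i, ] <- edge_key(tri[pair[crossing, 1]], tri[pair[crossing, 2]])
  }
  keys <- unique(as.numeric(ek))
  lo <- floor((keys - 1) / n_v) + 1
  hi <- keys - (lo - 1) * n_v
  t_par <- d[lo] / (d[lo] - d[hi])
  pts3 <- mesh$vertices[lo, , drop = FALSE] +
    t_par * (mesh$vertices[hi, , drop = FALSE] -
               mesh$vertices[lo, , drop = FALSE])
  rel <- sweep(pts3, 2L, plane$origin, "-")
  pts2 <- cbind(rel %*% plane$u, rel %*% plane$v)
  idx <- match(as.numeric(ek), keys)
  seg <- matrix(idx, ncol = 2L) # segment endpoints as point indices
  chain_segments(seg, pts2, tol)
}

# Chain segments (rows of point-index pairs) into maximal polylines.
chain_segments <- function(seg, pts2, tol) {
  n_pts <- nrow(pts2)
  adj <- vector("list", n_pts) # incident segment ids per point
  for (si in seq_len(nrow(seg))) {
    a <- seg[si, 1]; b <- seg[si, 2]
    adj[[a]] <- c(adj[[a]], si)
    adj[[b]] <- c(adj[[b]], si)
  }
  used <- logical(nrow(seg))
  deg <- lengths(adj)
  out <- list()
  walk <- function(start_pt) {
    path <- start_pt
    cur <- start_pt
    repeat {
      nxt_seg <- adj[[cur]][!used[adj[[cur]]]]
      if (!length(nxt_seg)) break
      si <- nxt_seg[1]
      used[si] <<- TRUE
      cur <- if (seg[si, 1] == cur) seg[si, 2] else seg[si, 1]
      path <- c(path, cur)
    }
    path
  }
  starts <- which(deg == 1L)
  for (sp in starts) {
    if (all(used[adj[[sp]]])) next
    path <- walk(sp)
    out[[length(out) + 1L]] <- path
  }
  # remaining segments form cycles
  for (si in seq_len(nrow(seg))) {
    if (used[si]) next
    used[si] <- TRUE
    start_pt <- seg[si, 1]
    path <- c(start_pt, seg[si, 2])
    cur <- seg[si, 2]
    repeat {
      nxt_seg <- adj[[cur]][!used[adj[[cur]]]]
      if (!length(nxt_seg)) break
      s2 <- nxt_seg[1]
      used[s2] <- TRUE
      cur <- if (seg[s2, 1] == cur) seg[s2, 2] else seg[s2, 1]
      path <- c(path, cur)
    }
    out[[length(out) + 1L]] <- path
  }
  lapply(out, function(path) {
    p <- pts2[path, , drop = FALSE]
    closed <- length(path) > 2L &&
      sqrt(sum((p[1, ] - p[nrow(p), ])^2)) <= tol
    list(points = p, closed = closed)
  })
}

#' Total length of a contour set
#' @param contours Output of [slice_contours()].
#' @return Sum of polyline segment lengths, mm.
#' @export
contour_length <- function(contours) {
  sum(vapply(contours, function(pl) {
    p <- pl$points
    if (nrow(p) < 2L) return(0)
    sum(sqrt(rowSums((p[-1, , drop = FALSE] -
                        p[-nrow(p), , drop = FALSE])^2)))
  }, numeric(1)))
}

#' Sample a volume on a slice plane
#'
#' Nearest-neighbour lookup in voxel space (the default preserves raw
#' intensity values, so artifacts such as ringing survive resampling);
#' set `interpolation = "linear"` for trilinear sampling.
#'
#' @param vol A [qc_volume].
#' @param plane A [slice_plane].
#' @param pixel_size Pixel spacing in mm.
#' @param interpolation `"nearest"` (default) or `"linear"`.
#' @return List: `image` (matrix, rows index the plane's u axis, columns
#'   v), `a0`, `b0` (plane-mm coordinates of pixel (1,1) centre),
#'   `pixel_size`, `empty` (TRUE when the plane misses the volume), and
#'   `plane`. Plane mm (a, b) map to pixel `((a - a0)/pixel_size + 1,
#'   (b - b0)/pixel_size + 1)`.
#' @export
extract_slice_image <- function(vol, plane, pixel_size = 1,
                                interpolation = c("nearest", "linear")) {
  stopifnot(pixel_size > 0)
  interpolation <- match.arg(interpolation)
  dims <- dim(vol$data)
  corners <- as.matrix(expand.grid(c(0, dims[1] - 1), c(0, dims[2] - 1),
                                   c(0, dims[3] - 1)))
  cw <- voxel_to_world(vol, corners)
  k <- PLANE_AXES[[plane$axis]]
  empty <- plane$coord < min(cw[, k]) || plane$coord > max(cw[, k])
  rel <- sweep(cw, 2L, plane$origin, "-")
  a_rng <- range(rel %*% plane$u)
  b_rng <- range(rel %*% plane$v)
  na <- max(2L, ceiling(diff(a_rng) / pixel_size))
  nb <- max(2L, ceiling(diff(b_rng) / pixel_size))
  a0 <- a_rng[1] + pixel_size / 2
  b0 <- b_rng[1] + pixel_size / 2
  av <- a0 + (seq_len(na) - 1L) * pixel_size
  bv <- b0 + (seq_len(nb) - 1L) * pixel_size
  grid <- cbind(rep(av, times = nb), rep(bv, each = na))
  world <- matrix(plane$origin, nrow = nrow(grid), ncol = 3L,
                  byrow = TRUE) +
    grid[, 1] %o% plane$u + grid[, 2] %o% plane$v
  vox <- world_to_voxel(vol, world)
  val <- if (interpolation == "nearest") {
    ij <- round(vox) + 1
    ok <- ij[, 1] >= 1 & ij[, 1] <= dims[1] & ij[, 2] >= 1 &
      ij[, 2] <= dims[2] & ij[, 3] >= 1 & ij[, 3] <= dims[3]
    v <- numeric(nrow(ij))
    v[ok] <- vol$data[ij[ok, , drop = FALSE]]
    v
  } else {
    trilinear_sample(vol$data, vox)
  }
  list(image = matrix(val, nrow = na, ncol = nb), a0 = a0, b0 = b0,
       pixel_size = pixel_size, empty = empty, plane = plane)
}

trilinear_sample <- function(arr, vox) {
  dims <- dim(arr)
  f <- pmin(pmax(vox, 0), matrix(dims - 1, nrow(vox), 3L, byrow = TRUE))
  i0 <- pmin(floor(f), matrix(dims - 2, nrow(vox), 3L, byrow = TRUE))
  w <- f - i0
  acc <- numeric(nrow(vox))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wt <- (dx * w[, 1] + (1 - dx) * (1 - w[, 1])) *
      (dy * w[, 2] + (1 - dy) * (1 - w[, 2])) *
      (dz * w[, 3] + (1 - dz) * (1 - w[, 3]))
    idx <- cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz) + 1
    acc <- acc + wt * arr[idx]
  }
  acc
}
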