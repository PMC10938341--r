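#' Icosphere mesh
#'
#' Icosahedron subdivided `subdivisions` times with vertices projected
#' onto the sphere; subdivision k has `2 + 10 * 4^k` vertices and
#' `20 * 4^k` faces.
#'
#' @param subdivisions Non-negative integer.
#' @param radius Sphere radius (mm), or length-3 for an ellipsoid
#'   (per-axis semi-axes).
#' @param center Length-3 center.
#' @return A closed [tri_mesh].
#' @export
make_icosphere <- function(subdivisions = 2L, radius = 1,
                           center = c(0, 0, 0)) {
  stopifnot(subdivisions >= 0L)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    midcache <- new.env(hash = TRUE)
    newv <- list()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      got <- midcache[[key]]
      if (!is.null(got)) return(got)
      p <- (v[a, ] + v[b, ]) / 2
      p <- p / sqrt(sum(p^2))
      newv[[length(newv) + 1L]] <<- p
      id <- nv + length(newv)
      midcache[[key]] <- id
      id
    }
    newf <- matrix(0L, nrow(f) * 4L, 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newf[(i - 1L) * 4L + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                           c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- newf
  }
  radius <- rep(radius, length.out = 3L)
  v <- sweep(sweep(v, 2L, radius, "*"), 2L, center, "+")
  tri_mesh(v, f)
}

#' Torus mesh
#'
#' Parametric torus on an `m x n` grid: major radius `R` in the x-y
#' plane, tube radius `r`.
#'
#' @param R Major radius (> r).
#' @param r Minor (tube) radius (> 0).
#' @param m Number of segments around the major circle (>= 3).
#' @param n Number of segments around the tube (>= 3).
#' @param center Length-3 center.
#' @return A closed [tri_mesh] with `m*n` vertices and `2*m*n` faces.
#' @export
make_torus <- function(R = 30, r = 10, m = 48L, n = 24L,
                       center = c(0, 0, 0)) {
  stopifnot(R > r, r > 0, m >= 3L, n >= 3L)
  uu <- 2 * pi * (seq_len(m) - 1L) / m
  vv <- 2 * pi * (seq_len(n) - 1L) / n
  idx <- function(i, j) ((i - 1L) %% m) * n + ((j - 1L) %% n) + 1L
  verts <- matrix(0, m * n, 3L)
  for (i in seq_len(m)) for (j in seq_len(n)) {
    verts[idx(i, j), ] <- c(
      (R + r * cos(vv[j])) * cos(uu[i]),
      (R + r * cos(vv[j])) * sin(uu[i]),
      r * sin(vv[j]))
  }
  faces <- matrix(0L, 2L * m * n, 3L)
  k <- 0L
  for (i in seq_len(m)) for (j in seq_len(n)) {
    a <- idx(i, j); b <- idx(i + 1L, j)
    cc <- idx(i + 1L, j + 1L); d <- idx(i, j + 1L)
    faces[k + 1L, ] <- c(a, b, cc)
    faces[k + 2L, ] <- c(a, cc, d)
    k <- k + 2L
  }
  verts <- sweep(verts, 2L, center, "+")
  tri_mesh(verts, faces)
}

#' Attach a topological handle to a closed mesh
#'
#' Removes two vertex-disjoint faces and stitches a triangulated tube
#' (six new triangles, six new edges, no new vertices) between their
#' boundary loops, lowering the Euler characteristic by exactly 2 —
#' the synthetic equivalent of one surface-reconstruction defect.
#'
#' @param mesh A closed [tri_mesh] with at least 8 faces.
#' @param seed Integer seed selecting the attachment site.
#' @return A [tri_mesh] with one more handle.
#' @export
add_handle <- function(mesh, seed = 1L) {
  f <- mesh$faces
  if (nrow(f) < 8L)
    stop("mesh too small to attach a handle (< 8 faces)", call. = FALSE)
  # an admissible pair shares no vertex and no pre-existing edge between
  # the two vertex sets, so the tube adds exactly 6 new edges
  nv <- nrow(mesh$vertices)
  e_all <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  ekeys <- (as.numeric(pmin(e_all[, 1], e_all[, 2])) - 1) * nv +
    as.numeric(pmax(e_all[, 1], e_all[, 2]))
  admissible <- function(a, b) {
    if (any(b %in% a)) return(FALSE)
    cross <- expand.grid(a, b)
    ck <- (as.numeric(pmin(cross[, 1], cross[, 2])) - 1) * nv +
      as.numeric(pmax(cross[, 1], cross[, 2]))
    !any(ck %in% ekeys)
  }
  pick <- with_preserved_seed(seed, {
    found <- NULL
    for (i in sample.int(nrow(f))) {
      cand <- which(vapply(seq_len(nrow(f)), function(j)
        j != i && admissible(f[i, ], f[j, ]), logical(1)))
      if (length(cand)) { found <- c(i, sample(cand, 1L)); break }
    }
    if (is.null(found))
      stop("no admissible face pair for handle attachment",
           call. = FALSE)
    found
  })
  a <- f[pick[1], ]; b <- f[pick[2], ]
  keep <- f[-pick, , drop = FALSE]
  tube <- rbind(c(a[1], a[2], b[1]), c(a[2], b[2], b[1]),
                c(a[2], a[3], b[2]), c(a[3], b[3], b[2]),
                c(a[3], a[1], b[3]), c(a[1], b[1], b[3]))
  tri_mesh(mesh$vertices, rbind(keep, tube))
}
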