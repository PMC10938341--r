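# Independent brute-force oracles used across tests. These deliberately
# avoid the package's code paths (no chaining, no p.adjust shortcuts).

# Per-triangle plane-intersection segment lengths, no chaining.
brute_contour_length <- function(mesh, plane) {
  k <- switch(plane$axis, sagittal = 1L, coronal = 2L, axial = 3L)
  d <- mesh$vertices[, k] - plane$coord
  d[abs(d) < 1e-9] <- 1e-9
  total <- 0
  for (i in seq_len(nrow(mesh$faces))) {
    tri <- mesh$faces[i, ]
    dd <- d[tri]
    pos <- dd > 0
    if (all(pos) || all(!pos)) next
    pts <- list()
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      a <- tri[e[1]]; b <- tri[e[2]]
      if ((d[a] > 0) == (d[b] > 0)) next
      t <- d[a] / (d[a] - d[b])
      pts[[length(pts) + 1L]] <- mesh$vertices[a, ] +
        t * (mesh$vertices[b, ] - mesh$vertices[a, ])
    }
    if (length(pts) == 2L)
      total <- total + sqrt(sum((pts[[1]] - pts[[2]])^2))
  }
  total
}

# Independent edge-set construction for Euler characteristic.
brute_euler <- function(mesh) {
  keys <- character(0)
  for (i in seq_len(nrow(mesh$faces))) {
    tri <- sort(mesh$faces[i, ])
    keys <- c(keys, paste(tri[1], tri[2]), paste(tri[1], tri[3]),
              paste(tri[2], tri[3]))
  }
  nrow(mesh$vertices) - length(unique(keys)) + nrow(mesh$faces)
}

# Step-up threshold scan for Benjamini-Hochberg significance flags.
brute_bh_flags <- function(p, level = 0.05) {
  m <- length(p)
  o <- order(p)
  flags <- logical(m)
  kmax <- 0L
  for (k in seq_len(m)) if (p[o[k]] <= level * k / m) kmax <- k
  if (kmax > 0L) flags[o[seq_len(kmax)]] <- TRUE
  flags
}

# MAD outlier filter + nested medians, re-implemented directly.
brute_deliberation <- function(times_s, subject, outlier_mad = 5) {
  med <- median(times_s)
  md <- median(abs(times_s - med))
  keep <- if (md > 0) abs(times_s - med) <= outlier_mad * md
          else times_s <= outlier_mad * med
  per_part <- tapply(times_s[keep], subject[keep], median)
  list(median_s = median(per_part), n_removed = sum(!keep))
}

# ANOVA mean squares for ICC(A,1) via aov.
aov_icc_a1 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  df <- data.frame(y = as.vector(m),
                   row = factor(rep(seq_len(n), times = k)),
                   col = factor(rep(seq_len(k), each = n)))
  tab <- summary(stats::aov(y ~ row + col, data = df))[[1]]
  msr <- tab["row", "Mean Sq"]; msc <- tab["col", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Tiny valid cohort for filter/analysis edge cases.
toy_cohort <- function(fsqc, site = "s1", diagnosis = NULL) {
  n <- length(fsqc)
  if (is.null(diagnosis)) diagnosis <- rep(0L, n)
  cohort_table(data.frame(
    subject_id = sprintf("p%02d", seq_len(n)), age = rep(20, n),
    sex = rep(0L, n), diagnosis = diagnosis,
    site = rep_len(site, n), fsqc = fsqc,
    stringsAsFactors = FALSE), qc_cols = "fsqc")
}

# Random closed test meshes: ellipsoidal icospheres and tori.
random_mesh <- function() {
  if (runif(1) < 0.5) {
    make_icosphere(sample(1:3, 1), radius = runif(3, 10, 60),
                   center = runif(3, -20, 20))
  } else {
    R <- runif(1, 20, 40)
    make_torus(R, runif(1, 5, R / 2 - 1), sample(12:32, 1),
               sample(8:16, 1), center = runif(3, -10, 10))
  }
}

random_plane <- function(mesh) {
  axis <- sample(c("axial", "coronal", "sagittal"), 1)
  k <- switch(axis, sagittal = 1L, coronal = 2L, axial = 3L)
  rng <- range(mesh$vertices[, k])
  slice_plane(axis, runif(1, rng[1] + 0.05 * diff(rng),
                          rng[2] - 0.05 * diff(rng)))
}

# Scratch file path under a per-session test directory.
withr_local_file <- function(name) {
  d <- file.path(tempdir(), "surfqc-tests")
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  file.path(d, name)
}
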