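#' Configuration for a synthetic phantom subject
#'
#' A two-hemisphere ellipsoid "brain": a CSF background, a grey-matter
#' shell between the inner (white-like) and outer (pial-like)
#' ellipsoids and a white-matter core, with optional multiplicative
#' ripple (the synthetic stand-in for motion ringing) and Gaussian
#' noise. Meshes are subdivided ellipsoids at the two tissue
#' boundaries, in the same world frame as the volume.
#'
#' @param grid_size Length-3 voxel grid dimensions.
#' @param voxel_size Isotropic voxel size, mm.
#' @param outer_semiaxes Length-3 pial-like semi-axes per hemisphere,
#'   mm (x = half-width of one hemisphere).
#' @param inner_scale White-like ellipsoid as a fraction of the outer
#'   (strictly < 1).
#' @param hemi_offset Distance of each hemisphere center from the
#'   midline along x, mm.
#' @param intensities Named CSF/GM/WM intensities (distinct).
#' @param ripple `NULL`, or list(amplitude (fraction in [0,1)),
#'   frequency (cycles/mm), axis (1-3)).
#' @param handles Per-hemisphere handle counts (length 2, lh/rh) to
#'   inject topology defects into the white meshes.
#' @param noise_sd Additive Gaussian noise SD (intensity units).
#' @param subdivisions Mesh subdivision level.
#' @param seed Integer seed.
#' @export
phantom_config <- function(grid_size = c(96L, 112L, 96L), voxel_size = 2,
                           outer_semiaxes = c(28, 75, 60),
                           inner_scale = 0.72, hemi_offset = 30,
                           intensities = c(CSF = 30, GM = 80, WM = 110),
                           ripple = NULL, handles = c(0L, 0L),
                           noise_sd = 0, subdivisions = 3L, seed = 1L) {
  if (inner_scale <= 0 || inner_scale >= 1)
    stop("inner ellipsoid must lie strictly inside the outer",
         call. = FALSE)
  if (length(unique(intensities)) != 3L)
    stop("tissue intensities must be distinct", call. = FALSE)
  if (!is.null(ripple) &&
      (ripple$amplitude < 0 || ripple$amplitude >= 1))
    stop("ripple amplitude fraction must be in [0, 1)", call. = FALSE)
  list(grid_size = as.integer(grid_size), voxel_size = voxel_size,
       outer_semiaxes = outer_semiaxes, inner_scale = inner_scale,
       hemi_offset = hemi_offset, intensities = intensities,
       ripple = ripple, handles = handles, noise_sd = noise_sd,
       subdivisions = as.integer(subdivisions), seed = as.integer(seed))
}

#' Build a synthetic phantom subject
#'
#' @param config A [phantom_config()].
#' @param subject_id Identifier for the bundle.
#' @return List: `bundle` (a [subject_bundle]) and `truth` — for every
#'   default slice plane, the analytic in-plane ellipse parameters
#'   (center and semi-axes in plane mm) of each hemisphere/layer cross
#'   section.
#' @export
make_phantom_subject <- function(config = phantom_config(),
                                 subject_id = "phantom01") {
  gs <- config$grid_size; vs <- config$voxel_size
  affine <- diag(c(vs, vs, vs, 1))
  affine[1:3, 4] <- -vs * (gs - 1) / 2
  centers <- list(lh = c(-config$hemi_offset, 0, 0),
                  rh = c(config$hemi_offset, 0, 0))
  axo <- config$outer_semiaxes
  axi <- axo * config$inner_scale
  ix <- seq_len(gs[1]) - 1L; iy <- seq_len(gs[2]) - 1L
  iz <- seq_len(gs[3]) - 1L
  wx <- affine[1, 1] * ix + affine[1, 4]
  wy <- affine[2, 2] * iy + affine[2, 4]
  wz <- affine[3, 3] * iz + affine[3, 4]
  inside <- function(center, semi) {
    dx2 <- ((wx - center[1]) / semi[1])^2
    dy2 <- ((wy - center[2]) / semi[2])^2
    dz2 <- ((wz - center[3]) / semi[3])^2
    q <- outer(outer(dx2, dy2, "+"), dz2, "+")
    q <= 1
  }
  tis <- config$intensities
  vol <- array(tis[["CSF"]], dim = gs)
  out_any <- inside(centers$lh, axo) | inside(centers$rh, axo)
  in_any <- inside(centers$lh, axi) | inside(centers$rh, axi)
  vol[out_any] <- tis[["GM"]]
  vol[in_any] <- tis[["WM"]]
  if (!is.null(config$ripple)) {
    rp <- config$ripple
    wcoord <- list(wx, wy, wz)[[rp$axis]]
    mod <- 1 + rp$amplitude * sin(2 * pi * rp$frequency * wcoord)
    mod_arr <- switch(as.character(rp$axis),
      "1" = array(mod, dim = gs),
      "2" = array(rep(rep(mod, each = gs[1]), times = gs[3]), dim = gs),
      "3" = array(rep(mod, each = gs[1] * gs[2]), dim = gs))
    vol <- vol * mod_arr
  }
  if (config$noise_sd > 0)
    vol <- vol + with_preserved_seed(config$seed,
      array(stats::rnorm(prod(gs), 0, config$noise_sd), dim = gs))
  t1 <- qc_volume(vol, affine)
  surfaces <- list()
  for (h in c("lh", "rh")) {
    pial <- make_icosphere(config$subdivisions, radius = axo,
                           center = centers[[h]])
    white <- make_icosphere(config$subdivisions, radius = axi,
                            center = centers[[h]])
    ng <- config$handles[if (h == "lh") 1L else 2L]
    if (ng > 0) for (g in seq_len(ng))
      white <- add_handle(white, seed = config$seed + g)
    surfaces[[paste0(h, "_white")]] <- white
    surfaces[[paste0(h, "_pial")]] <- pial
  }
  bundle <- subject_bundle(subject_id, t1, surfaces)
  box <- brain_bounding_box(t1, 0.1)
  planes <- select_slice_planes(box)
  truth <- list()
  for (i in seq_along(planes)) {
    pl <- planes[[i]]
    k <- PLANE_AXES[[pl$axis]]
    uv <- setdiff(1:3, k)
    ent <- list()
    for (h in c("lh", "rh")) for (layer in c("white", "pial")) {
      semi <- if (layer == "pial") axo else axi
      dc <- (pl$coord - centers[[h]][k]) / semi[k]
      if (abs(dc) >= 1) next
      shrink <- sqrt(1 - dc^2)
      # plane coordinates relative to pl$origin along (u, v)
      cen <- c(centers[[h]][uv[1]] - pl$origin[uv[1]],
               centers[[h]][uv[2]] - pl$origin[uv[2]])
      ent[[paste(h, layer, sep = "_")]] <-
        list(center = cen, semi = semi[uv] * shrink)
    }
    truth[[i]] <- list(axis = pl$axis, coord = pl$coord,
                       ellipses = ent)
  }
  list(bundle = bundle, truth = truth)
}

#' Write a phantom subject as a FreeSurfer-style directory
#'
#' Creates `mri/T1.mgz` and `surf/{lh,rh}.{white,pial}` under
#' `dir/<subject_id>`.
#'
#' @param bundle A [subject_bundle].
#' @param dir Parent directory.
#' @return The subject directory path, invisibly.
#' @export
write_subject_dir <- function(bundle, dir) {
  sd <- file.path(dir, bundle$subject_id)
  dir.create(file.path(sd, "mri"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(sd, "surf"), recursive = TRUE,
             showWarnings = FALSE)
  write_volume(bundle$t1, file.path(sd, "mri", "T1.mgz"))
  for (h in c("lh", "rh")) for (layer in c("white", "pial"))
    write_surface(bundle$surfaces[[paste0(h, "_", layer)]],
                  file.path(sd, "surf", paste0(h, ".", layer)))
  invisible(sd)
}

#' Read a FreeSurfer-style subject directory into a bundle
#'
#' @param sd Subject directory containing `mri/T1.mgz` (or `.nii[.gz]`)
#'   and `surf/{lh,rh}.{white,pial}`.
#' @export
read_subject_dir <- function(sd) {
  t1_cand <- c("T1.mgz", "T1.mgh", "T1.nii.gz", "T1.nii")
  t1_path <- file.path(sd, "mri", t1_cand)
  t1_path <- t1_path[file.exists(t1_path)][1]
  if (is.na(t1_path))
    stop("no T1 volume under ", file.path(sd, "mri"), call. = FALSE)
  surfaces <- list()
  for (h in c("lh", "rh")) for (layer in c("white", "pial")) {
    p <- file.path(sd, "surf", paste0(h, ".", layer))
    if (!file.exists(p)) stop("missing surface: ", p, call. = FALSE)
    surfaces[[paste0(h, "_", layer)]] <- read_surface(p)
  }
  subject_bundle(basename(sd), read_volume(t1_path), surfaces)
}
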