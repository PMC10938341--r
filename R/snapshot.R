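#' Default snapshot rendering style
#'
#' @param white_col,pial_col RGB triples in `[0,1]` for the white and
#'   pial surface contours.
#' @param line_step Contour rasterization step in pixels.
#' @export
snapshot_style <- function(white_col = c(1, 1, 0), pial_col = c(1, 0.2, 0.2),
                           line_step = 0.4) {
  list(white = white_col, pial = pial_col, line_step = line_step)
}

#' Render one QC snapshot to a PNG file
#'
#' Grayscale underlay (min-max normalized slice intensities) with the
#' white- and pial-surface contours drawn in distinct colours. Writing
#' goes through \pkg{png} on a raw pixel array, so identical inputs give
#' byte-identical files.
#'
#' @param slice Output of [extract_slice_image()].
#' @param contours Named list of contour sets (as returned by
#'   [slice_contours()]), typically `list(white = ..., pial = ...)`;
#'   each set may pool both hemispheres.
#' @param path Output PNG path.
#' @param style A [snapshot_style()].
#' @return `path`, invisibly.
#' @export
render_snapshot <- function(slice, contours = list(), path,
                            style = snapshot_style()) {
  img <- slice$image
  rng <- range(img)
  g <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
  na <- nrow(g); nb <- ncol(g)
  # pixel row = v axis (flipped so +v is up), column = u axis
  arr <- array(0, dim = c(nb, na, 3L))
  base <- t(g)[nb:1, , drop = FALSE]
  for (ch in 1:3) arr[, , ch] <- base
  for (layer in names(contours)) {
    col <- style[[layer]] %||% c(0, 1, 0)
    for (pl in contours[[layer]]) {
      px <- rasterize_polyline(pl$points, slice, na, nb, style$line_step)
      if (!nrow(px)) next
      for (ch in 1:3) arr[cbind(px[, 1], px[, 2], ch)] <- col[ch]
    }
  }
  png::writePNG(arr, target = path)
  invisible(path)
}

rasterize_polyline <- function(p, slice, na, nb, step = 0.4) {
  if (nrow(p) < 2L) return(matrix(integer(), 0L, 2L))
  ax <- (p[, 1] - slice$a0) / slice$pixel_size + 1
  bx <- (p[, 2] - slice$b0) / slice$pixel_size + 1
  cols <- integer(0); rows <- integer(0)
  for (i in seq_len(nrow(p) - 1L)) {
    len <- max(abs(ax[i + 1] - ax[i]), abs(bx[i + 1] - bx[i]))
    nstep <- max(2L, ceiling(len / step) + 1L)
    tt <- seq(0, 1, length.out = nstep)
    cc <- round(ax[i] + tt * (ax[i + 1] - ax[i]))
    rr <- round(bx[i] + tt * (bx[i + 1] - bx[i]))
    cols <- c(cols, cc); rows <- c(rows, rr)
  }
  keep <- cols >= 1 & cols <= na & rows >= 1 & rows <= nb
  cbind(nb - rows[keep] + 1L, cols[keep]) # (pixel row, pixel col)
}

#' Generate the full snapshot set for one subject
#'
#' Computes the brain bounding box, selects the slice planes (default 3
#' axial / 3 coronal / 4 sagittal), and writes one PNG per plane with
#' all four surfaces (lh/rh white and pial) contoured on the T1 slice.
#'
#' @param bundle A [subject_bundle].
#' @param out_dir Output directory (created if needed).
#' @param fractions Per-axis slice fractions, see [snapshot_fractions()].
#' @param pixel_size Snapshot pixel size, mm.
#' @param intensity_fraction Bounding-box threshold fraction.
#' @param style A [snapshot_style()].
#' @return Data frame of manifest rows: `subject_id`, `axis`,
#'   `slice_index`, `world_coord`, `filename`, `n_contours`,
#'   `no_contour_flag`.
#' @export
generate_subject_snapshots <- function(bundle, out_dir,
                                       fractions = snapshot_fractions(),
                                       pixel_size = 1,
                                       intensity_fraction = 0.1,
                                       style = snapshot_style()) {
  stopifnot(inherits(bundle, "subject_bundle"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  box <- brain_bounding_box(bundle$t1, intensity_fraction)
  planes <- select_slice_planes(box, fractions)
  rows <- vector("list", length(planes))
  axis_counter <- c(axial = 0L, coronal = 0L, sagittal = 0L)
  for (i in seq_along(planes)) {
    pl <- planes[[i]]
    axis_counter[pl$axis] <- axis_counter[pl$axis] + 1L
    slice <- extract_slice_image(bundle$t1, pl, pixel_size)
    layer_contours <- list(
      white = c(slice_contours(bundle$surfaces$lh_white, pl),
                slice_contours(bundle$surfaces$rh_white, pl)),
      pial = c(slice_contours(bundle$surfaces$lh_pial, pl),
               slice_contours(bundle$surfaces$rh_pial, pl)))
    n_contours <- sum(lengths(layer_contours))
    fname <- sprintf("%s_%s_%02d.png", bundle$subject_id, pl$axis,
                     axis_counter[pl$axis])
    render_snapshot(slice, layer_contours, file.path(out_dir, fname),
                    style)
    rows[[i]] <- data.frame(subject_id = bundle$subject_id,
                            axis = pl$axis,
                            slice_index = axis_counter[pl$axis],
                            world_coord = pl$coord, filename = fname,
                            n_contours = n_contours,
                            no_contour_flag = n_contours == 0L,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Anonymize snapshot filenames and shuffle the rating order
#'
#' Each image is assigned the MD5 hex digest of `salt` + original
#' filename, and a seeded uniform permutation over all images (pooled
#' across subjects and sites) fixes the presentation order, so raters
#' are not influenced by consecutive images from one participant. The
#' original-to-hash bijection, salt and seed are stored in the manifest
#' for later de-anonymization.
#'
#' @param rows Manifest rows from [generate_subject_snapshots()]
#'   (possibly concatenated over subjects).
#' @param seed Integer seed for the shuffle.
#' @param salt Character salt prepended before hashing.
#' @return A `snapshot_manifest`: the rows augmented with `image_hash`
#'   and `shuffle_position`, plus attributes `salt` and `seed`.
#' @export
anonymize_and_shuffle <- function(rows, seed, salt = "surfqc") {
  if (anyDuplicated(rows$filename))
    stop("filenames must be unique before anonymization", call. = FALSE)
  hashes <- vapply(rows$filename, function(f)
    digest::digest(paste0(salt, f), algo = "md5", serialize = FALSE),
    character(1), USE.NAMES = FALSE)
  if (anyDuplicated(hashes)) {
    dup <- hashes[duplicated(hashes)][1]
    stop("MD5 collision among filenames: ",
         paste(rows$filename[hashes == dup], collapse = ", "),
         call. = FALSE)
  }
  rows$image_hash <- hashes
  rows$shuffle_position <- with_preserved_seed(seed,
                                               sample.int(nrow(rows)))
  attr(rows, "salt") <- salt
  attr(rows, "seed") <- seed
  class(rows) <- c("snapshot_manifest", "data.frame")
  rows
}

# Run expr under a seed without disturbing the caller's RNG stream.
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Recover original filenames from an anonymized manifest
#'
#' @param manifest A `snapshot_manifest`.
#' @param image_hash Character vector of hashes to look up.
#' @return Character vector of original filenames (NA when unknown).
#' @export
deanonymize <- function(manifest, image_hash) {
  manifest$filename[match(image_hash, manifest$image_hash)]
}

#' Write / read a snapshot manifest
#'
#' The machine copy is JSON (rows plus salt and seed); a CSV copy can be
#' written alongside for human inspection.
#'
#' @param manifest A `snapshot_manifest`.
#' @param path JSON output path.
#' @param csv Optional CSV path.
#' @export
write_manifest <- function(manifest, path, csv = NULL) {
  payload <- list(salt = attr(manifest, "salt"),
                  seed = attr(manifest, "seed"),
                  rows = as.data.frame(manifest))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv))
    utils::write.csv(as.data.frame(manifest), csv, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  rows <- as.data.frame(payload$rows)
  attr(rows, "salt") <- payload$salt
  attr(rows, "seed") <- payload$seed
  class(rows) <- c("snapshot_manifest", "data.frame")
  rows
}

#' Copy snapshot files to their anonymized names
#'
#' @param manifest A `snapshot_manifest`.
#' @param src_dir Directory holding the original files.
#' @param dest_dir Directory to receive `<hash>.png` copies.
#' @export
apply_anonymization <- function(manifest, src_dir, dest_dir) {
  dir.create(dest_dir, showWarnings = FALSE, recursive = TRUE)
  ok <- file.copy(file.path(src_dir, manifest$filename),
                  file.path(dest_dir, paste0(manifest$image_hash, ".png")),
                  overwrite = TRUE)
  if (!all(ok))
    warning(sum(!ok), " snapshot file(s) could not be copied")
  invisible(dest_dir)
}
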