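#' Volume image container
#'
#' A 3-D intensity grid together with a 4x4 affine mapping 0-based voxel
#' indices to world coordinates in millimetres. The affine is the single
#' source of truth for voxel/world conversions; `voxel_sizes` are derived
#' from its column norms.
#'
#' @param data 3-D numeric array of intensities (arbitrary units).
#' @param affine 4x4 numeric matrix, voxel index (0-based) to world mm.
#' @return An object of class `qc_volume` with elements `data`, `affine`
#'   and `voxel_sizes`.
#' @export
qc_volume <- function(data, affine = diag(4)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume data must be a 3-D array, got ",
         paste(dim(data), collapse = "x"), call. = FALSE)
  if (any(dim(data) < 8L))
    stop("volume grid dimensions must be >= 8 per axis", call. = FALSE)
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)))
    stop("affine must be a 4x4 matrix", call. = FALSE)
  det_a <- det(affine)
  if (!is.finite(det_a) || abs(det_a) < .Machine$double.eps)
    stop("affine must be invertible", call. = FALSE)
  vox <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(vox <= 0)) stop("voxel sizes must be positive", call. = FALSE)
  structure(list(data = data, affine = affine, voxel_sizes = vox),
            class = "qc_volume")
}

#' @export
print.qc_volume <- function(x, ...) {
  cat("<qc_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, ", paste(signif(x$voxel_sizes, 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' Apply a volume affine to 0-based voxel indices
#'
#' @param vol A [qc_volume].
#' @param ijk n x 3 matrix of 0-based voxel indices.
#' @return n x 3 matrix of world-mm coordinates.
#' @export
voxel_to_world <- function(vol, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3L)
  h <- cbind(ijk, 1)
  out <- h %*% t(vol$affine)
  out[, 1:3, drop = FALSE]
}

#' World mm to continuous 0-based voxel indices
#' @inheritParams voxel_to_world
#' @param xyz n x 3 matrix of world coordinates (mm).
#' @export
world_to_voxel <- function(vol, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  h <- cbind(xyz, 1)
  out <- h %*% t(solve(vol$affine))
  out[, 1:3, drop = FALSE]
}

#' Triangle mesh container
#'
#' @param vertices N x 3 numeric matrix of world-mm vertex coordinates.
#' @param faces M x 3 integer matrix of 1-based vertex indices.
#' @return An object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be N x 3", call. = FALSE)
  if (ncol(faces) != 3L) stop("faces must be M x 3", call. = FALSE)
  n <- nrow(vertices)
  if (n < 4L || nrow(faces) < 4L)
    stop("mesh must have at least 4 vertices and 4 faces", call. = FALSE)
  if (any(faces < 1L) || any(faces > n))
    stop("face index out of range [1, ", n, "]", call. = FALSE)
  if (any(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
          faces[, 1] == faces[, 3]))
    stop("a face repeats a vertex", call. = FALSE)
  structure(list(vertices = vertices, faces = faces), class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat("<tri_mesh> ", nrow(x$vertices), " vertices, ",
      nrow(x$faces), " faces\n", sep = "")
  invisible(x)
}

#' Per-subject bundle of T1 volume and four cortical surfaces
#'
#' @param subject_id Subject identifier string.
#' @param t1 A [qc_volume].
#' @param surfaces Named list with elements `lh_white`, `lh_pial`,
#'   `rh_white`, `rh_pial`, each a [tri_mesh] in the volume's world frame.
#' @return An object of class `subject_bundle`.
#' @export
subject_bundle <- function(subject_id, t1, surfaces) {
  needed <- c("lh_white", "lh_pial", "rh_white", "rh_pial")
  if (!all(needed %in% names(surfaces)))
    stop("surfaces must contain: ", paste(needed, collapse = ", "),
         call. = FALSE)
  stopifnot(inherits(t1, "qc_volume"))
  for (nm in needed) stopifnot(inherits(surfaces[[nm]], "tri_mesh"))
  structure(list(subject_id = as.character(subject_id), t1 = t1,
                 surfaces = surfaces[needed]),
            class = "subject_bundle")
}

#' Declare a QC metric and its direction convention
#'
#' Every quality metric entering an analysis carries a direction flag so
#' that signs can be harmonized: for `higher_better` metrics (e.g. a
#' Qoala-T-style certainty score) reported partial correlations are
#' negated so that positive always means "worse quality, larger value".
#'
#' @param name Column name of the metric in a cohort table.
#' @param direction `"higher_worse"` (default; e.g. FSQC score, Euler
#'   defect index) or `"higher_better"`.
#' @param source `"computed"` or `"supplied"`.
#' @return An object of class `qc_metric`.
#' @export
qc_metric <- function(name, direction = c("higher_worse", "higher_better"),
                      source = c("supplied", "computed")) {
  direction <- match.arg(direction)
  source <- match.arg(source)
  structure(list(name = as.character(name), direction = direction,
                 source = source), class = "qc_metric")
}

as_qc_metric <- function(x) {
  if (inherits(x, "qc_metric")) return(x)
  qc_metric(x)
}

#' Cohort table container
#'
#' A participant-by-variable table: demographics (`age`, `sex`,
#' `diagnosis`, `site`), zero or more QC metric columns and per-region
#' phenotype columns. Region columns are tracked per phenotype so the
#' regional analyses can iterate over them.
#'
#' @param df A data.frame with one row per participant, including a
#'   unique `subject_id` column, `age` (> 0, years), `sex` (binary code),
#'   `diagnosis` (binary, 1 = case) and `site` (categorical label).
#' @param qc_cols Character vector of QC metric column names.
#' @param region_cols Named list, phenotype (e.g. `"CT"`) to character
#'   vector of region column names.
#' @return The data.frame with class `cohort_table` and attributes
#'   `qc_cols` and `region_cols`.
#' @export
cohort_table <- function(df, qc_cols = character(), region_cols = list()) {
  df <- as.data.frame(df)
  req <- c("subject_id", "age", "sex", "diagnosis", "site")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("cohort table missing required columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$subject_id))
    stop("subject_id must be unique", call. = FALSE)
  if (any(df$age <= 0, na.rm = TRUE))
    stop("age must be positive", call. = FALSE)
  bad <- setdiff(c(qc_cols, unlist(region_cols)), names(df))
  if (length(bad))
    stop("declared columns absent from table: ",
         paste(bad, collapse = ", "), call. = FALSE)
  attr(df, "qc_cols") <- qc_cols
  attr(df, "region_cols") <- region_cols
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Region columns of a cohort table for one phenotype
#' @param cohort A [cohort_table].
#' @param phenotype Phenotype key, e.g. `"CT"`.
#' @export
region_columns <- function(cohort, phenotype) {
  rc <- attr(cohort, "region_cols")
  if (is.null(rc[[phenotype]]) || !length(rc[[phenotype]]))
    stop("no region columns registered for phenotype ", phenotype,
         call. = FALSE)
  rc[[phenotype]]
}

# Keep attributes through row subsetting
#' @export
`[.cohort_table` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "qc_cols") <- intersect(attr(x, "qc_cols"), names(out))
    rc <- lapply(attr(x, "region_cols"), intersect, names(out))
    attr(out, "region_cols") <- rc
    class(out) <- c("cohort_table", "data.frame")
  }
  out
}
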