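#' Read a FreeSurfer binary triangle surface
#'
#' Parses the classic FreeSurfer triangle-surface format: a 3-byte magic
#' (0xFFFFFE), a creation comment terminated by two newlines, big-endian
#' vertex/face counts, float32 vertex coordinates and int32 face indices.
#' If the optional footer carries a volume-geometry block with a
#' `cras = x y z` line (FreeSurfer's per-subject rigid offset between the
#' surface frame and the volume's world frame), the offset is applied to
#' the vertices at load so that surfaces and volume share one frame.
#'
#' @param path Path to the surface file.
#' @return A [tri_mesh] with vertex coordinates in world mm.
#' @export
read_surface <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 3L)
  if (length(magic) < 3L ||
      !identical(as.integer(magic), c(255L, 255L, 254L)))
    stop("bad magic number in surface file ", path,
         " (expected ff ff fe)", call. = FALSE)
  # comment: bytes up to and including "\n\n"
  prev <- as.raw(0L)
  repeat {
    b <- readBin(con, "raw", n = 1L)
    if (!length(b)) stop("truncated surface file ", path, call. = FALSE)
    if (b == as.raw(10L) && prev == as.raw(10L)) break
    prev <- b
  }
  counts <- readBin(con, "integer", n = 2L, size = 4L, endian = "big")
  if (length(counts) < 2L || any(counts < 1L))
    stop("truncated or corrupt surface header in ", path, call. = FALSE)
  nv <- counts[1]; nf <- counts[2]
  vert <- readBin(con, "double", n = 3L * nv, size = 4L, endian = "big")
  if (length(vert) < 3L * nv)
    stop("truncated vertex block in ", path, call. = FALSE)
  fac <- readBin(con, "integer", n = 3L * nf, size = 4L, endian = "big")
  if (length(fac) < 3L * nf)
    stop("truncated face block in ", path, call. = FALSE)
  if (any(fac < 0L) || any(fac >= nv))
    stop("face index out of range [0, ", nv, ") in ", path, call. = FALSE)
  vertices <- matrix(vert, ncol = 3L, byrow = TRUE)
  faces <- matrix(fac, ncol = 3L, byrow = TRUE) + 1L
  # optional footer: scan remaining bytes for a cras line
  rest <- readBin(con, "raw", n = 1e6L)
  if (length(rest)) {
    txt <- rawToChar(rest[rest >= as.raw(9L) & rest < as.raw(127L)])
    m <- regmatches(txt, regexec(
      "cras\\s*=\\s*(-?[0-9.eE+-]+)\\s+(-?[0-9.eE+-]+)\\s+(-?[0-9.eE+-]+)",
      txt))[[1]]
    if (length(m) == 4L) {
      cras <- as.numeric(m[2:4])
      vertices <- sweep(vertices, 2L, cras, "+")
    }
  }
  tri_mesh(vertices, faces)
}

#' Write a FreeSurfer binary triangle surface
#'
#' @param mesh A [tri_mesh].
#' @param path Output path.
#' @param cras Optional length-3 numeric: a volume-geometry offset to
#'   record in the footer. Vertices are stored relative to it (i.e.
#'   `vertices - cras`), so [read_surface()] restores the original
#'   coordinates.
#' @return `path`, invisibly.
#' @export
write_surface <- function(mesh, path, cras = NULL) {
  stopifnot(inherits(mesh, "tri_mesh"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(255L, 255L, 254L)), con)
  writeChar("created by surfqc\n\n", con, eos = NULL)
  vert <- mesh$vertices
  if (!is.null(cras)) {
    stopifnot(length(cras) == 3L)
    vert <- sweep(vert, 2L, cras, "-")
  }
  writeBin(c(nrow(vert), nrow(mesh$faces)), con, size = 4L,
           endian = "big")
  writeBin(as.numeric(t(vert)), con, size = 4L, endian = "big")
  writeBin(as.integer(t(mesh$faces) - 1L), con, size = 4L, endian = "big")
  if (!is.null(cras)) {
    writeBin(c(2L, 0L), con, size = 4L, endian = "big") # useRealRAS tag
    geom <- sprintf(
      "valid = 1  # volume info valid\nvoxelsize = 1 1 1\ncras   = %.10g %.10g %.10g\n",
      cras[1], cras[2], cras[3])
    writeChar(geom, con, eos = NULL)
  }
  invisible(path)
}
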