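#' Read a T1 volume from MGZ/MGH or NIfTI-1
#'
#' Dispatches on the file extension: `.mgz`/`.mgh` use the built-in MGH
#' reader (the format is a fixed 284-byte big-endian header followed by
#' the voxel payload; `.mgz` is the gzip-compressed variant), `.nii` and
#' `.nii.gz` go through \pkg{RNifti}. Intensities are returned unchanged;
#' orientation metadata is folded into the affine.
#'
#' @param path Path to an existing volume file.
#' @return A [qc_volume].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lower <- tolower(path)
  if (grepl("\\.(mgz|mgh)$", lower)) {
    read_mgh(path)
  } else if (grepl("\\.nii(\\.gz)?$", lower)) {
    img <- RNifti::readNifti(path)
    dat <- as.array(img)
    if (length(dim(dat)) == 4L && dim(dat)[4] == 1L)
      dat <- array(dat, dim = dim(dat)[1:3])
    if (length(dim(dat)) != 3L)
      stop("expected a 3-D volume, got ",
           length(dim(dat)), "-D in ", path, call. = FALSE)
    dat <- array(as.numeric(dat), dim = dim(dat)) # drop RNifti attrs
    qc_volume(dat, matrix(as.numeric(RNifti::xform(img)), 4L, 4L))
  } else {
    stop("unrecognized volume format (expected .mgz/.mgh/.nii/.nii.gz): ",
         path, call. = FALSE)
  }
}

#' Write a volume to MGZ/MGH or NIfTI-1
#'
#' @param vol A [qc_volume].
#' @param path Output path; format chosen by extension as in
#'   [read_volume()]. MGH payload is written as 32-bit float.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "qc_volume"))
  lower <- tolower(path)
  if (grepl("\\.(mgz|mgh)$", lower)) {
    write_mgh(vol, path)
  } else if (grepl("\\.nii(\\.gz)?$", lower)) {
    img <- RNifti::asNifti(vol$data)
    img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
    RNifti::writeNifti(img, path)
  } else {
    stop("unrecognized volume format for writing: ", path, call. = FALSE)
  }
  invisible(path)
}

# MGH format constants: header occupies 284 bytes; payload types
MGH_TYPE_UCHAR <- 0L
MGH_TYPE_INT <- 1L
MGH_TYPE_FLOAT <- 3L
MGH_TYPE_SHORT <- 4L

read_mgh <- function(path) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  rd_int <- function(n, size = 4L) {
    v <- readBin(con, "integer", n = n, size = size, endian = "big")
    if (length(v) < n)
      stop("truncated MGH file ", path, ": unexpected end of header",
           call. = FALSE)
    v
  }
  version <- rd_int(1L)
  if (version != 1L)
    stop("bad MGH magic/version at byte offset 0 in ", path,
         " (got ", version, ", expected 1)", call. = FALSE)
  dims <- rd_int(4L)
  type <- rd_int(1L)
  rd_int(1L) # dof, unused
  goodras <- rd_int(1L, size = 2L)
  affine <- diag(4)
  bytes_read <- 30L
  if (goodras == 1L) {
    geom <- readBin(con, "double", n = 15L, size = 4L, endian = "big")
    if (length(geom) < 15L)
      stop("truncated MGH file ", path, ": geometry block at byte offset ",
           bytes_read, call. = FALSE)
    delta <- geom[1:3]
    mdc <- matrix(geom[4:12], nrow = 3L) # columns = x/y/z direction cosines
    c_ras <- geom[13:15]
    a3 <- mdc %*% diag(delta)
    affine[1:3, 1:3] <- a3
    affine[1:3, 4] <- c_ras - a3 %*% (dims[1:3] / 2)
    bytes_read <- bytes_read + 60L
  }
  readBin(con, "raw", n = 284L - bytes_read) # header padding
  if (dims[4] > 1L)
    stop("expected a 3-D volume, got ", dims[4], " frames in ", path,
         call. = FALSE)
  nvox <- prod(dims[1:3])
  dat <- switch(as.character(type),
    "0" = as.numeric(readBin(con, "integer", n = nvox, size = 1L,
                             signed = FALSE)),
    "1" = as.numeric(readBin(con, "integer", n = nvox, size = 4L,
                             endian = "big")),
    "3" = readBin(con, "double", n = nvox, size = 4L, endian = "big"),
    "4" = as.numeric(readBin(con, "integer", n = nvox, size = 2L,
                             endian = "big")),
    stop("unsupported MGH data type ", type, " in ", path, call. = FALSE))
  if (length(dat) < nvox)
    stop("truncated MGH file ", path, ": payload ends at byte offset ",
         284L + length(dat), call. = FALSE)
  qc_volume(array(dat, dim = dims[1:3]), affine)
}

write_mgh <- function(vol, path) {
  con <- if (grepl("\\.mgz$", tolower(path))) gzfile(path, "wb")
         else file(path, "wb")
  on.exit(close(con))
  dims <- dim(vol$data)
  writeBin(1L, con, size = 4L, endian = "big")
  writeBin(as.integer(c(dims, 1L)), con, size = 4L, endian = "big")
  writeBin(MGH_TYPE_FLOAT, con, size = 4L, endian = "big")
  writeBin(0L, con, size = 4L, endian = "big") # dof
  writeBin(1L, con, size = 2L, endian = "big") # goodRASflag
  a3 <- vol$affine[1:3, 1:3]
  delta <- sqrt(colSums(a3^2))
  mdc <- sweep(a3, 2L, delta, "/")
  c_ras <- vol$affine[1:3, 4] + a3 %*% (dims / 2)
  writeBin(c(delta, as.numeric(mdc), as.numeric(c_ras)), con,
           size = 4L, endian = "big")
  writeBin(raw(284L - 90L), con)
  writeBin(as.numeric(vol$data), con, size = 4L, endian = "big")
  invisible(path)
}
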