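#' Read an MRC/CCP4 volume
#'
#' Reads a volume in MRC/CCP4 format (modes 0, 1 and 2). The axis order is
#' normalized on read to fast-to-slow X,Y,Z regardless of the MAPC/MAPR/MAPS
#' fields, so all volumes share one internal convention. Voxel size comes from
#' the cell dimensions divided by the sampling counts MX/MY/MZ. The origin is
#' taken from the ORIGIN header words if any is nonzero, otherwise from the
#' NXSTART/NYSTART/NZSTART start indices times the voxel size (the common
#' cryo-EM versus crystallographic header dialects). Only orthogonal cells
#' (all angles 90 degrees) are supported.
#'
#' @param path Path to an MRC/CCP4 file.
#' @return A `mapgrid`.
#' @export
read_map <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 256, size = 4, endian = "little")
  seek(con, 0)
  hdr_num <- readBin(con, "numeric", n = 256, size = 4, endian = "little")
  nxyz <- hdr_int[1:3]                      # NC, NR, NS: fast, medium, slow counts
  mode <- hdr_int[4]
  nstart <- hdr_int[5:7]
  mxyz <- hdr_int[8:10]
  cell <- hdr_num[11:13]
  angles <- hdr_num[14:16]
  mapcrs <- hdr_int[17:19]
  nsymbt <- hdr_int[24]
  orig <- hdr_num[50:52]
  if (any(nxyz <= 0)) stop("zero-sized axis in MRC header")
  if (!mode %in% c(0L, 1L, 2L)) stop("unsupported MRC mode: ", mode)
  if (any(abs(angles - 90) > 1e-3)) stop("non-orthogonal cells are not supported")
  if (any(mxyz <= 0)) stop("invalid sampling counts in MRC header")
  if (!setequal(mapcrs, 1:3)) stop("invalid MAPC/MAPR/MAPS axis assignment")
  seek(con, 1024 + nsymbt)
  n <- prod(nxyz)
  vals <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = n, size = 1, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n = n, size = 2, signed = TRUE,
                             endian = "little")),
    "2" = readBin(con, "numeric", n = n, size = 4, endian = "little"))
  if (length(vals) != n) stop("truncated MRC data block")
  vol <- array(vals, nxyz)                  # stored fast-to-slow = axes mapcrs
  # permute so that array index i runs along crystallographic axis i (X,Y,Z)
  perm <- order(mapcrs)                     # position of axis X, Y, Z among fast/medium/slow
  vol <- aperm(vol, perm)
  voxel <- cell / mxyz
  nstart_xyz <- nstart[perm]
  origin <- if (any(orig != 0)) orig else nstart_xyz * voxel
  map_grid(vol, voxel, origin)
}

#' Write a MapGrid as an MRC mode-2 volume
#'
#' Writes a 32-bit float MRC file whose header encodes the dimensions, voxel
#' size and origin so that [read_map()] inverts it exactly (bit-level for the
#' values, which are stored at float32 precision). Axis order is X,Y,Z
#' fast-to-slow.
#'
#' @param m A `mapgrid` (all values finite; enforced before any bytes are
#'   written).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_map <- function(m, path) {
  stopifnot(inherits(m, "mapgrid"))
  if (!all(is.finite(m$values))) stop("refusing to write non-finite map values")
  d <- map_dims(m)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                                    # NC NR NS
  wi(2)                                    # mode 2: float32
  wi(c(0, 0, 0))                           # nstart
  wi(d)                                    # mx my mz
  wf(d * m$voxel)                          # cell a b c
  wf(c(90, 90, 90))                        # angles
  wi(1:3)                                  # mapc mapr maps = X,Y,Z
  wf(c(min(m$values), max(m$values), mean(m$values)))
  wi(c(1, 0))                              # ispg, nsymbt
  wi(rep(0, 25))                           # extra (words 26-50 of header)
  wf(m$origin)                             # origin x y z (words 50-52)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machine stamp: little endian
  wf(stats::sd(as.vector(m$values)))
  wi(0)                                    # nlabl
  writeBin(raw(800), con)                  # labels
  wf(as.vector(m$values))
  invisible(path)
}

#' Cut a working box around a macromolecule
#'
#' Extracts the sub-volume containing all flagged grid points (from an atomic
#' model or a boolean mask) plus `pad` Angstrom on every side. The box is used
#' as is — it is not placed into a larger empty volume — and the origin is
#' updated so absolute Angstrom coordinates of retained points are preserved.
#' Padding that would extend beyond the source map is clamped with a warning.
#'
#' @param m A `mapgrid`.
#' @param model_or_mask Either an `atommodel` (box encloses all atoms) or a
#'   logical `mapgrid` aligned with `m`.
#' @param pad Padding in Angstrom (may be 0).
#' @return A `mapgrid` sub-volume.
#' @export
extract_box <- function(m, model_or_mask, pad = 0) {
  d <- map_dims(m)
  if (inherits(model_or_mask, "atommodel")) {
    xyz <- model_coords(model_or_mask)
    idx <- t(vapply(1:3, function(a)
      round((range(xyz[, a]) - m$origin[a]) / m$voxel[a]), numeric(2)))
    lo <- idx[, 1]; hi <- idx[, 2]
  } else {
    mask <- model_or_mask$values
    stop_if_misaligned(m, model_or_mask, "map and mask")
    if (!any(mask)) stop("empty mask")
    w <- which(mask, arr.ind = TRUE)
    lo <- apply(w, 2, min) - 1; hi <- apply(w, 2, max) - 1
  }
  padv <- ceiling(pad / m$voxel)
  lo <- lo - padv; hi <- hi + padv
  if (any(lo < 0) || any(hi > d - 1)) {
    warning("padding clamped at map boundary")
    lo <- pmax(lo, 0); hi <- pmin(hi, d - 1)
  }
  sub <- m$values[(lo[1] + 1):(hi[1] + 1), (lo[2] + 1):(hi[2] + 1),
                  (lo[3] + 1):(hi[3] + 1), drop = FALSE]
  map_grid(sub, m$voxel, m$origin + lo * m$voxel)
}
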