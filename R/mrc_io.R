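# MRC2014 volume/image reader and writer (modes 0, 1, 2, 6).
#
# In memory a volume is a `volume_grid`: list(data = 3D array indexed
# [x, y, z] with x fastest (matching the file layout, where z is the
# slowest axis), pixel_size in Angstrom/px, origin in Angstrom,
# axis_order = "x-fastest"). 2D images are stored with a singleton third
# axis. All lengths are Angstrom in memory; pixels appear only at this
# I/O boundary.

#' Construct a volume grid
#' @param data 3D (or 2D) real array
#' @param pixel_size Angstrom per pixel (> 0)
#' @param origin 3D origin offset in Angstrom
#' @return object of class `volume_grid`
#' @export
volume_grid <- function(data, pixel_size = 1, origin = c(0, 0, 0)) {
  if (length(dim(data)) == 2) dim(data) <- c(dim(data), 1L)
  stopifnot(length(dim(data)) == 3, pixel_size > 0, all(dim(data) >= 1))
  structure(list(data = data, pixel_size = pixel_size,
                 origin = as.numeric(origin), axis_order = "x-fastest"),
            class = "volume_grid")
}

#' Read an MRC2014 file
#'
#' Supports modes 0 (int8), 1 (int16), 2 (float32) and 6 (uint16), both
#' byte orders. The pixel size is taken from the cell dimensions divided
#' by the grid size.
#'
#' @param path path to an MRC file
#' @return a [volume_grid()]
#' @export
read_mrc <- function(path) {
  if (!file.exists(path)) stop("MRC file not found: ", path)
  sz <- file.info(path)$size
  if (sz < 1024) stop("truncated MRC file (no full header): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  endian <- "little"
  hdr_raw <- readBin(con, "raw", 1024)
  rd_int <- function(off, n = 1) {
    readBin(hdr_raw[(off + 1):(off + 4 * n)], "integer", n, size = 4,
            endian = endian)
  }
  rd_flt <- function(off, n = 1) {
    readBin(hdr_raw[(off + 1):(off + 4 * n)], "double", n, size = 4,
            endian = endian)
  }
  nxyz <- rd_int(0, 3)
  if (any(nxyz <= 0) || any(nxyz > 1e6)) {
    endian <- "big"
    nxyz <- rd_int(0, 3)
    if (any(nxyz <= 0) || any(nxyz > 1e6)) {
      stop("unreadable MRC dimensions in ", path)
    }
  }
  mode <- rd_int(12)
  mxyz <- rd_int(28, 3)
  cella <- rd_flt(40, 3)
  nsymbt <- rd_int(92)
  nvox <- prod(nxyz)
  bytes <- c(`0` = 1L, `1` = 2L, `2` = 4L, `6` = 2L)[as.character(mode)]
  if (is.na(bytes)) stop("unsupported MRC mode ", mode, " in ", path)
  if (sz < 1024 + nsymbt + nvox * bytes) {
    stop("truncated MRC data section in ", path)
  }
  if (nsymbt > 0) readBin(con, "raw", nsymbt)
  data <- switch(as.character(mode),
    `0` = as.numeric(readBin(con, "integer", nvox, size = 1,
                             signed = TRUE, endian = endian)),
    `1` = as.numeric(readBin(con, "integer", nvox, size = 2,
                             signed = TRUE, endian = endian)),
    `2` = readBin(con, "double", nvox, size = 4, endian = endian),
    `6` = as.numeric(readBin(con, "integer", nvox, size = 2,
                             signed = FALSE, endian = endian)))
  dim(data) <- nxyz
  px <- if (mxyz[1] > 0 && cella[1] > 0) cella[1] / mxyz[1] else 1
  org <- rd_flt(196, 3)
  volume_grid(data, pixel_size = px, origin = org)
}

#' Write an MRC2014 file (mode 2, float32)
#'
#' Header statistics (min/max/mean/rms) are recomputed from the data;
#' [read_mrc()] is the exact inverse up to float32 precision.
#'
#' @param vol a [volume_grid()] (or bare array)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_mrc <- function(vol, path) {
  if (!inherits(vol, "volume_grid")) vol <- volume_grid(vol)
  d <- vol$data
  if (any(!is.finite(d))) stop("refusing to write non-finite data to MRC")
  n <- dim(d)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4,
                             endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4,
                             endian = "little")
  wi(n)                        # nx ny nz
  wi(2)                        # mode 2: float32
  wi(c(0, 0, 0))               # nxstart
  wi(n)                        # mx my mz
  wf(n * vol$pixel_size)       # cella
  wf(c(90, 90, 90))            # cellb
  wi(c(1, 2, 3))               # mapc mapr maps
  wf(c(min(d), max(d), mean(d)))
  wi(0)                        # ispg
  wi(0)                        # nsymbt
  writeBin(raw(100), con)      # extra (words 25-49)
  wf(vol$origin)               # origin x y z
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(sd(as.numeric(d)))        # rms
  wi(1)                        # nlabl
  lab <- paste0("pseudotomo", strrep(" ", 70))
  writeChar(lab, con, 80, eos = NULL)
  writeBin(raw(720), con)      # remaining label slots
  writeBin(as.numeric(d), con, size = 4, endian = "little")
  invisible(path)
}
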