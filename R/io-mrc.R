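#' Read an MRC/CCP4 density map
#'
#' Supports MRC2014 mode-2 (float32) volumes. The header's axis order
#' (MAPC/MAPR/MAPS) is honoured and the returned grid is always stored
#' x-fastest. Voxel spacing is CELLA/(MX,MY,MZ) and the origin is taken
#' from the ORIGIN fields, in Angstrom.
#'
#' @param path MRC/CCP4 file.
#' @return a [DensityGrid-class].
#' @export
readMRC <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdrInt <- readBin(con, "integer", n = 256, size = 4, endian = "little")
  seek(con, 0)
  hdrFlt <- readBin(con, "numeric", n = 256, size = 4, endian = "little")
  dims <- hdrInt[1:3]
  mode <- hdrInt[4]
  if (mode != 2L)
    rwStop("rw_format_error",
           sprintf("unsupported MRC mode %d (only mode 2, float32)", mode))
  mxyz <- hdrInt[8:10]
  cella <- hdrFlt[11:13]
  mapcrs <- hdrInt[17:19]
  if (!all(sort(mapcrs) == 1:3))
    rwStop("rw_format_error", "malformed MRC axis-order fields")
  nsymbt <- hdrInt[24]
  origin <- hdrFlt[50:52]
  seek(con, 1024 + nsymbt)
  nvox <- prod(dims)
  vals <- readBin(con, "numeric", n = nvox, size = 4, endian = "little")
  if (length(vals) != nvox)
    rwStop("rw_format_error", "truncated MRC data block")
  arr <- array(vals, dim = dims)  # fastest index = column axis mapc
  # permute so that array index 1,2,3 correspond to crystallographic x,y,z
  perm <- match(1:3, mapcrs)
  if (!all(perm == 1:3)) arr <- aperm(arr, perm)
  spacing <- cella / mxyz
  spacing[!is.finite(spacing) | spacing <= 0] <- 1
  DensityGrid(arr, spacing = spacing, origin = origin)
}

#' Write a density map as MRC2014 mode 2
#'
#' @param grid a [DensityGrid-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeMRC <- function(grid, path) {
  d <- dim(grid@values)
  con <- file(path, "wb")
  on.exit(close(con))
  wInt <- function(x) writeBin(as.integer(x), con, size = 4,
                               endian = "little")
  wFlt <- function(x) writeBin(as.numeric(x), con, size = 4,
                               endian = "little")
  wInt(d)                      # NX NY NZ
  wInt(2)                      # MODE 2 float32
  wInt(c(0, 0, 0))             # NXSTART..
  wInt(d)                      # MX MY MZ
  wFlt(d * grid@spacing)       # CELLA
  wFlt(c(90, 90, 90))          # CELLB
  wInt(1:3)                    # MAPC MAPR MAPS: x fastest
  v <- grid@values
  wFlt(c(min(v), max(v), mean(v)))  # DMIN DMAX DMEAN
  wInt(c(1, 0))                # ISPG, NSYMBT
  wInt(rep(0, 25))             # EXTRA (words 26-50 of the int view)
  wFlt(grid@origin)            # ORIGIN X Y Z (words 50-52, float view)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wFlt(stats::sd(v))           # RMS
  wInt(0)                      # NLABL
  writeBin(raw(800), con)      # labels
  wFlt(as.numeric(v))
  invisible(path)
}
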