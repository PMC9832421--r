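#' Cubic voxel grid
#'
#' Container for a cubic density map. The first array index runs along x,
#' the box centre (`floor(box/2)` in 0-based voxel indices) is the origin of
#' the centred coordinate frame and the centre of the unit ball used by the
#' deformation basis.
#'
#' @param values cubic 3D numeric array.
#' @param voxel_size voxel sampling in Angstrom per voxel.
#' @return an object of class `volume_grid`.
#' @export
volume_grid <- function(values, voxel_size) {
  d <- dim(values)
  if (length(d) != 3L || length(unique(d)) != 1L)
    stop(sprintf("volume must be cubic; got %s", paste(d, collapse = "x")))
  if (!is.finite(voxel_size) || voxel_size <= 0)
    stop("voxel_size must be positive")
  structure(list(values = values, voxel_size = voxel_size),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("volume_grid: %d^3 voxels, %.4g A/voxel\n",
              dim(x$values)[1], x$voxel_size))
  invisible(x)
}

vol_box <- function(v) dim(v$values)[1]

#' Default physical radius of the unit ball for a volume
#'
#' The unit ball of the deformation basis is by default inscribed in the
#' volume box: radius `(box/2) * voxel_size` Angstrom.
#'
#' @param v a [volume_grid()].
#' @return radius in Angstrom.
#' @export
default_scale_radius <- function(v) vol_box(v) / 2 * v$voxel_size

# 0-based voxel index grid of the ball inscribed in an n-box, plus centred
# unit-ball coordinates of each ball voxel. Cached per box size.
ball_cache <- new.env(parent = emptyenv())
ball_voxels <- function(n) {
  key <- as.character(n)
  got <- ball_cache[[key]]
  if (!is.null(got)) return(got)
  c0 <- floor(n / 2)
  ax <- (0:(n - 1)) - c0
  g <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  u <- g / (n / 2)
  ok <- sqrt(rowSums(u^2)) <= 1
  out <- list(ijk = g[ok, , drop = FALSE] + c0, unit = u[ok, , drop = FALSE])
  ball_cache[[key]] <- out
  out
}

# --- MRC2014 I/O (mode 2, little-endian) ------------------------------------
# The MRC2014 map format: 1024-byte header followed by the voxel data with x
# fastest, matching this package's array layout directly.

mrc_read_header <- function(con) {
  h <- list()
  ints1 <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  h$nx <- ints1[1]; h$ny <- ints1[2]; h$nz <- ints1[3]; h$mode <- ints1[4]
  h$mx <- ints1[8]; h$my <- ints1[9]; h$mz <- ints1[10]
  cell <- readBin(con, "double", n = 6, size = 4, endian = "little")
  h$cella <- cell[1:3]
  maps <- readBin(con, "integer", n = 3, size = 4, endian = "little")
  h$mapc <- maps[1]; h$mapr <- maps[2]; h$maps <- maps[3]
  readBin(con, "double", n = 3, size = 4, endian = "little") # dmin/dmax/dmean
  h$ispg <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  h$nsymbt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  readBin(con, "raw", n = 1024 - 96) # rest of the 1024-byte header
  h
}

mrc_write_header <- function(con, nx, ny, nz, voxel_size, values, ispg) {
  writeBin(as.integer(c(nx, ny, nz, 2L, 0L, 0L, 0L, nx, ny, nz)), con,
           size = 4, endian = "little")
  writeBin(as.numeric(c(nx, ny, nz) * voxel_size), con, size = 4,
           endian = "little")
  writeBin(as.numeric(c(90, 90, 90)), con, size = 4, endian = "little")
  writeBin(as.integer(c(1L, 2L, 3L)), con, size = 4, endian = "little")
  writeBin(as.numeric(c(min(values), max(values), mean(values))), con,
           size = 4, endian = "little")
  writeBin(as.integer(c(ispg, 0L)), con, size = 4, endian = "little")
  writeBin(raw(100), con)                                   # extra space
  writeBin(as.numeric(c(0, 0, 0)), con, size = 4, endian = "little") # origin
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)          # little-endian
  writeBin(as.numeric(sd(as.numeric(values))), con, size = 4,
           endian = "little")
  writeBin(as.integer(0L), con, size = 4, endian = "little") # nlabl
  writeBin(raw(800), con)                                    # labels
}

#' Read a cubic volume from an MRC2014 file
#'
#' Accepts mode-2 (32-bit float) maps; the voxel size is taken from the cell
#' dimensions. Non-cubic maps (including 2D images stored as `nz = 1`) are
#' rejected with an explicit error.
#'
#' @param path file path.
#' @return a [volume_grid()].
#' @export
read_volume <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  h <- mrc_read_header(con)
  if (h$mode != 2L)
    stop(sprintf("unsupported MRC mode %d (only mode 2 float maps)", h$mode))
  if (h$nx != h$ny || h$ny != h$nz)
    stop(sprintf("volume is not cubic: nx=%d ny=%d nz=%d", h$nx, h$ny, h$nz))
  vals <- readBin(con, "double", n = h$nx * h$ny * h$nz, size = 4,
                  endian = "little")
  voxel <- if (h$mx > 0 && h$cella[1] > 0) h$cella[1] / h$mx else 1
  volume_grid(array(vals, dim = c(h$nx, h$ny, h$nz)), voxel)
}

#' Write a cubic volume to an MRC2014 file
#'
#' Writes a mode-2 map with the voxel size recorded in the header cell.
#'
#' @param v a [volume_grid()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "volume_grid"))
  n <- vol_box(v)
  con <- file(path, "wb"); on.exit(close(con))
  mrc_write_header(con, n, n, n, v$voxel_size, v$values, ispg = 1L)
  writeBin(as.numeric(v$values), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an MRC image stack
#'
#' Reads a mode-2 stack of square images (`nx = ny`, `nz` images).
#'
#' @param path file path.
#' @return list with `images` (list of matrices) and `pixel_size` (Angstrom).
#' @export
read_image_stack <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  h <- mrc_read_header(con)
  if (h$mode != 2L)
    stop(sprintf("unsupported MRC mode %d (only mode 2 float stacks)", h$mode))
  if (h$nx != h$ny)
    stop(sprintf("stack images are not square: nx=%d ny=%d", h$nx, h$ny))
  vals <- readBin(con, "double", n = h$nx * h$ny * h$nz, size = 4,
                  endian = "little")
  arr <- array(vals, dim = c(h$nx, h$ny, h$nz))
  pixel <- if (h$mx > 0 && h$cella[1] > 0) h$cella[1] / h$mx else 1
  list(images = lapply(seq_len(h$nz), function(k) arr[, , k]),
       pixel_size = pixel)
}

#' Write an MRC image stack
#'
#' @param images list of square matrices of identical size.
#' @param pixel_size pixel sampling in Angstrom.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(images, pixel_size, path) {
  stopifnot(length(images) >= 1)
  n <- nrow(images[[1]])
  arr <- array(unlist(images), dim = c(n, n, length(images)))
  con <- file(path, "wb"); on.exit(close(con))
  mrc_write_header(con, n, n, length(images), pixel_size, arr, ispg = 0L)
  writeBin(as.numeric(arr), con, size = 4, endian = "little")
  invisible(path)
}

#' Fourier-crop a volume to a smaller box
#'
#' Downsampling by cropping the centred Fourier spectrum, the standard
#' band-limiting decimation used on cryo-EM data before estimation. The
#' physical extent of the box is preserved: the voxel size grows by
#' `box/box_new`.
#'
#' @param v a [volume_grid()].
#' @param box_new target box (even, smaller than the input box).
#' @return a [volume_grid()] of the new box size.
#' @export
fourier_crop_volume <- function(v, box_new) {
  n <- vol_box(v)
  stopifnot(box_new <= n, box_new %% 2 == 0)
  if (box_new == n) return(v)
  ft <- fft(v$values)
  keep <- fft_keep_indices(n, box_new)
  out <- Re(fft(ft[keep, keep, keep], inverse = TRUE)) / n^3
  volume_grid(out, v$voxel_size * n / box_new)
}

#' Fourier-crop a square image to a smaller box
#'
#' @param img square numeric matrix.
#' @param box_new target box (even).
#' @return matrix of size `box_new` x `box_new`.
#' @export
fourier_crop_image <- function(img, box_new) {
  n <- nrow(img)
  stopifnot(box_new <= n, box_new %% 2 == 0)
  if (box_new == n) return(img)
  ft <- fft(img)
  keep <- fft_keep_indices(n, box_new)
  Re(fft(ft[keep, keep], inverse = TRUE)) / n^2
}

# 1-based indices of the frequencies -m/2 .. m/2-1 in an n-point DFT layout.
fft_keep_indices <- function(n, m) {
  f <- c(0:(m / 2 - 1), (-m / 2):(-1))
  ifelse(f >= 0, f + 1L, n + f + 1L)
}
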