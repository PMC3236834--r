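#' RGB image container
#'
#' Builds the in-memory representation of an 8-bit RGB image used throughout
#' the package: three integer matrices (one per channel) indexed `[row, col]`,
#' i.e. `[y + 1, x + 1]` in the package's pixel coordinate convention, where
#' pixel (0, 0) is the top-left corner, `x` grows rightward (columns) and `y`
#' grows downward (rows).
#'
#' @param r,g,b integer matrices of identical dimensions with values in
#'   0--255 (red, green and blue channels).
#' @return An object of class `rgb_image`: a list with elements `width`,
#'   `height`, `r`, `g`, `b`.
#' @export
rgb_image <- function(r, g, b) {
  r <- as.matrix(r); g <- as.matrix(g); b <- as.matrix(b)
  if (!identical(dim(r), dim(g)) || !identical(dim(r), dim(b)))
    stop("channel matrices must have identical dimensions")
  if (nrow(r) < 1L || ncol(r) < 1L) stop("image must contain at least one pixel")
  vals <- c(r, g, b)
  if (anyNA(vals) || any(vals < 0) || any(vals > 255))
    stop("channel values must lie in [0, 255]")
  structure(
    list(width = ncol(r), height = nrow(r),
         r = .int_mat(r), g = .int_mat(g), b = .int_mat(b)),
    class = "rgb_image"
  )
}

.int_mat <- function(m) matrix(as.integer(round(m)), nrow = nrow(m))

#' @export
print.rgb_image <- function(x, ...) {
  cat(sprintf("<rgb_image %d x %d>\n", x$width, x$height))
  invisible(x)
}

#' Binary mask container
#'
#' A per-pixel 0/1 mask paired with an RGB image of the same dimensions.
#' In memory the foreground is always coded 1; the `foreground` attribute
#' records what the foreground means semantically (e.g. `"dark"` for a mask
#' produced by intermeans thresholding, where the lesion is the dark class).
#'
#' @param m integer matrix of 0/1 values, `[row, col]` indexed like
#'   [rgb_image()] channels.
#' @param foreground short label describing the foreground convention.
#' @return An object of class `binary_mask`: a list with `width`, `height`,
#'   `fg` (the 0/1 matrix) and `foreground`.
#' @export
binary_mask <- function(m, foreground = "foreground") {
  m <- as.matrix(m)
  if (!all(m %in% c(0, 1))) stop("mask values must be 0 or 1")
  structure(
    list(width = ncol(m), height = nrow(m), fg = .int_mat(m),
         foreground = foreground),
    class = "binary_mask"
  )
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask %d x %d, %d foreground (%s)>\n",
              x$width, x$height, sum(x$fg), x$foreground))
  invisible(x)
}

#' Read an RGB image from PNG or PPM
#'
#' Reads an 8-bit image file into an [rgb_image()]. PNG (via the \pkg{png}
#' package) and binary PPM (P6) are supported. Grayscale inputs are promoted
#' to RGB by channel replication so that colour-aware clustering is always
#' applicable; alpha channels are dropped.
#'
#' @param path path to a `.png` or `.ppm` file.
#' @return An [rgb_image()].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: file not found: ", path)
  magic <- readBin(path, "raw", n = 8L)
  if (length(magic) >= 8L &&
      identical(magic[1:4], as.raw(c(0x89, 0x50, 0x4e, 0x47)))) {
    return(.read_png_rgb(path))
  }
  if (length(magic) >= 2L && rawToChar(magic[1:2]) == "P6") {
    return(.read_ppm_p6(path))
  }
  stop("unsupported image format (expected 8-bit PNG or binary PPM P6): ", path)
}

.read_png_rgb <- function(path) {
  hdr <- readBin(path, "raw", n = 26L)
  bitdepth <- as.integer(hdr[25L])  # IHDR bit depth byte
  if (!is.na(bitdepth) && bitdepth != 8L)
    stop("unsupported PNG bit depth: ", bitdepth, " (only 8-bit supported)")
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 1L))
  nc <- dim(a)[3L]
  to255 <- function(m) matrix(as.integer(round(m * 255)), nrow = dim(a)[1L])
  if (nc >= 3L) {
    rgb_image(to255(a[, , 1L]), to255(a[, , 2L]), to255(a[, , 3L]))
  } else {
    gm <- to255(a[, , 1L])  # grayscale (possibly + alpha): replicate
    rgb_image(gm, gm, gm)
  }
}

# Minimal binary PPM (P6, maxval 255) reader; no installed R package parses
# PPM so the format is handled directly.
.read_ppm_p6 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- function() {
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L || !nzchar(ch)) stop("truncated PPM header")
      if (ch == "#") {  # comment to end of line
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (!length(ch) || ch == "\n") break
        }
        next
      }
      if (grepl("[^[:space:]]", ch)) {
        out <- ch
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (!length(ch) || grepl("[[:space:]]", ch)) break
          out <- paste0(out, ch)
        }
        return(out)
      }
    }
  }
  if (tok() != "P6") stop("not a binary PPM (P6) file")
  w <- as.integer(tok()); h <- as.integer(tok()); maxval <- as.integer(tok())
  if (is.na(w) || is.na(h) || w < 1L || h < 1L) stop("invalid PPM dimensions")
  if (is.na(maxval) || maxval != 255L)
    stop("unsupported PPM maxval: ", maxval, " (only 8-bit/255 supported)")
  bytes <- readBin(con, "raw", n = 3L * w * h)
  if (length(bytes) < 3L * w * h) stop("truncated PPM pixel data")
  v <- as.integer(bytes)
  idx <- seq(1L, by = 3L, length.out = w * h)
  # pixel data is row-major; fill matrices accordingly
  shape <- function(ch) matrix(ch, nrow = h, ncol = w, byrow = TRUE)
  rgb_image(shape(v[idx]), shape(v[idx + 1L]), shape(v[idx + 2L]))
}

#' Write an RGB image as PNG
#'
#' @param img an [rgb_image()].
#' @param path output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "rgb_image"))
  a <- array(0, c(img$height, img$width, 3L))
  a[, , 1L] <- img$r / 255; a[, , 2L] <- img$g / 255; a[, , 3L] <- img$b / 255
  png::writePNG(a, target = path)
  invisible(path)
}

#' Write a binary mask as an 8-bit grayscale PNG
#'
#' Foreground pixels are written as 255 and background as 0; reading the file
#' back with [read_mask()] reproduces the mask exactly.
#'
#' @param mask a [binary_mask()].
#' @param path output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  png::writePNG(mask$fg * 1.0, target = path)
  invisible(path)
}

#' Read a binary mask from an 8-bit grayscale PNG
#'
#' Pixels with value >= 128 become foreground (1). Colour inputs are reduced
#' to luminance first.
#'
#' @param path path to a mask PNG.
#' @param foreground label recorded on the resulting mask.
#' @return A [binary_mask()].
#' @export
read_mask <- function(path, foreground = "foreground") {
  img <- read_image(path)
  g <- to_gray(img)
  binary_mask((g >= 128) * 1L, foreground = foreground)
}

#' Flatten an image into clustering points
#'
#' Converts an image (optionally restricted to the foreground of a companion
#' mask) into the point table consumed by the clustering functions: one row
#' per pixel with integer coordinates `x`, `y` (0-based, top-left origin) and
#' channels `r`, `g`, `b`. Rows are in deterministic row-major order (`y`
#' outer, `x` inner), which fixes the seed scan order of the clusterers.
#'
#' @param img an [rgb_image()].
#' @param mask optional [binary_mask()] of matching dimensions; when given,
#'   only foreground pixels are emitted (the binary clustering mode).
#' @return A `data.frame` with columns `x`, `y`, `r`, `g`, `b`.
#' @export
image_to_points <- function(img, mask = NULL) {
  stopifnot(inherits(img, "rgb_image"))
  w <- img$width; h <- img$height
  x <- rep.int(0:(w - 1L), h)
  y <- rep(0:(h - 1L), each = w)
  # row-major flattening: transpose so rows (y) vary slowest
  pts <- data.frame(
    x = x, y = y,
    r = as.vector(t(img$r)), g = as.vector(t(img$g)), b = as.vector(t(img$b))
  )
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "binary_mask"))
    if (mask$width != w || mask$height != h)
      stop("mask dimensions (", mask$width, "x", mask$height,
           ") do not match image (", w, "x", h, ")")
    pts <- pts[as.vector(t(mask$fg)) == 1L, , drop = FALSE]
    rownames(pts) <- NULL
  }
  pts
}

#' Build a mask from a subset of pixel coordinates
#'
#' Inverse of the point view: marks the listed pixels as foreground in a
#' `width` x `height` mask.
#'
#' @param x,y integer pixel coordinates (0-based).
#' @param width,height mask dimensions.
#' @param foreground label recorded on the mask.
#' @return A [binary_mask()].
#' @export
points_to_mask <- function(x, y, width, height, foreground = "foreground") {
  stopifnot(length(x) == length(y))
  m <- matrix(0L, nrow = height, ncol = width)
  if (length(x)) {
    if (any(x < 0 | x >= width | y < 0 | y >= height))
      stop("pixel coordinates outside the mask")
    m[cbind(y + 1L, x + 1L)] <- 1L
  }
  binary_mask(m, foreground = foreground)
}
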