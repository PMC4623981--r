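#' Create an empty framebuffer
#'
#' A framebuffer pairs a per-pixel RGB color store with a per-pixel linear
#' eye-space depth store (Angstrom). Background pixels carry the depth
#' sentinel `+Inf`, so any finite sample depth compares as nearer than
#' empty space. The framebuffer is the sole input of the SSAO post-process.
#'
#' @param width,height image dimensions in pixels (>= 1).
#' @param background RGB triple in `[0,1]` used for uncovered pixels.
#' @return an object of class `"framebuffer"`: a list with `color`
#'   (`height x width x 3` array, channels in `[0,1]`), `depth`
#'   (`height x width` matrix, Angstrom or `+Inf`) and `background`.
#' @export
new_framebuffer <- function(width, height, background = c(1, 1, 1)) {
  if (length(width) != 1 || length(height) != 1 || width < 1 || height < 1)
    stop("width and height must be >= 1")
  background <- as.numeric(background)
  stopifnot(length(background) == 3, all(background >= 0 & background <= 1))
  width <- as.integer(width); height <- as.integer(height)
  color <- array(rep(background, each = height * width),
                 dim = c(height, width, 3))
  fb <- list(color = color,
             depth = matrix(Inf, height, width),
             background = background)
  class(fb) <- "framebuffer"
  fb
}

#' @export
print.framebuffer <- function(x, ...) {
  n_fg <- sum(is.finite(x$depth))
  cat(sprintf("<framebuffer> %dx%d px, %d foreground pixels\n",
              ncol(x$depth), nrow(x$depth), n_fg))
  if (n_fg > 0)
    cat(sprintf("  depth range %.3f .. %.3f Angstrom\n",
                min(x$depth[is.finite(x$depth)]),
                max(x$depth[is.finite(x$depth)])))
  invisible(x)
}

fb_dim <- function(fb) c(nrow(fb$depth), ncol(fb$depth))

check_fb_camera <- function(fb, cam) {
  if (nrow(fb$depth) != cam$height || ncol(fb$depth) != cam$width)
    stop("framebuffer dimensions do not match the camera image size")
  invisible(TRUE)
}

#' Write a framebuffer to a color PNG plus raw depth grid
#'
#' The interchange format for the post-process-only path: an 8-bit RGB PNG
#' for color next to a raw 32-bit little-endian float grid for depth with a
#' 16-byte header (magic `"MDPT"`, int32 width, int32 height, 4 reserved
#' bytes). Background depth is stored as `+Inf`.
#'
#' @param fb a [new_framebuffer()] object.
#' @param png_path output path for the color PNG.
#' @param depth_path output path for the depth grid.
#' @export
write_framebuffer <- function(fb, png_path, depth_path) {
  png::writePNG(fb$color, png_path)
  con <- file(depth_path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("MDPT"), con)
  writeBin(as.integer(c(ncol(fb$depth), nrow(fb$depth))), con,
           size = 4L, endian = "little")
  writeBin(raw(4), con)
  # row-major: one image row (top to bottom) at a time
  writeBin(as.numeric(t(fb$depth)), con, size = 4L, endian = "little")
  invisible(fb)
}

#' Read a framebuffer from a color PNG plus raw depth grid
#'
#' @param png_path color PNG path (8-bit RGB or RGBA; alpha is dropped).
#' @param depth_path depth grid path in the format written by
#'   [write_framebuffer()].
#' @return a `"framebuffer"` object.
#' @export
read_framebuffer <- function(png_path, depth_path) {
  if (!file.exists(png_path)) stop("color file not found: ", png_path)
  if (!file.exists(depth_path)) stop("depth file not found: ", depth_path)
  col <- png::readPNG(png_path)
  if (length(dim(col)) == 2) col <- array(rep(col, 3), dim = c(dim(col), 3))
  if (dim(col)[3] > 3) col <- col[, , 1:3, drop = FALSE]
  con <- file(depth_path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4L)
  if (!identical(rawToChar(magic), "MDPT"))
    stop("bad depth grid magic (expected 'MDPT')")
  wh <- readBin(con, "integer", 2L, size = 4L, endian = "little")
  readBin(con, "raw", 4L)
  if (any(wh < 1L)) stop("bad depth grid dimensions")
  vals <- readBin(con, "numeric", wh[1] * wh[2], size = 4L,
                  endian = "little")
  if (length(vals) != wh[1] * wh[2]) stop("truncated depth grid")
  depth <- t(matrix(vals, nrow = wh[1], ncol = wh[2]))
  if (nrow(depth) != dim(col)[1] || ncol(depth) != dim(col)[2])
    stop("color and depth dimensions disagree")
  if (any(is.nan(depth)) || any(depth[is.finite(depth)] < 0))
    stop("depth grid contains negative or NaN values")
  fb <- list(color = col, depth = depth, background = c(1, 1, 1))
  class(fb) <- "framebuffer"
  fb
}
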