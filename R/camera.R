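#' Camera model
#'
#' Defines the viewpoint used by the rasterizer, the analytic depth renderer
#' and the SSAO back-projection. Scene coordinates are in Angstrom. Depth is
#' the *linear* eye-space distance along the view direction (not a normalized
#' device coordinate), so distances measured in the depth buffer are directly
#' comparable to scene distances and the sampling-sphere diameter is
#' meaningful in Angstrom.
#'
#' Pixel convention: pixel `(i, j)` (zero-based, `i` = column, `j` = row)
#' covers the half-open square `[i, i+1) x [j, j+1)`; its center is
#' `(i + 0.5, j + 0.5)`. The origin is the top-left corner of the image and
#' `y` increases downward. Continuous pixel coordinates are used throughout;
#' the image center is `(width/2, height/2)`.
#'
#' @param eye numeric length-3, camera position (Angstrom).
#' @param view numeric length-3, viewing direction (normalized internally).
#' @param up numeric length-3, approximate up direction (must not be parallel
#'   to `view`).
#' @param width,height image dimensions in pixels (>= 1).
#' @param mode `"orthographic"` or `"perspective"`.
#' @param scale Angstrom per pixel at the focal plane (orthographic mode).
#' @param fov vertical field of view in degrees (perspective mode).
#' @param near near clip distance in Angstrom (> 0).
#' @return an object of class `"camera"`.
#' @export
camera <- function(eye, view, up = c(0, 1, 0), width = 256L, height = 256L,
                   mode = c("orthographic", "perspective"),
                   scale = 1, fov = 35, near = 0.1) {
  mode <- match.arg(mode)
  eye <- as.numeric(eye); view <- as.numeric(view); up <- as.numeric(up)
  stopifnot(length(eye) == 3, length(view) == 3, length(up) == 3,
            all(is.finite(c(eye, view, up))),
            width >= 1, height >= 1, scale > 0, near > 0, fov > 0, fov < 180)
  nv <- sqrt(sum(view^2)); nu <- sqrt(sum(up^2))
  if (nv == 0 || nu == 0) stop("view and up must be non-zero vectors")
  view <- view / nv; up <- up / nu
  cr <- .cross(view, up)
  if (sqrt(sum(cr^2)) < 1e-6) stop("view and up directions are parallel")
  right <- cr / sqrt(sum(cr^2))
  down <- .cross(view, right)            # y increases downward in the image
  down <- down / sqrt(sum(down^2))
  cam <- list(mode = mode, eye = eye, view = view, up = up,
              right = right, down = down,
              width = as.integer(width), height = as.integer(height),
              scale = scale, fov = fov,
              focal_px = (height / 2) / tan(fov * pi / 360),
              near = near)
  class(cam) <- "camera"
  cam
}

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @export
print.camera <- function(x, ...) {
  cat(sprintf("<camera> %s %dx%d px, eye (%g, %g, %g)\n", x$mode,
              x$width, x$height, x$eye[1], x$eye[2], x$eye[3]))
  if (x$mode == "orthographic")
    cat(sprintf("  scale %g Angstrom/px, near %g\n", x$scale, x$near))
  else
    cat(sprintf("  fov %g deg (focal %g px), near %g\n", x$fov,
                x$focal_px, x$near))
  invisible(x)
}

#' Project scene points to continuous pixel coordinates and depth
#'
#' @param points numeric length-3 vector or N x 3 matrix of scene points
#'   (Angstrom).
#' @param cam a [camera()].
#' @return N x 3 matrix with columns `px`, `py` (continuous pixel
#'   coordinates, possibly outside the image) and `depth` (linear eye-space
#'   distance along the view direction, Angstrom).
#' @details Points at or behind the near clip plane raise an error.
#'   `project()` and [backproject()] are exact inverses on points in front
#'   of the near plane.
#' @export
project <- function(points, cam) {
  p <- .as_mat3(points)
  rel <- sweep(p, 2, cam$eye)
  d <- rel %*% cam$view
  if (any(d < cam$near - 1e-12))
    stop("point at or behind the near clip plane")
  lx <- rel %*% cam$right
  ly <- rel %*% cam$down
  if (cam$mode == "orthographic") {
    px <- cam$width / 2 + lx / cam$scale
    py <- cam$height / 2 + ly / cam$scale
  } else {
    px <- cam$width / 2 + lx / d * cam$focal_px
    py <- cam$height / 2 + ly / d * cam$focal_px
  }
  cbind(px = as.numeric(px), py = as.numeric(py), depth = as.numeric(d))
}

#' Back-project pixel coordinates and depth to a scene point
#'
#' Inverse of [project()]: recovers the 3D scene position of a pixel from
#' its continuous coordinates and its linear eye-space depth.
#'
#' @param px,py continuous pixel coordinates (vectors).
#' @param depth linear eye-space depth in Angstrom; must be finite
#'   (background pixels carry an infinite sentinel and cannot be
#'   back-projected).
#' @param cam a [camera()].
#' @return N x 3 matrix of scene points (Angstrom).
#' @export
backproject <- function(px, py, depth, cam) {
  if (any(!is.finite(depth)))
    stop("cannot back-project background (infinite) depth")
  if (any(depth < cam$near - 1e-12))
    stop("depth in front of the near clip plane")
  if (cam$mode == "orthographic") {
    lx <- (px - cam$width / 2) * cam$scale
    ly <- (py - cam$height / 2) * cam$scale
  } else {
    lx <- (px - cam$width / 2) * depth / cam$focal_px
    ly <- (py - cam$height / 2) * depth / cam$focal_px
  }
  n <- max(length(px), length(py), length(depth))
  matrix(cam$eye, n, 3, byrow = TRUE) +
    outer(as.numeric(lx), cam$right) +
    outer(as.numeric(ly), cam$down) +
    outer(as.numeric(depth), cam$view)
}

.as_mat3 <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3, byrow = TRUE)
  storage.mode(p) <- "double"
  p
}
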