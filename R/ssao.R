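#' SSAO parameters
#'
#' The user-facing knobs of the screen-space ambient occlusion
#' post-process. The two parameters that matter most visually are the
#' sampling-sphere `diameter` — which selects the spatial scale of the
#' cavities and pockets the shading emphasizes — and the `intensity` of the
#' darkening.
#'
#' @param mode `"point"` (hidden/visible sample-point ratio, per-pixel
#'   randomized, then blurred) or `"line"` (view-aligned chord clipping,
#'   deterministic, needs no blur).
#' @param diameter sampling-sphere diameter, > 0.
#' @param diameter_unit `"angstrom"` (scene units; the scale the shading
#'   highlights is fixed in object space) or `"pixel"` (qualitative
#'   screen-space slider; the sphere covers a fixed pixel footprint).
#' @param intensity darkening strength in `[0, 2]`.
#' @param n_samples number of sample points (point mode) or sampling lines
#'   (line mode), >= 1.
#' @param seed integer seed driving the kernel layout and the per-pixel
#'   kernel rotation; identical parameters give bit-identical results.
#' @param range_check when `TRUE` (default), point samples lying farther
#'   than `range_factor * diameter` behind the depth buffer count as
#'   visible, so foreground objects do not cast dark halos onto distant
#'   geometry. Line chords whose surface depth is that far in front fall
#'   back to the flat baseline fraction.
#' @param range_factor range-check distance in units of `diameter`.
#' @param blur_width odd width of the separable box blur applied to
#'   point-mode AO maps (default 7); `1` disables blurring.
#' @param randomize per-pixel random kernel rotation (point mode). On by
#'   default; turning it off reproduces the classic banding artifact.
#' @param blur_line also blur line-mode AO maps (off by default: line
#'   sampling has no randomization noise to remove).
#' @return an object of class `"ao_params"`.
#' @export
ao_params <- function(mode = c("line", "point"), diameter = 8,
                      diameter_unit = c("angstrom", "pixel"),
                      intensity = 1, n_samples = if (mode == "point") 64 else 32,
                      seed = 1L, range_check = TRUE, range_factor = 1,
                      blur_width = 7L, randomize = TRUE, blur_line = FALSE) {
  mode <- match.arg(mode)
  diameter_unit <- match.arg(diameter_unit)
  stopifnot(diameter > 0, intensity >= 0, intensity <= 2, n_samples >= 1,
            range_factor > 0, blur_width >= 1, blur_width %% 2 == 1)
  structure(list(mode = mode, diameter = diameter,
                 diameter_unit = diameter_unit, intensity = intensity,
                 n_samples = as.integer(n_samples), seed = as.integer(seed),
                 range_check = isTRUE(range_check),
                 range_factor = range_factor,
                 blur_width = as.integer(blur_width),
                 randomize = isTRUE(randomize),
                 blur_line = isTRUE(blur_line)),
            class = "ao_params")
}

#' @export
print.ao_params <- function(x, ...) {
  cat(sprintf(
    "<ao_params> %s sampling, diameter %g %s, intensity %g, n=%d, seed %d\n",
    x$mode, x$diameter, x$diameter_unit, x$intensity, x$n_samples, x$seed))
  invisible(x)
}

#' Build the sampling kernel
#'
#' Point mode: `n_samples` offsets drawn uniformly inside the unit ball,
#' deterministically from the seed (direction from normalized Gaussians,
#' radius from the cube-root transform). Line mode: a deterministic
#' sunflower-spiral layout of `n_samples` offsets inside the unit disk
#' (including the disk center), each carrying the half-length
#' `h = sqrt(1 - |o|^2)` of the view-aligned chord through the unit sphere
#' at that offset and a weight proportional to the chord length
#' (normalized to sum to 1).
#'
#' @param params an [ao_params()].
#' @return a list of class `"sample_kernel"`: point mode has `offsets`
#'   (n x 3); line mode has `offsets` (n x 2), `h`, `weights`.
#' @export
build_kernel <- function(params) {
  n <- params$n_samples
  if (params$mode == "point") {
    # deterministic from the seed; caller's RNG state is left untouched
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, globalenv())
      else if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv()))
    set.seed(params$seed)
    # depth-stratified uniform ball: half the offsets in the front
    # half-ball (z < 0), half in the back (z > 0), independent draws.
    # The marginal stays uniform in the ball, but the hidden ratio of an
    # open screen-parallel surface is exactly 1/2 (not binomially noisy),
    # so after the 2(r - 1/2) remap flat geometry renders exactly
    # undarkened. The stratification survives the per-pixel
    # randomization because that rotates only about the view axis.
    dirs <- matrix(stats::rnorm(3 * n), n, 3)
    len <- sqrt(rowSums(dirs^2)); len[len == 0] <- 1
    dirs <- dirs / len
    r <- stats::runif(n)^(1 / 3)
    offs <- dirs * r
    nh <- n %/% 2
    sgn <- c(rep(1, nh), rep(-1, n - nh))
    offs[, 3] <- sgn * abs(offs[, 3])
    k <- list(mode = "point", offsets = offs)
  } else {
    i <- seq_len(n) - 1
    r <- sqrt(i / n)                        # strictly < 1; i=0 is the center
    theta <- i * pi * (3 - sqrt(5))         # golden angle
    offs <- cbind(r * cos(theta), r * sin(theta))
    h <- sqrt(1 - r^2)
    k <- list(mode = "line", offsets = offs, h = h, weights = h / sum(h))
  }
  class(k) <- "sample_kernel"
  k
}

#' Sampling-sphere radius in pixels at a given depth
#'
#' Converts the configured diameter to a screen-space radius. In
#' `"angstrom"` mode the sphere has a fixed scene size: the pixel radius is
#' `(diameter/2)/scale` under an orthographic camera and
#' `(diameter/2) * focal_px / depth` under perspective. In `"pixel"` mode
#' the configured diameter already is a pixel measure and half of it is
#' returned unchanged, at any depth.
#'
#' @param params an [ao_params()].
#' @param cam a [camera()].
#' @param depth finite eye-space depth (Angstrom), vectorized.
#' @return pixel radius (vector matching `depth`).
#' @export
diameter_to_pixels <- function(params, cam, depth) {
  if (params$diameter_unit == "pixel")
    return(rep(params$diameter / 2, length(depth)))
  if (cam$mode == "orthographic")
    rep(params$diameter / 2 / cam$scale, length(depth))
  else
    params$diameter / 2 * cam$focal_px / depth
}

# sampling-sphere radius in scene units at a given depth (inverse mapping
# for pixel-unit diameters)
.radius_world <- function(params, cam, depth) {
  if (params$diameter_unit == "angstrom")
    return(rep(params$diameter / 2, length(depth)))
  if (cam$mode == "orthographic")
    rep(params$diameter / 2 * cam$scale, length(depth))
  else
    params$diameter / 2 * depth / cam$focal_px
}

# deterministic per-pixel uniforms: integer hash of (seed, x, y) expanded
# by an LCG; exact in doubles (all intermediates < 2^53)
.pixel_hash <- function(x, y, seed) {
  m <- 2^31
  h <- (x * 374761393 + y * 668265263) %% m
  h <- (h + (seed %% m) * 69069) %% m
  u <- matrix(0, length(x), 3)
  for (i in 1:3) {
    h <- (h * 1103515245 + 12345) %% m
    h <- (h * 1103515245 + 12345) %% m
    u[, i] <- (h + 0.5) / m
  }
  u
}

# per-pixel kernel randomization: rotate the kernel about the view axis
# by a hashed random angle and mirror the y component with probability
# 1/2. These transforms decorrelate neighboring pixels (removing the
# banding a fixed kernel produces) while preserving each offset's depth
# component, so the kernel's front/back stratification — and with it the
# exact flat-surface balance — survives the randomization.
.pixel_rotation <- function(u) {
  ang <- 2 * pi * u[, 1]
  list(cs = cos(ang), sn = sin(ang), mir = ifelse(u[, 2] > 0.5, -1, 1))
}

.rotate_offset <- function(rot, o) {
  oy <- rot$mir * o[2]
  cbind(rot$cs * o[1] - rot$sn * oy,
        rot$sn * o[1] + rot$cs * oy,
        o[3])
}

#' Point-sampling ambient occlusion
#'
#' For every foreground pixel the scene position is recovered by
#' back-projection and a sampling sphere of the configured diameter is
#' centered on it. The kernel of sample points is randomized per pixel by
#' a rotation about the view axis plus an optional mirror (derived
#' deterministically from the seed and the pixel coordinates; these
#' transforms preserve the kernel's front/back depth stratification, so
#' open flat surfaces stay exactly balanced while neighboring pixels are
#' decorrelated), each sample is projected back to the image, and its depth
#' is compared against the depth buffer at the pixel it lands in
#' (nearest-pixel lookup). Samples behind the stored surface count as
#' hidden — unless they are farther behind than
#' `range_factor * diameter` with the range check on, or land outside the
#' image or on background, in which cases they count as visible. The raw
#' hidden fraction `r` of an open flat surface is 1/2 (half the ball lies
#' behind any surface), so the stored coefficient is renormalized to
#' `A = clamp(2 (r - 1/2), 0, 1)`: flat renders undarkened, fully
#' enclosed renders black.
#'
#' @param fb a framebuffer.
#' @param cam the camera that produced `fb`.
#' @param params an [ao_params()] with `mode = "point"`.
#' @param raw return the raw hidden ratio instead of the remapped
#'   coefficient (background pixels then carry the flat baseline 1/2).
#' @return an occlusion map: `height x width` matrix in `[0, 1]`,
#'   background pixels 0 (or 1/2 when `raw`).
#' @export
ao_point <- function(fb, cam, params, raw = FALSE) {
  stopifnot(params$mode == "point")
  check_fb_camera(fb, cam)
  H <- cam$height; W <- cam$width
  A <- matrix(0, H, W)
  fg <- which(is.finite(fb$depth))
  if (length(fg) == 0) return(A)
  rows <- ((fg - 1L) %% H) + 1L
  cols <- ((fg - 1L) %/% H) + 1L
  px <- cols - 0.5; py <- rows - 0.5        # pixel centers, continuous coords
  d <- fb$depth[fg]
  Rw <- .radius_world(params, cam, d)
  persp <- cam$mode == "perspective"
  # camera-basis lateral coordinates of each pixel's scene point
  if (!persp) {
    lx <- (px - W / 2) * cam$scale
    ly <- (py - H / 2) * cam$scale
  } else {
    lx <- (px - W / 2) * d / cam$focal_px
    ly <- (py - H / 2) * d / cam$focal_px
  }
  kern <- build_kernel(params)
  if (params$randomize) {
    q <- .pixel_rotation(.pixel_hash(px - 0.5, py - 0.5, params$seed))
  } else q <- NULL
  range_cut <- params$range_factor *
    (if (params$diameter_unit == "angstrom") params$diameter else 2 * Rw)
  hidden <- numeric(length(fg))
  for (s in seq_len(params$n_samples)) {
    o <- kern$offsets[s, ]
    if (is.null(q)) {
      ox <- rep(o[1], length(fg)); oy <- rep(o[2], length(fg)); oz <- rep(o[3], length(fg))
    } else {
      ro <- .rotate_offset(q, o)
      ox <- ro[, 1]; oy <- ro[, 2]; oz <- ro[, 3]
    }
    sx_lat <- lx + Rw * ox
    sy_lat <- ly + Rw * oy
    sd <- d + Rw * oz
    if (!persp) {
      spx <- W / 2 + sx_lat / cam$scale
      spy <- H / 2 + sy_lat / cam$scale
    } else {
      spx <- W / 2 + sx_lat / sd * cam$focal_px
      spy <- H / 2 + sy_lat / sd * cam$focal_px
    }
    ci <- floor(spx); ri <- floor(spy)
    inb <- ci >= 0 & ci < W & ri >= 0 & ri < H & sd > 0
    zb <- rep(Inf, length(fg))
    zb[inb] <- fb$depth[cbind(ri[inb] + 1L, ci[inb] + 1L)]
    hid <- is.finite(zb) & sd > zb
    if (params$range_check) hid <- hid & (sd - zb) < range_cut
    hidden <- hidden + hid
  }
  ratio <- hidden / params$n_samples
  if (raw) {
    A[] <- 0.5
    A[fg] <- ratio
  } else {
    A[fg] <- pmin(pmax(2 * (ratio - 0.5), 0), 1)
  }
  A
}

#' Line-sampling ambient occlusion
#'
#' For every foreground pixel, `n_samples` view-aligned chords through the
#' sampling sphere are examined. A chord at disk offset `o` (pixel radius
#' `r_px`) spans eye-space depths `[d - h R, d + h R]`, where `d` is the
#' pixel's depth, `R` the sphere radius and `h = sqrt(1 - |o|^2)` the chord
#' half-length. The depth buffer value `z` at the chord's pixel clips the
#' chord: its hidden fraction is
#' `f = clamp((z_far - max(z_near, z)) / (z_far - z_near), 0, 1)`
#' (the max-min form). Chords landing off-image or on background (or
#' rejected by the range check) fall back to the flat baseline evaluated
#' with the center depth. The occlusion coefficient is the chord-length
#' weighted sum of the fractions, renormalized like point mode:
#' `A = clamp(2 (sum w f - 1/2), 0, 1)`. No per-pixel randomization is
#' used — the deterministic low-discrepancy layout leaves no banding to
#' suppress — so on a screen-parallel plane the result is exactly 0, not
#' just statistically small.
#'
#' @inheritParams ao_point
#' @param params an [ao_params()] with `mode = "line"`.
#' @return an occlusion map (matrix in `[0,1]`, background 0; with `raw`,
#'   the weighted hidden fraction with flat baseline 1/2).
#' @export
ao_line <- function(fb, cam, params, raw = FALSE) {
  stopifnot(params$mode == "line")
  check_fb_camera(fb, cam)
  H <- cam$height; W <- cam$width
  A <- matrix(0, H, W)
  fg <- which(is.finite(fb$depth))
  if (length(fg) == 0) return(A)
  rows <- ((fg - 1L) %% H) + 1L
  cols <- ((fg - 1L) %/% H) + 1L
  px <- cols - 0.5; py <- rows - 0.5
  d <- fb$depth[fg]
  Rw <- .radius_world(params, cam, d)
  rpx <- diameter_to_pixels(params, cam, d)
  kern <- build_kernel(params)
  range_cut <- params$range_factor *
    (if (params$diameter_unit == "angstrom") params$diameter else 2 * Rw)
  # accumulate the signed excess over the flat baseline: for a chord with
  # half-length h R, hidden fraction f = 1/2 + clamp((d - z)/(2 h R),
  # -1/2, 1/2) (equivalent to the max-min form); summing the excess
  # directly makes a flat surface give exactly 0, with no rounding residue
  excess <- numeric(length(fg))
  for (s in seq_len(params$n_samples)) {
    o <- kern$offsets[s, ]
    h <- kern$h[s]
    spx <- px + o[1] * rpx
    spy <- py + o[2] * rpx
    ci <- floor(spx); ri <- floor(spy)
    inb <- ci >= 0 & ci < W & ri >= 0 & ri < H
    z <- rep(NA_real_, length(fg))
    z[inb] <- fb$depth[cbind(ri[inb] + 1L, ci[inb] + 1L)]
    # off-image, background, or range-rejected chords use the flat baseline
    bad <- !inb | !is.finite(z)
    if (params$range_check) bad <- bad | (!bad & (d - z) > range_cut)
    g <- (d - z) / (2 * h * Rw)
    g[bad] <- 0
    g <- pmin(pmax(g, -0.5), 0.5)
    excess <- excess + kern$weights[s] * g
  }
  if (raw) {
    A[] <- 0.5
    A[fg] <- 0.5 + excess
  } else {
    A[fg] <- pmin(pmax(2 * excess, 0), 1)
  }
  A
}

#' Separable box blur of an occlusion map
#'
#' `width x width` box average decomposed into a horizontal then a vertical
#' pass; image borders are handled by clamp-to-edge replication. On
#' interior pixels the result equals the direct 2D box convolution exactly.
#' Used to remove the noise that per-pixel kernel randomization introduces
#' in point mode.
#'
#' @param ao occlusion map matrix.
#' @param width odd blur width (default 7).
#' @return blurred occlusion map.
#' @export
blur_separable <- function(ao, width = 7L) {
  if (width %% 2 != 1 || width < 1) stop("blur width must be odd and >= 1")
  if (width == 1) return(ao)
  half <- (width - 1L) %/% 2L
  pass <- function(m, along_rows) {
    n <- if (along_rows) ncol(m) else nrow(m)
    out <- 0
    for (k in -half:half) {
      idx <- pmin(pmax(seq_len(n) + k, 1L), n)
      out <- out + if (along_rows) m[, idx, drop = FALSE]
             else m[idx, , drop = FALSE]
    }
    out / width
  }
  pass(pass(ao, TRUE), FALSE)
}

#' Modulate a framebuffer's colors by an occlusion map
#'
#' Per channel: `color <- color * clamp(1 - intensity * A, 0, 1)`. Depth and
#' background pixels are untouched.
#'
#' @param fb a framebuffer.
#' @param ao occlusion map with matching dimensions.
#' @param intensity darkening strength (>= 0).
#' @return the updated framebuffer.
#' @export
modulate <- function(fb, ao, intensity = 1) {
  stopifnot(all(dim(ao) == dim(fb$depth)), intensity >= 0)
  fac <- pmin(pmax(1 - intensity * ao, 0), 1)
  fac[!is.finite(fb$depth)] <- 1
  for (ch in 1:3) fb$color[, , ch] <- fb$color[, , ch] * fac
  fb
}

#' Apply the full SSAO post-process
#'
#' The three sequential buffer transforms: occlusion sampling (point or
#' line mode), separable blur (point mode by default; line mode only when
#' `blur_line` is set), and color modulation. A pure function of its
#' inputs: identical `(fb, cam, params)` give bit-identical output.
#'
#' @param fb a framebuffer (color + linear depth).
#' @param cam the camera that produced `fb`.
#' @param params an [ao_params()].
#' @param return_ao also return the (blurred) occlusion map.
#' @return the modulated framebuffer; if `return_ao`, a list
#'   `list(fb, ao)`.
#' @export
apply_ssao <- function(fb, cam, params = ao_params(), return_ao = FALSE) {
  ao <- if (params$mode == "point") ao_point(fb, cam, params)
        else ao_line(fb, cam, params)
  do_blur <- (params$mode == "point" && params$blur_width > 1) ||
    (params$mode == "line" && params$blur_line && params$blur_width > 1)
  if (do_blur) ao <- blur_separable(ao, params$blur_width)
  out <- modulate(fb, ao, params$intensity)
  if (return_ao) list(fb = out, ao = ao) else out
}
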