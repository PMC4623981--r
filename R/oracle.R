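#' Analytic scenes for ground-truth ambient occlusion
#'
#' An analytic scene is a collection of signed primitives with exact
#' ray-intersection queries: infinite or bounded planes, spheres and
#' spherical caps, open cylinder walls and disks. Scenes double as ground
#' truth for the hemisphere-integration oracle and as exact depth-buffer
#' sources for SSAO (no rasterization error).
#'
#' Primitives (all sizes in Angstrom):
#' * `prim_plane(point, normal, hole_center, hole_radius, bounds)` —
#'   infinite plane, optionally with a circular hole and half-space bounds
#'   (a list of `list(dir, max)` constraints `dot(hit, dir) <= max`).
#' * `prim_sphere(center, radius, cap_dir, cap_max)` — sphere, optionally
#'   keeping only hits with `dot(hit - center, cap_dir) <= cap_max` (a
#'   spherical cap, e.g. the bowl of a hemispherical pit).
#' * `prim_cylinder(base, axis, radius, h0, h1)` — open lateral wall with
#'   hits kept for axial height in `[h0, h1]`.
#' * `prim_disk(center, normal, radius)`.
#'
#' @param ... primitives.
#' @param base_color flat color used by [render_analytic_depth()].
#' @return an object of class `"analytic_scene"`.
#' @name analytic_scene
NULL

#' @rdname analytic_scene
#' @export
analytic_scene <- function(..., base_color = c(0.7, 0.7, 0.7)) {
  prims <- list(...)
  if (length(prims) == 1 && is.list(prims[[1]]) &&
      !inherits(prims[[1]], "scene_prim") && is.null(prims[[1]]$type))
    prims <- prims[[1]]
  structure(list(primitives = prims, base_color = as.numeric(base_color)),
            class = "analytic_scene")
}

#' @export
print.analytic_scene <- function(x, ...) {
  cat(sprintf("<analytic_scene> %d primitives (%s)\n",
              length(x$primitives),
              paste(vapply(x$primitives, function(p) p$type, ""),
                    collapse = ", ")))
  invisible(x)
}

#' @rdname analytic_scene
#' @export
prim_plane <- function(point, normal, hole_center = NULL, hole_radius = 0,
                       bounds = list()) {
  normal <- normal / sqrt(sum(normal^2))
  structure(list(type = "plane", point = as.numeric(point), normal = normal,
                 hole_center = hole_center, hole_radius = hole_radius,
                 bounds = bounds), class = "scene_prim")
}

#' @rdname analytic_scene
#' @export
prim_sphere <- function(center, radius, cap_dir = NULL, cap_max = NULL) {
  structure(list(type = "sphere", center = as.numeric(center),
                 radius = radius, cap_dir = cap_dir, cap_max = cap_max),
            class = "scene_prim")
}

#' @rdname analytic_scene
#' @export
prim_cylinder <- function(base, axis, radius, h0, h1) {
  axis <- axis / sqrt(sum(axis^2))
  structure(list(type = "cylinder", base = as.numeric(base), axis = axis,
                 radius = radius, h0 = h0, h1 = h1), class = "scene_prim")
}

#' @rdname analytic_scene
#' @export
prim_disk <- function(center, normal, radius) {
  normal <- normal / sqrt(sum(normal^2))
  structure(list(type = "disk", center = as.numeric(center),
                 normal = normal, radius = radius), class = "scene_prim")
}

# nearest-hit parameter t for a batch of rays against one primitive;
# Inf where the ray misses. origins, dirs: N x 3.
.prim_intersect <- function(p, origins, dirs, tmin = 1e-9) {
  n <- nrow(origins)
  t <- rep(Inf, n)
  if (p$type == "plane" || p$type == "disk") {
    nrm <- if (p$type == "plane") p$normal else p$normal
    pt <- if (p$type == "plane") p$point else p$center
    denom <- dirs %*% nrm
    num <- (matrix(pt, n, 3, byrow = TRUE) - origins) %*% nrm
    tc <- as.numeric(num) / as.numeric(denom)
    ok <- is.finite(tc) & tc > tmin & abs(as.numeric(denom)) > 1e-14
    if (any(ok)) {
      hit <- origins[ok, , drop = FALSE] + tc[ok] * dirs[ok, , drop = FALSE]
      keep <- rep(TRUE, sum(ok))
      if (p$type == "disk") {
        r2 <- rowSums((hit - matrix(pt, sum(ok), 3, byrow = TRUE))^2)
        keep <- r2 <= p$radius^2
      } else {
        if (!is.null(p$hole_center) && p$hole_radius > 0) {
          rel <- hit - matrix(p$hole_center, sum(ok), 3, byrow = TRUE)
          rel <- rel - as.numeric(rel %*% p$normal) %o% p$normal
          keep <- keep & rowSums(rel^2) >= p$hole_radius^2
        }
        if (!is.null(p$multi_hole)) {
          # disk-shaped plane patch with several circular holes
          mh <- p$multi_hole
          r2 <- hit[, 1]^2 + hit[, 2]^2
          keep <- keep & r2 <= mh$basin_r^2
          for (i in seq_len(nrow(mh$centers))) {
            dd <- (hit[, 1] - mh$centers[i, 1])^2 +
              (hit[, 2] - mh$centers[i, 2])^2
            keep <- keep & dd >= mh$pit_r^2
          }
        }
        for (b in p$bounds)
          keep <- keep & as.numeric(hit %*% (b$dir / sqrt(sum(b$dir^2)))) <=
            b$max + 1e-12
      }
      tt <- tc[ok]; tt[!keep] <- Inf
      t[ok] <- tt
    }
  } else if (p$type == "sphere") {
    oc <- origins - matrix(p$center, n, 3, byrow = TRUE)
    a <- rowSums(dirs^2)
    b <- rowSums(oc * dirs)
    c_ <- rowSums(oc^2) - p$radius^2
    disc <- b^2 - a * c_
    ok <- disc >= 0
    if (any(ok)) {
      sq <- sqrt(disc[ok])
      t1 <- (-b[ok] - sq) / a[ok]
      t2 <- (-b[ok] + sq) / a[ok]
      cand <- cbind(t1, t2)
      cand[cand <= tmin] <- Inf
      if (!is.null(p$cap_dir)) {
        for (j in 1:2) {
          hit <- origins[ok, , drop = FALSE] +
            cand[, j] * dirs[ok, , drop = FALSE]
          hgt <- as.numeric((hit - matrix(p$center, sum(ok), 3,
                                          byrow = TRUE)) %*% p$cap_dir)
          cand[is.finite(cand[, j]) & hgt > p$cap_max + 1e-12, j] <- Inf
        }
      }
      t[ok] <- pmin(cand[, 1], cand[, 2])
    }
  } else if (p$type == "cylinder") {
    rel <- origins - matrix(p$base, n, 3, byrow = TRUE)
    ax <- p$axis
    rel_perp <- rel - as.numeric(rel %*% ax) %o% ax
    dir_perp <- dirs - as.numeric(dirs %*% ax) %o% ax
    a <- rowSums(dir_perp^2)
    b <- rowSums(rel_perp * dir_perp)
    c_ <- rowSums(rel_perp^2) - p$radius^2
    disc <- b^2 - a * c_
    ok <- disc >= 0 & a > 1e-14
    if (any(ok)) {
      sq <- sqrt(disc[ok])
      cand <- cbind((-b[ok] - sq) / a[ok], (-b[ok] + sq) / a[ok])
      cand[cand <= tmin] <- Inf
      for (j in 1:2) {
        hit <- origins[ok, , drop = FALSE] +
          cand[, j] * dirs[ok, , drop = FALSE]
        hgt <- as.numeric((hit - matrix(p$base, sum(ok), 3,
                                        byrow = TRUE)) %*% ax)
        cand[is.finite(cand[, j]) &
               (hgt < p$h0 - 1e-12 | hgt > p$h1 + 1e-12), j] <- Inf
      }
      t[ok] <- pmin(cand[, 1], cand[, 2])
    }
  } else stop("unknown primitive type ", p$type)
  t
}

#' Nearest ray-scene intersection
#'
#' @param scene an [analytic_scene()].
#' @param origins,dirs N x 3 matrices of ray origins and (not necessarily
#'   unit) directions.
#' @return vector of nearest hit parameters `t` (`Inf` = miss).
#' @export
intersect_scene <- function(scene, origins, dirs) {
  origins <- .as_mat3(origins); dirs <- .as_mat3(dirs)
  t <- rep(Inf, nrow(origins))
  for (p in scene$primitives)
    t <- pmin(t, .prim_intersect(p, origins, dirs))
  t
}

#' Ground-truth ambient occlusion by hemisphere ray casting
#'
#' Monte-Carlo estimate of the cosine-weighted blocked fraction of the
#' hemisphere above a surface point: the ambient-occlusion integral with
#' binary visibility. Directions are drawn cosine-weighted (unit-disk
#' mapping, so the cosine factor is absorbed into the sampling density) and
#' a ray counts as blocked when it hits scene geometry within `max_range`.
#' The standard error of the estimate scales as `1/sqrt(n_rays)`.
#'
#' @param scene an [analytic_scene()].
#' @param position surface point (Angstrom).
#' @param normal unit surface normal at `position`.
#' @param n_rays number of rays (>= 1).
#' @param seed RNG seed (deterministic result).
#' @param max_range rays hitting farther than this do not count as
#'   blocking (`Inf` = unbounded). A finite range matching the SSAO
#'   sampling-sphere radius makes oracle and screen-space estimates
#'   comparable, since SSAO is inherently local.
#' @return blocked fraction in `[0, 1]`.
#' @export
brute_force_ao <- function(scene, position, normal, n_rays = 10000,
                           seed = 1L, max_range = Inf) {
  stopifnot(n_rays >= 1)
  normal <- normal / sqrt(sum(normal^2))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  u1 <- stats::runif(n_rays); u2 <- stats::runif(n_rays)
  r <- sqrt(u1); th <- 2 * pi * u2
  lx <- r * cos(th); ly <- r * sin(th); lz <- sqrt(pmax(0, 1 - u1))
  # orthonormal frame around the normal
  aux <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  t1 <- .cross(normal, aux); t1 <- t1 / sqrt(sum(t1^2))
  t2 <- .cross(normal, t1)
  dirs <- outer(lx, t1) + outer(ly, t2) + outer(lz, normal)
  origins <- matrix(position + 1e-7 * normal, n_rays, 3, byrow = TRUE)
  t <- intersect_scene(scene, origins, dirs)
  mean(is.finite(t) & t <= max_range)
}

#' Render an exact depth buffer of an analytic scene
#'
#' Casts the camera ray through every pixel center and stores the nearest
#' hit's linear eye-space depth (background sentinel on a miss) with a flat
#' scene color. Produces rasterization-error-free inputs for comparing the
#' SSAO estimate against the hemisphere oracle.
#'
#' @param scene an [analytic_scene()].
#' @param cam a [camera()].
#' @param lighting optional [lighting_params()]; when supplied, hits are
#'   Phong-shaded using the analytic surface normal obtained by numerical
#'   gradient of the hit primitive (flat gray otherwise).
#' @return a framebuffer.
#' @export
render_analytic_depth <- function(scene, cam, lighting = NULL) {
  W <- cam$width; H <- cam$height
  fb <- new_framebuffer(W, H)
  px <- rep(seq_len(W) - 0.5, each = H)
  py <- rep(seq_len(H) - 0.5, times = W)
  if (cam$mode == "orthographic") {
    origins <- matrix(cam$eye, W * H, 3, byrow = TRUE) +
      outer((px - W / 2) * cam$scale, cam$right) +
      outer((py - H / 2) * cam$scale, cam$down)
    dirs <- matrix(cam$view, W * H, 3, byrow = TRUE)
  } else {
    dx <- (px - W / 2) / cam$focal_px
    dy <- (py - H / 2) / cam$focal_px
    origins <- matrix(cam$eye, W * H, 3, byrow = TRUE)
    dirs <- outer(dx, cam$right) + outer(dy, cam$down) +
      matrix(cam$view, W * H, 3, byrow = TRUE)
  }
  t <- intersect_scene(scene, origins, dirs)
  # depth = distance along the view direction; dirs have view component 1
  hit <- is.finite(t) & t >= cam$near
  depth <- rep(Inf, W * H)
  depth[hit] <- t[hit]
  fb$depth <- matrix(depth, H, W)          # px varies with column: H-major
  for (ch in 1:3) {
    plane <- matrix(fb$background[ch], H, W)
    plane[is.finite(fb$depth)] <- scene$base_color[ch]
    fb$color[, , ch] <- plane
  }
  fb
}

#' Reference analytic scenes
#'
#' Four canonical local geometries used to validate the concavity response
#' of the SSAO estimate against the hemisphere oracle, each returned with a
#' key surface sample (position + normal), a camera factory and the key
#' pixel it maps to:
#' * `"flat"` — an open plane; true AO 0.
#' * `"convex"` — a sphere resting on a plane, sampled at the apex; no
#'   upward ray can be blocked, true AO 0.
#' * `"corner"` — a step: floor meeting a raised slab of height
#'   `2 * size` (a right-angle concave corner), sampled on the floor at
#'   distance `size / 2` from the wall, where the wall blocks a
#'   substantial but sub-half fraction of the hemisphere.
#' * `"pit"` — a hemispherical pit of radius `size` carved into a plane,
#'   sampled at the pit bottom; true unbounded-range AO 1/2, and still
#'   1/2 for any occlusion range of at least `2 * size` (every wall
#'   chord from the bottom is shorter than the pit diameter).
#'
#' @param kind scene kind.
#' @param size feature size in Angstrom (sphere/pit radius, step height).
#' @param plane_depth distance of the reference plane from the camera eye.
#' @return a list with `scene`, `sample` (`position`, `normal`),
#'   `camera(width, height, scale)` and `key_pixel(cam)` giving the
#'   continuous pixel coordinates of the key sample.
#' @export
reference_scene <- function(kind = c("flat", "convex", "corner", "pit"),
                            size = 4, plane_depth = 50) {
  kind <- match.arg(kind)
  # camera on +z looking down -z; the reference plane is z = 0
  eye <- c(0, 0, plane_depth)
  cam_factory <- function(width = 128, height = 128, scale = 0.25)
    camera(eye, view = c(0, 0, -1), up = c(0, 1, 0), width = width,
           height = height, mode = "orthographic", scale = scale)
  up <- c(0, 0, 1)
  if (kind == "flat") {
    scene <- analytic_scene(prim_plane(c(0, 0, 0), up))
    sample <- list(position = c(0, 0, 0), normal = up)
  } else if (kind == "convex") {
    scene <- analytic_scene(
      prim_sphere(c(0, 0, size), size),
      prim_plane(c(0, 0, 0), up))
    sample <- list(position = c(0, 0, 2 * size), normal = up)
  } else if (kind == "corner") {
    h <- 2 * size
    scene <- analytic_scene(
      prim_plane(c(0, 0, 0), up,
                 bounds = list(list(dir = c(1, 0, 0), max = 0))),
      prim_plane(c(0, 0, h), up,
                 bounds = list(list(dir = c(-1, 0, 0), max = 0))),
      prim_plane(c(0, 0, 0), c(-1, 0, 0),
                 bounds = list(list(dir = c(0, 0, 1), max = h),
                               list(dir = c(0, 0, -1), max = 0))))
    sample <- list(position = c(-size / 2, 0, 0), normal = up)
  } else {
    scene <- analytic_scene(
      prim_plane(c(0, 0, 0), up, hole_center = c(0, 0, 0),
                 hole_radius = size),
      prim_sphere(c(0, 0, 0), size, cap_dir = up, cap_max = 0))
    sample <- list(position = c(0, 0, -size), normal = up)
  }
  key_pixel <- function(cam) {
    pr <- project(sample$position + 1e-9 * up, cam)
    c(pr[1, 1], pr[1, 2])
  }
  list(kind = kind, scene = scene, sample = sample,
       camera = cam_factory, key_pixel = key_pixel)
}

#' Infinite right-angle concave corner (closed-form oracle check)
#'
#' Floor and an infinite wall meeting at a right angle; for a point on the
#' edge line the wall blocks exactly a cosine-weighted half of the
#' hemisphere, so the true AO is 1/2.
#' @return an [analytic_scene()].
#' @export
corner_scene_infinite <- function() {
  analytic_scene(
    prim_plane(c(0, 0, 0), c(0, 0, 1),
               bounds = list(list(dir = c(1, 0, 0), max = 0))),
    prim_plane(c(0, 0, 0), c(-1, 0, 0),
               bounds = list(list(dir = c(0, 0, -1), max = 0))))
}

#' Cylindrical pit in a plane
#'
#' @param radius pit radius (Angstrom).
#' @param depth pit depth (Angstrom).
#' @param center xy center of the pit mouth on the plane z = 0.
#' @return an [analytic_scene()].
#' @export
cylinder_pit_scene <- function(radius = 3, depth = 3, center = c(0, 0)) {
  up <- c(0, 0, 1)
  analytic_scene(
    prim_plane(c(0, 0, 0), up, hole_center = c(center, 0),
               hole_radius = radius),
    prim_cylinder(c(center, -depth), up, radius, 0, depth),
    prim_disk(c(center, -depth), up, radius))
}
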