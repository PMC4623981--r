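#' Local lighting parameters
#'
#' Classic Phong local illumination: ambient + Lambert diffuse + Phong
#' specular. These are the per-fragment lighting terms that SSAO then
#' modulates; they provide only a locally plausible approximation, with no
#' inter-object shadowing.
#'
#' @param light direction *toward* the light source (normalized internally).
#' @param ambient,diffuse,specular non-negative term weights.
#' @param shininess Phong exponent (>= 1).
#' @return an object of class `"lighting_params"`.
#' @export
lighting_params <- function(light = c(-0.3, -0.5, 1), ambient = 0.2,
                            diffuse = 0.7, specular = 0.3, shininess = 32) {
  light <- as.numeric(light)
  stopifnot(length(light) == 3, sum(light^2) > 0,
            ambient >= 0, diffuse >= 0, specular >= 0, shininess >= 1)
  structure(list(light = light / sqrt(sum(light^2)), ambient = ambient,
                 diffuse = diffuse, specular = specular,
                 shininess = shininess),
            class = "lighting_params")
}

#' Phong shading of a fragment
#'
#' `color = base * (ambient + diffuse * max(0, n.l)) +
#'  specular * max(0, r.v)^shininess`, clamped to `[0,1]`, where `r` is the
#' light direction reflected about the normal and `v` points toward the eye.
#'
#' @param normal N x 3 matrix of unit surface normals.
#' @param view_dir N x 3 matrix of unit directions from surface toward the
#'   eye.
#' @param base_color N x 3 matrix (or length-3 vector) of base RGB.
#' @param lighting a [lighting_params()] object.
#' @return N x 3 matrix of shaded RGB in `[0,1]`.
#' @export
local_shade <- function(normal, view_dir, base_color, lighting) {
  n <- .as_mat3(normal); v <- .as_mat3(view_dir)
  if (is.null(dim(base_color)) || nrow(base_color) == 1)
    base_color <- matrix(as.numeric(base_color), nrow(n), 3, byrow = TRUE)
  l <- lighting$light
  ndl <- pmax(0, as.numeric(n %*% l))
  # r = 2 (n.l) n - l, the mirror reflection of the light direction
  r <- 2 * (as.numeric(n %*% l)) * n -
    matrix(l, nrow(n), 3, byrow = TRUE)
  rdv <- pmax(0, rowSums(r * v))
  spec <- lighting$specular * rdv^lighting$shininess
  out <- base_color * (lighting$ambient + lighting$diffuse * ndl) + spec
  pmin(pmax(out, 0), 1)
}

# Depth-test write helper: strict less-than, ties broken by lower primitive
# index so rendering is independent of primitive submission order.
.fragment_write <- function(state, rows, cols, depth, rgb, prim_idx) {
  prim_idx <- rep_len(prim_idx, length(depth))
  lin <- (cols - 1L) * nrow(state$depth) + rows
  old_d <- state$depth[lin]
  old_i <- state$prim[lin]
  win <- depth < old_d | (depth == old_d & prim_idx < old_i)
  if (any(win)) {
    lin <- lin[win]
    state$depth[lin] <- depth[win]
    state$prim[lin] <- prim_idx[win]
    hw <- nrow(state$depth) * ncol(state$depth)
    state$color[lin] <- rgb[win, 1]
    state$color[lin + hw] <- rgb[win, 2]
    state$color[lin + 2 * hw] <- rgb[win, 3]
  }
  state
}

.raster_state <- function(fb) {
  list(color = fb$color, depth = fb$depth,
       prim = matrix(Inf, nrow(fb$depth), ncol(fb$depth)))
}

.raster_finish <- function(fb, state) {
  fb$color <- state$color
  fb$depth <- state$depth
  fb
}

#' Rasterize van der Waals spheres into a framebuffer
#'
#' Exact per-pixel sphere impostors: for every sphere and every pixel center
#' in its screen bounding box the analytic ray-sphere intersection is
#' solved; the nearest intersection competes in a strict less-than depth
#' test (equal depths are won by the lower atom index). Winning fragments
#' store linear eye-space depth and a Phong-shaded color computed from the
#' exact sphere normal. No anti-aliasing, no tessellation error.
#'
#' @param atoms an [atom_set()].
#' @param cam a [camera()] whose image size matches `fb`.
#' @param fb a [new_framebuffer()] to render into.
#' @param lighting a [lighting_params()].
#' @return the updated framebuffer.
#' @export
rasterize_spheres <- function(atoms, cam, fb,
                              lighting = lighting_params()) {
  check_fb_camera(fb, cam)
  st <- .raster_state(fb)
  if (n_atoms(atoms) == 0) return(.raster_finish(fb, st))
  W <- cam$width; H <- cam$height
  persp <- cam$mode == "perspective"
  for (a in seq_len(n_atoms(atoms))) {
    ctr <- atoms$positions[a, ]
    R <- atoms$radii[a]
    cd <- sum((ctr - cam$eye) * cam$view)
    if (cd + R <= cam$near) next
    # conservative screen bounding box of the sphere
    cl <- sum((ctr - cam$eye) * cam$right)
    cu <- sum((ctr - cam$eye) * cam$down)
    if (!persp) {
      cx <- W / 2 + cl / cam$scale; cy <- H / 2 + cu / cam$scale
      pr <- R / cam$scale
    } else {
      dmin <- max(cd - R, cam$near)
      cx <- W / 2 + cl / cd * cam$focal_px
      cy <- H / 2 + cu / cd * cam$focal_px
      pr <- R * cam$focal_px / dmin *
        sqrt(1 + (cl^2 + cu^2) / cd^2)      # margin for oblique views
    }
    x0 <- max(0L, as.integer(floor(cx - pr - 1))); x1 <- min(W - 1L, as.integer(ceiling(cx + pr)))
    y0 <- max(0L, as.integer(floor(cy - pr - 1))); y1 <- min(H - 1L, as.integer(ceiling(cy + pr)))
    if (x0 > x1 || y0 > y1) next
    xs <- x0:x1; ys <- y0:y1
    pxc <- rep(xs + 0.5, each = length(ys))
    pyc <- rep(ys + 0.5, times = length(xs))
    if (!persp) {
      ox <- (pxc - W / 2) * cam$scale - cl
      oy <- (pyc - H / 2) * cam$scale - cu
      s2 <- ox^2 + oy^2
      hit <- s2 <= R^2
      if (!any(hit)) next
      hz <- sqrt(R^2 - s2[hit])
      depth <- cd - hz
      keep <- depth >= cam$near
      if (!any(keep)) next
      idx <- which(hit)[keep]
      depth <- depth[keep]
      # normal in camera basis: lateral offset / R, pointing toward the eye
      nx <- ox[idx] / R; ny <- oy[idx] / R; nz <- -sqrt(pmax(0, 1 - ox[idx]^2 / R^2 - oy[idx]^2 / R^2))
      nrm <- outer(nx, cam$right) + outer(ny, cam$down) + outer(nz, cam$view)
      vdir <- matrix(-cam$view, length(idx), 3, byrow = TRUE)
    } else {
      # ray through each pixel center
      dx <- (pxc - W / 2) / cam$focal_px
      dy <- (pyc - H / 2) / cam$focal_px
      dl <- sqrt(1 + dx^2 + dy^2)
      oc <- cam$eye - ctr
      # direction (unnormalized) d = view + dx*right + dy*down
      dvec <- cbind(dx, dy, 1)            # in (right, down, view) basis
      occ <- c(sum(oc * cam$right), sum(oc * cam$down), sum(oc * cam$view))
      bq <- dvec[, 1] * occ[1] + dvec[, 2] * occ[2] + dvec[, 3] * occ[3]
      aq <- dl^2
      cq <- sum(occ^2) - R^2
      disc <- bq^2 - aq * cq
      hit <- disc >= 0
      if (!any(hit)) next
      t <- (-bq[hit] - sqrt(disc[hit])) / aq[hit]   # nearest root
      depth <- t * 1                                 # t multiplies view comp = 1
      keep <- depth >= cam$near & t > 0
      if (!any(keep)) next
      idx <- which(hit)[keep]
      t <- t[keep]; depth <- depth[keep]
      hitp <- matrix(cam$eye, length(idx), 3, byrow = TRUE) +
        outer(t * dx[idx], cam$right) + outer(t * dy[idx], cam$down) +
        outer(t, cam$view)
      nrm <- sweep(hitp, 2, ctr) / R
      vdir <- -(outer(dx[idx], cam$right) + outer(dy[idx], cam$down) +
                  matrix(cam$view, length(idx), 3, byrow = TRUE)) / dl[idx]
    }
    rgb <- local_shade(nrm, vdir, atoms$colors[a, ], lighting)
    rows <- as.integer(pyc[idx] - 0.5) + 1L
    cols <- as.integer(pxc[idx] - 0.5) + 1L
    st <- .fragment_write(st, rows, cols, depth, rgb, a)
  }
  .raster_finish(fb, st)
}

#' Rasterize a triangle mesh into a framebuffer
#'
#' Projects each triangle and fills pixels whose centers fall inside the
#' projected triangle using a top-left fill rule, so pixels on an edge
#' shared by two triangles are written exactly once. Depth is interpolated
#' barycentrically (perspective-correct under a perspective camera);
#' normals are interpolated from vertex normals and renormalized, and
#' shading is evaluated per pixel (Phong shading). Back faces are kept:
#' isosurface meshes may be open.
#'
#' @param mesh a [triangle_mesh()].
#' @inheritParams rasterize_spheres
#' @return the updated framebuffer.
#' @export
rasterize_mesh <- function(mesh, cam, fb, lighting = lighting_params()) {
  check_fb_camera(fb, cam)
  st <- .raster_state(fb)
  if (nrow(mesh$triangles) == 0) return(.raster_finish(fb, st))
  W <- cam$width; H <- cam$height
  persp <- cam$mode == "perspective"
  # cull vertices behind the near plane triangle-wise (no clipping: fixture
  # meshes are fully in front of the camera)
  pv <- project(mesh$vertices, cam)
  for (tr in seq_len(nrow(mesh$triangles))) {
    vi <- mesh$triangles[tr, ]
    p <- pv[vi, , drop = FALSE]
    ax <- p[1, 1]; ay <- p[1, 2]; bx <- p[2, 1]; by <- p[2, 2]
    cx <- p[3, 1]; cy <- p[3, 2]
    area <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
    if (area == 0) next
    if (area < 0) {                       # orient consistently
      tmp <- c(bx, by); bx <- cx; by <- cy; cx <- tmp[1]; cy <- tmp[2]
      vi <- vi[c(1, 3, 2)]
      p <- p[c(1, 3, 2), , drop = FALSE]
      area <- -area
    }
    x0 <- max(0L, as.integer(floor(min(ax, bx, cx))))
    x1 <- min(W - 1L, as.integer(ceiling(max(ax, bx, cx))))
    y0 <- max(0L, as.integer(floor(min(ay, by, cy))))
    y1 <- min(H - 1L, as.integer(ceiling(max(ay, by, cy))))
    if (x0 > x1 || y0 > y1) next
    xs <- x0:x1; ys <- y0:y1
    pxc <- rep(xs + 0.5, each = length(ys))
    pyc <- rep(ys + 0.5, times = length(xs))
    e0 <- (cx - bx) * (pyc - by) - (cy - by) * (pxc - bx)  # opposite vertex a
    e1 <- (ax - cx) * (pyc - cy) - (ay - cy) * (pxc - cx)  # opposite b
    e2 <- (bx - ax) * (pyc - ay) - (by - ay) * (pxc - ax)  # opposite c
    inside <- .edge_ok(e0, bx, by, cx, cy) &
      .edge_ok(e1, cx, cy, ax, ay) &
      .edge_ok(e2, ax, ay, bx, by)
    if (!any(inside)) next
    idx <- which(inside)
    l0 <- e0[idx] / area; l1 <- e1[idx] / area; l2 <- e2[idx] / area
    d3 <- p[, 3]
    nrm3 <- mesh$vertex_normals[vi, , drop = FALSE]
    if (persp) {
      iw <- l0 / d3[1] + l1 / d3[2] + l2 / d3[3]
      depth <- 1 / iw
      w0 <- (l0 / d3[1]) * depth; w1 <- (l1 / d3[2]) * depth
      w2 <- (l2 / d3[3]) * depth
    } else {
      depth <- l0 * d3[1] + l1 * d3[2] + l2 * d3[3]
      w0 <- l0; w1 <- l1; w2 <- l2
    }
    keep <- depth >= cam$near
    if (!any(keep)) next
    idx <- idx[keep]; depth <- depth[keep]
    w0 <- w0[keep]; w1 <- w1[keep]; w2 <- w2[keep]
    nrm <- outer(w0, nrm3[1, ]) + outer(w1, nrm3[2, ]) + outer(w2, nrm3[3, ])
    nl <- sqrt(rowSums(nrm^2)); nl[nl == 0] <- 1
    nrm <- nrm / nl
    if (!persp) {
      vdir <- matrix(-cam$view, length(idx), 3, byrow = TRUE)
    } else {
      sp <- backproject(pxc[idx], pyc[idx], depth, cam)
      vdir <- -sweep(sp, 2, cam$eye)
      vdir <- vdir / sqrt(rowSums(vdir^2))
    }
    rgb <- local_shade(nrm, vdir, mesh$base_color, lighting)
    rows <- as.integer(pyc[idx] - 0.5) + 1L
    cols <- as.integer(pxc[idx] - 0.5) + 1L
    st <- .fragment_write(st, rows, cols, depth, rgb, tr)
  }
  .raster_finish(fb, st)
}

# top-left fill rule: pixels exactly on an edge belong to the triangle only
# if that edge is a top or left edge (y down, counter-clockwise orientation
# after the area sign fix: interior has non-negative edge functions).
.edge_ok <- function(e, x0, y0, x1, y1) {
  dx <- x1 - x0; dy <- y1 - y0
  top_left <- (dy < 0) || (dy == 0 && dx > 0)
  if (top_left) e >= 0 else e > 0
}

#' Depth cueing ("fog") baseline
#'
#' Blends each foreground pixel's color toward the background color by a
#' factor linear in its depth: no lighting involved, purely
#' distance-dependent. Kept as the historical baseline that SSAO replaces.
#'
#' @param fb a framebuffer.
#' @param background_color RGB triple blended toward.
#' @param near_full depth (Angstrom) at and before which colors are
#'   unchanged.
#' @param far_full depth at and beyond which colors equal the background.
#' @return the updated framebuffer (depth untouched).
#' @export
depth_cue <- function(fb, background_color = fb$background,
                      near_full, far_full) {
  if (near_full >= far_full) stop("near_full must be < far_full")
  t <- (fb$depth - near_full) / (far_full - near_full)
  t <- pmin(pmax(t, 0), 1)
  t[!is.finite(fb$depth)] <- 0
  for (ch in 1:3)
    fb$color[, , ch] <- (1 - t) * fb$color[, , ch] +
      t * background_color[ch]
  fb
}
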