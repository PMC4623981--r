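test_that("a sphere impostor has exact analytic depth at its center pixel", {
  # 65x65 image: the central pixel center projects exactly onto the axis
  cam <- camera(c(0, 0, 10), c(0, 0, -1), c(0, 1, 0), 65, 65, scale = 1)
  at <- atom_set(matrix(c(0, 0, 0), 1, 3), 2)
  fb <- rasterize_spheres(at, cam, new_framebuffer(65, 65))
  expect_equal(fb$depth[33, 33], 8)       # 10 - radius
  # depth grows monotonically from the center toward the silhouette
  row <- fb$depth[33, 33:65]
  row <- row[is.finite(row)]
  expect_true(all(diff(row) > 0))
})

test_that("overlapping spheres store the per-pixel minimum analytic depth", {
  cam <- down_camera(64, 64, scale = 0.25, dist = 10)
  at <- atom_set(rbind(c(0, 0, 0), c(1, 0, -1)), c(2, 2))
  fb <- rasterize_spheres(at, cam, new_framebuffer(64, 64))
  worst <- 0
  for (i in 1:64) for (j in 1:64) {
    lat <- backproject(i - 0.5, j - 0.5, 10, cam)   # pixel ray at depth 10
    dmin <- Inf
    for (a in 1:2) {
      oc <- lat - at$positions[a, ]
      perp <- oc - sum(oc * cam$view) * cam$view
      s2 <- sum(perp^2)
      if (s2 <= 4) {
        cd <- sum((at$positions[a, ] - cam$eye) * cam$view)
        dmin <- min(dmin, cd - sqrt(4 - s2))
      }
    }
    got <- fb$depth[j, i]
    if (is.finite(dmin) || is.finite(got))
      worst <- max(worst, abs(got - dmin))
  }
  expect_lt(worst, 1e-9)
})

test_that("perspective sphere depths agree with the analytic ray solution", {
  cam <- camera(c(0, 0, 12), c(0, 0, -1), c(0, 1, 0), 48, 48,
                mode = "perspective", fov = 45)
  at <- atom_set(rbind(c(0.5, -0.3, 0)), 1.8)
  fb <- rasterize_spheres(at, cam, new_framebuffer(48, 48))
  worst <- 0
  for (i in 1:48) for (j in 1:48) {
    d <- fb$depth[j, i]
    if (!is.finite(d)) next
    p <- backproject(i - 0.5, j - 0.5, d, cam)
    expect_r <- sqrt(sum((p - at$positions[1, ])^2))
    worst <- max(worst, abs(expect_r - 1.8))
  }
  expect_lt(worst, 1e-9)
})

test_that("rendering is independent of primitive submission order", {
  cam <- down_camera(64, 64, scale = 0.3, dist = 30)
  at <- make_sphere_cluster(n = 15, extent = 8, seed = 9)
  fb1 <- rasterize_spheres(at, cam, new_framebuffer(64, 64))
  perm <- rev(seq_len(n_atoms(at)))
  at2 <- atom_set(at$positions[perm, ], at$radii[perm],
                  at$colors[perm, ], at$elements[perm])
  fb2 <- rasterize_spheres(at2, cam, new_framebuffer(64, 64))
  expect_identical(fb1$depth, fb2$depth)
  expect_identical(fb1$color, fb2$color)
})

test_that("exactly coincident spheres resolve ties to the first-listed atom", {
  cam <- down_camera(32, 32, scale = 0.25, dist = 10)
  pos <- rbind(c(0, 0, 0), c(0, 0, 0))
  at <- atom_set(pos, c(2, 2), rbind(c(1, 0, 0), c(0, 0, 1)))
  fb <- rasterize_spheres(at, cam, new_framebuffer(32, 32))
  covered <- is.finite(fb$depth)
  expect_true(all(fb$color[, , 1][covered] > 0))  # red (atom 1) won
})

test_that("screen-parallel triangles rasterize at constant exact depth", {
  cam <- down_camera(32, 32, scale = 1, dist = 10)
  nrm <- matrix(c(0, 0, 1), 3, 3, byrow = TRUE)
  m <- triangle_mesh(rbind(c(-20, -20, 5), c(20, -20, 5), c(0, 20, 5)),
                     nrm, rbind(c(1, 2, 3)))
  fb <- rasterize_mesh(m, cam, new_framebuffer(32, 32))
  d <- fb$depth[is.finite(fb$depth)]
  expect_gt(length(d), 100)
  expect_true(all(d == 5))
})

test_that("pixels on a shared triangle edge are written exactly once", {
  cam <- down_camera(32, 32, scale = 1, dist = 10)
  nrm <- matrix(c(0, 0, 1), 4, 3, byrow = TRUE)
  v <- rbind(c(-5, -5, 5), c(5, -5, 5), c(5, 5, 5), c(-5, 5, 5))
  t1 <- triangle_mesh(v[1:3, ], nrm[1:3, ], rbind(c(1, 2, 3)))
  t2 <- triangle_mesh(v[c(1, 3, 4), ], nrm[1:3, ], rbind(c(1, 2, 3)))
  f1 <- rasterize_mesh(t1, cam, new_framebuffer(32, 32))
  f2 <- rasterize_mesh(t2, cam, new_framebuffer(32, 32))
  c1 <- is.finite(f1$depth); c2 <- is.finite(f2$depth)
  expect_equal(sum(c1 & c2), 0)           # disjoint coverage
  quad <- triangle_mesh(v, nrm, rbind(c(1, 2, 3), c(1, 3, 4)))
  fq <- rasterize_mesh(quad, cam, new_framebuffer(32, 32))
  expect_identical(is.finite(fq$depth), c1 | c2)  # union covers the quad
})

test_that("a tilted triangle's depth matches the analytic plane", {
  cam <- down_camera(32, 32, scale = 1, dist = 10)
  v <- rbind(c(-30, -30, 2), c(30, -30, 8), c(0, 30, 5))
  nrm <- matrix(c(0, 0, 1), 3, 3, byrow = TRUE)
  m <- triangle_mesh(v, nrm, rbind(c(1, 2, 3)))
  fb <- rasterize_mesh(m, cam, new_framebuffer(32, 32))
  e1 <- v[2, ] - v[1, ]; e2 <- v[3, ] - v[1, ]
  nn <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  worst <- 0
  for (i in 1:32) for (j in 1:32) {
    if (!is.finite(fb$depth[j, i])) next
    p <- backproject(i - 0.5, j - 0.5, 10, cam)
    z <- v[1, 3] - (nn[1] * (p[1] - v[1, 1]) + nn[2] * (p[2] - v[1, 2])) / nn[3]
    worst <- max(worst, abs(fb$depth[j, i] - (10 - z)))
  }
  expect_lt(worst, 1e-5)
})

test_that("Phong shading follows the ambient/diffuse/specular contract", {
  lt <- lighting_params(light = c(0, 0, 1), ambient = 0.2, diffuse = 0.6,
                        specular = 0.25, shininess = 8)
  n <- rbind(c(0, 0, 1))
  v <- rbind(c(0, 0, 1))
  # normal facing the light, view at mirror direction: full diffuse + spec
  col <- local_shade(n, v, c(0.5, 0.5, 0.5), lt)
  expect_equal(as.numeric(col), rep(0.5 * 0.8 + 0.25, 3))
  # normal perpendicular to the light: ambient only
  col2 <- local_shade(rbind(c(1, 0, 0)), rbind(c(1, 0, 0)),
                      c(0.5, 0.5, 0.5), lt)
  expect_equal(as.numeric(col2), rep(0.1, 3))
})

test_that("depth cueing blends linearly toward the background", {
  fb <- new_framebuffer(2, 2, c(1, 1, 1))
  fb$depth <- matrix(c(10, 20, 30, Inf), 2, 2)
  fb$color[, , 1] <- 0.8; fb$color[, , 2] <- 0.4; fb$color[, , 3] <- 0
  out <- depth_cue(fb, c(1, 1, 1), near_full = 10, far_full = 30)
  expect_equal(out$color[1, 1, ], c(0.8, 0.4, 0))        # at near: unchanged
  expect_equal(out$color[1, 2, ], c(1, 1, 1))            # at far: background
  expect_equal(out$color[2, 1, ], c(0.9, 0.7, 0.5))      # midway: 50/50
  expect_equal(out$color[2, 2, ], c(0.8, 0.4, 0))        # background untouched
  expect_identical(out$depth, fb$depth)
  expect_error(depth_cue(fb, c(1, 1, 1), 30, 10), "near_full")
})
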