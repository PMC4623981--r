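test_that("point kernels are uniform in the unit ball and seed-deterministic", {
  p <- ao_params(mode = "point", n_samples = 2000, seed = 3)
  k <- build_kernel(p)
  nrm <- sqrt(rowSums(k$offsets^2))
  expect_true(all(nrm <= 1))
  # E|r| = 3/4 for the uniform ball
  expect_lt(abs(mean(nrm) - 0.75) / 0.75, 0.05)
  # front/back stratification: exactly half the offsets in each depth half
  expect_equal(sum(k$offsets[, 3] > 0), 1000)
  k2 <- build_kernel(ao_params(mode = "point", n_samples = 2000, seed = 3))
  expect_identical(k, k2)
  k3 <- build_kernel(ao_params(mode = "point", n_samples = 2000, seed = 4))
  expect_false(identical(k, k3))
})

test_that("a single sampling line is the unit-weight center chord", {
  k <- build_kernel(ao_params(mode = "line", n_samples = 1))
  expect_equal(as.numeric(k$offsets), c(0, 0))
  expect_equal(k$h, 1)
  expect_equal(k$weights, 1)
  k8 <- build_kernel(ao_params(mode = "line", n_samples = 8))
  expect_true(all(sqrt(rowSums(k8$offsets^2)) < 1))
  expect_equal(sum(k8$weights), 1)
})

test_that("diameter converts to pixel radius by camera model", {
  cam <- down_camera(64, 64, scale = 0.5)
  p <- ao_params(mode = "line", diameter = 8)
  expect_equal(diameter_to_pixels(p, cam, 10), 8)
  px <- ao_params(mode = "line", diameter = 12, diameter_unit = "pixel")
  expect_equal(diameter_to_pixels(px, cam, 10), 6)
  expect_equal(diameter_to_pixels(px, cam, 33), 6)
  pc <- camera(c(0, 0, 0), c(0, 0, -1), c(0, 1, 0), 64, 64,
               mode = "perspective", fov = 40)
  r1 <- diameter_to_pixels(p, pc, 10)
  r2 <- diameter_to_pixels(p, pc, 20)
  expect_equal(r1, 2 * r2)
})

test_that("a screen-parallel plane yields zero occlusion in both modes", {
  flat <- reference_scene("flat")
  cam <- flat$camera(96, 96)
  fb <- render_analytic_depth(flat$scene, cam)
  A_pt <- ao_point(fb, cam, ao_params(mode = "point", diameter = 8,
                                      n_samples = 64, seed = 2,
                                      blur_width = 1L))
  expect_equal(max(A_pt), 0)              # exact: stratified kernel balance
  A_ln <- ao_line(fb, cam, ao_params(mode = "line", diameter = 8,
                                     n_samples = 32))
  expect_equal(max(A_ln), 0)              # exact: signed-excess form
})

test_that("an all-background buffer yields a zero occlusion map", {
  cam <- down_camera(16, 16)
  fb <- new_framebuffer(16, 16)
  for (mode in c("point", "line")) {
    A <- apply_ssao(fb, cam, ao_params(mode = mode), return_ao = TRUE)$ao
    expect_true(all(A == 0))
  }
})

test_that("concave steps darken and convex edges lighten, for every seed", {
  ref <- reference_scene("corner", size = 4)
  cam <- ref$camera(96, 96)
  fb <- render_analytic_depth(ref$scene, cam)
  # pixels on the floor at the step base vs far out on the flat floor;
  # and on the slab top at its convex edge vs mid-slab
  col_at <- function(x_world) floor(x_world / cam$scale + 48) + 1L
  for (seed in 1:3) {
    p <- ao_params(mode = "point", diameter = 8, n_samples = 64,
                   seed = seed, blur_width = 1L)
    A <- ao_point(fb, cam, p)
    inner <- mean(A[, col_at(-1)])        # floor at the wall base
    flat_far <- mean(A[, col_at(-9)])     # open floor
    convex <- mean(A[, col_at(0.5)])      # slab top at the convex edge
    slab_mid <- mean(A[, col_at(9)])      # open slab top
    expect_gt(inner, flat_far)
    expect_lte(convex, slab_mid + 1e-12)
  }
})

test_that("line sampling has finer granularity than point sampling on a step", {
  cam <- down_camera(128, 128)
  fb <- render_analytic_depth(step_scene(2), cam)
  pp <- ao_params(mode = "point", diameter = 8, n_samples = 8,
                  blur_width = 1L)
  lp <- ao_params(mode = "line", diameter = 8, n_samples = 8)
  raw_pt <- ao_point(fb, cam, pp, raw = TRUE)
  raw_ln <- ao_line(fb, cam, lp, raw = TRUE)
  # point-mode ratios are quantized to the grid {0, 1/8, ..., 1}
  expect_true(all(abs(raw_pt * 8 - round(raw_pt * 8)) < 1e-12))
  # line-mode fractions are not confined to that grid
  expect_gt(sum(abs(raw_ln * 8 - round(raw_ln * 8)) > 1e-9), 0)
  expect_gt(n_distinct_vals(raw_ln), n_distinct_vals(raw_pt))
})

test_that("separable blur equals direct 2D box convolution", {
  set.seed(5)
  A <- matrix(stats::runif(40 * 30), 30, 40)
  out <- blur_separable(A, 7)
  # brute-force 2D convolution on interior pixels
  worst <- 0
  for (i in 4:27) for (j in 4:37)
    worst <- max(worst, abs(out[i, j] - mean(A[(i - 3):(i + 3),
                                               (j - 3):(j + 3)])))
  expect_lt(worst, 1e-12)
  # impulse response: 1/49 over the 7x7 neighborhood
  imp <- matrix(0, 21, 21); imp[11, 11] <- 1
  r <- blur_separable(imp, 7)
  expect_equal(r[8:14, 8:14], matrix(1 / 49, 7, 7))
  expect_equal(sum(r), 1)
  r[8:14, 8:14] <- 0
  expect_true(all(r == 0))
  # constant maps are fixed points; even widths are rejected
  cst <- matrix(0.3, 9, 9)
  expect_equal(blur_separable(cst, 7), cst)
  expect_error(blur_separable(cst, 4), "odd")
})

test_that("modulation darkens linearly and leaves background untouched", {
  fb <- new_framebuffer(2, 2, c(1, 1, 1))
  fb$depth <- matrix(c(10, 10, 10, Inf), 2, 2)
  fb$color[, , 1] <- 0.8
  ao <- matrix(c(0.5, 1, 0, 0.9), 2, 2)
  out <- modulate(fb, ao, 1)
  expect_equal(out$color[1, 1, 1], 0.4)
  expect_equal(out$color[2, 1, ], c(0, 0, 0))
  expect_equal(out$color[2, 2, 1], 0.8)   # background pixel unchanged
  out0 <- modulate(fb, ao, 0)
  expect_identical(out0$color, fb$color)
})

test_that("the full post-process is a pure, deterministic transform", {
  at <- make_channel_atoms(seed = 2)
  cam <- camera(c(0, 0, 40), c(0, 0, -1), c(0, 1, 0), 64, 64, scale = 0.3)
  fb <- rasterize_spheres(at, cam, new_framebuffer(64, 64))
  p <- ao_params(mode = "point", diameter = 8, seed = 11)
  r1 <- apply_ssao(fb, cam, p)
  r2 <- apply_ssao(fb, cam, p)
  expect_identical(r1, r2)
  r0 <- apply_ssao(fb, cam, ao_params(mode = "line", intensity = 0))
  expect_identical(r0$color, fb$color)
})

test_that("occlusion depends only on the buffers, not scene complexity", {
  cam <- down_camera(64, 64, scale = 0.3, dist = 30)
  base <- make_sphere_cluster(n = 10, extent = 6, seed = 7)
  # the same 10 spheres duplicated 100x over: identical depth buffer
  reps <- rep(seq_len(10), 99)
  big <- atom_set(rbind(base$positions, base$positions[reps, ]),
                  c(base$radii, base$radii[reps]))
  small_at <- atom_set(base$positions, base$radii)
  fb_small <- rasterize_spheres(small_at, cam, new_framebuffer(64, 64))
  fb_big <- rasterize_spheres(big, cam, new_framebuffer(64, 64))
  expect_identical(fb_small$depth, fb_big$depth)
  p <- ao_params(mode = "line", diameter = 6)
  expect_identical(ao_line(fb_small, cam, p), ao_line(fb_big, cam, p))
})

test_that("occlusion maps are in range and NaN-free on fixture scenes", {
  scenes <- list(
    render_analytic_depth(reference_scene("pit")$scene, down_camera(48, 48)),
    render_analytic_depth(step_scene(4), down_camera(48, 48)),
    rasterize_spheres(make_channel_atoms(seed = 1),
                      camera(c(0, 0, 40), c(0, 0, -1), c(0, 1, 0), 48, 48,
                             scale = 0.4),
                      new_framebuffer(48, 48)))
  for (fb in scenes) for (mode in c("point", "line")) {
    prm <- ao_params(mode = mode, diameter = 8, n_samples = 16, seed = 1)
    A <- apply_ssao(fb, down_camera(48, 48), prm, return_ao = TRUE)$ao
    expect_false(any(is.na(A)))
    expect_true(all(A >= 0 & A <= 1))
    expect_true(all(A[!is.finite(fb$depth)] == 0))
  }
})

test_that("randomization breaks banding; blur suppresses the added noise", {
  cam <- down_camera(128, 128)
  fb <- render_analytic_depth(tilted_plane_scene(40), cam)
  i <- 20:108                              # interior, away from borders
  p_nr <- ao_params(mode = "point", diameter = 8, n_samples = 16,
                    blur_width = 1L, randomize = FALSE)
  p_r <- ao_params(mode = "point", diameter = 8, n_samples = 16,
                   blur_width = 1L, randomize = TRUE)
  raw_nr <- ao_point(fb, cam, p_nr, raw = TRUE)[i, i]
  raw_r <- ao_point(fb, cam, p_r, raw = TRUE)[i, i]
  d_nr <- n_distinct_vals(raw_nr)
  d_r <- n_distinct_vals(raw_r)
  expect_lte(d_nr, 17)                     # n + 1 quantization levels
  expect_gte(d_r, 4 * d_nr)
  A_r <- ao_point(fb, cam, p_r)
  tv_ratio <- total_variation(A_r[i, i]) /
    total_variation(blur_separable(A_r, 7)[i, i])
  expect_gte(tv_ratio, 2)
})

test_that("pit-bottom occlusion is non-decreasing in pit depth to saturation", {
  cam <- down_camera(128, 128)
  vals <- sapply(c(1, 2, 3, 5, 8), function(dep) {
    fb <- render_analytic_depth(cylinder_pit_scene(radius = 3, depth = dep),
                                cam)
    ao_line(fb, cam, ao_params(mode = "line", diameter = 12,
                               n_samples = 32))[64, 64]
  })
  expect_true(all(diff(vals) > -1e-9))
  expect_gt(vals[5], vals[1])
})

test_that("pixel-unit diameters produce a fixed screen footprint", {
  # same scene at two orthographic zoom levels: angstrom-diameter AO
  # changes with zoom, pixel-diameter AO does not
  scn <- cylinder_pit_scene(radius = 3, depth = 3)
  A <- list()
  for (scale in c(0.25, 0.5)) {
    cam <- down_camera(64, 64, scale = scale)
    fb <- render_analytic_depth(scn, cam)
    ppx <- ao_params(mode = "line", diameter = 24, diameter_unit = "pixel",
                     n_samples = 16)
    A[[as.character(scale)]] <- ao_line(fb, cam, ppx)[32, 32]
  }
  # the pit shrinks in pixels at coarser scale, so the fixed pixel-radius
  # sphere sees relatively more of the surrounding plane: occlusion rises
  expect_gt(A[["0.5"]], A[["0.25"]])
})
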