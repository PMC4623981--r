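test_that("channel rings place atoms at the ring radius, deterministically", {
  at <- make_channel_atoms(ring_radius = 6, atom_radius = 1.7, n_rings = 1,
                           atoms_per_ring = 8, seed = 1, jitter = 0)
  expect_equal(n_atoms(at), 8)
  expect_equal(sqrt(rowSums(at$positions[, 1:2]^2)), rep(6, 8))
  f1 <- tempfile(fileext = ".pdb"); f2 <- tempfile(fileext = ".pdb")
  write_pdb_atoms(make_channel_atoms(seed = 5), f1)
  write_pdb_atoms(make_channel_atoms(seed = 5), f2)
  expect_identical(readLines(f1), readLines(f2))
  f3 <- tempfile(fileext = ".pdb")
  write_pdb_atoms(make_channel_atoms(seed = 6), f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("the channel pore darkens more than the outer surface", {
  at <- make_channel_atoms(ring_radius = 4, atoms_per_ring = 12,
                           n_rings = 8, seed = 1)
  th <- 20 * pi / 180                      # slightly tilted, as rendered
  cam <- camera(c(0, -40 * sin(th), 40 * cos(th)),
                c(0, sin(th), -cos(th)), c(0, 1, 0), 128, 128,
                scale = 0.15)
  fb <- rasterize_spheres(at, cam, new_framebuffer(128, 128))
  idx <- which(is.finite(fb$depth))
  rows <- ((idx - 1) %% 128) + 1; cols <- ((idx - 1) %/% 128) + 1
  P <- backproject(cols - 0.5, rows - 0.5, fb$depth[idx], cam)
  rad <- sqrt(P[, 1]^2 + P[, 2]^2)         # distance from the pore axis
  pore <- rad < 4; outer <- rad > 4.8
  for (mode in c("point", "line")) {
    prm <- ao_params(mode = mode, diameter = 8,
                     n_samples = if (mode == "point") 64 else 32,
                     blur_width = 1L)
    A <- if (mode == "point") ao_point(fb, cam, prm)
         else ao_line(fb, cam, prm)
    expect_gt(mean(A[idx][pore]), mean(A[idx][outer]))
  }
})

test_that("pseudo-EM maps have the analytic Gaussian mass and peak", {
  at <- atom_set(rbind(c(0, 0, 0), c(6, 0, 0)), c(1.7, 1.7))
  map <- make_gaussian_map(at, resolution = 5, voxel_size = 1)
  sigma <- 5 / (pi * sqrt(2))
  mass <- sum(map$grid) * prod(map$voxel_size)
  expect_lt(abs(mass / (2 * (2 * pi * sigma^2)^1.5) - 1), 0.01)
  # single atom: maximum at the atom's voxel, radially monotone profile
  m1 <- make_gaussian_map(atom_set(matrix(0, 1, 3), 1.7), 5, 1)
  peak <- which(m1$grid == max(m1$grid), arr.ind = TRUE)[1, ]
  ppos <- m1$origin + (peak - 1) * m1$voxel_size
  expect_true(all(abs(ppos) <= m1$voxel_size / 2 + 1e-9))
  prof <- m1$grid[peak[1]:dim(m1$grid)[1], peak[2], peak[3]]
  expect_true(all(diff(prof) < 0))
  expect_error(make_gaussian_map(at, resolution = 1, voxel_size = 1),
               "Nyquist")
})

test_that("helix maps merge into one tube at low resolution and resolve detail at high", {
  hx <- make_helix_atoms()
  m8 <- make_gaussian_map(hx, resolution = 8, voxel_size = 1)
  m3 <- make_gaussian_map(hx, resolution = 3, voxel_size = 1)
  iso8 <- max(m8$grid) / 2
  s8 <- extract_isosurface(m8, iso8)
  expect_equal(mesh_components(s8), 1)     # one connected tube
  # at its own half-max contour the sharp map resolves individual atoms
  s3_half <- extract_isosurface(m3, max(m3$grid) / 2)
  expect_gte(mesh_components(s3_half), 10)
  # contoured at equal enclosed volume (the standard way to compare maps
  # of one object at two resolutions) the sharp map exposes more surface
  vol8 <- sum(m8$grid > iso8)
  iso3 <- stats::quantile(as.vector(m3$grid), 1 - vol8 / length(m3$grid))
  s3 <- extract_isosurface(m3, iso3)
  expect_gt(mesh_area(s3) / mesh_area(s8), 1.6)
})

test_that("the two-scale scene has disjoint masks and scale-dependent oracle AO", {
  ts <- make_two_scale_scene()
  cam <- ts$camera(128, 128)
  reg <- ts$regions(cam)
  expect_gt(sum(reg$pit), 0)
  expect_gt(sum(reg$floor), 0)
  expect_gt(sum(reg$rim), 0)
  expect_false(any(reg$pit & reg$floor))
  expect_false(any(reg$pit & reg$rim))
  expect_false(any(reg$floor & reg$rim))
  up <- c(0, 0, 1)
  # a point on a pit bottom 1 Angstrom from its wall (at the exact center
  # of a 2 Angstrom-wide pit no wall lies within a 2 Angstrom range)
  pitc <- c(ts$pit_centers[1, 1] + 1, ts$pit_centers[1, 2], -8 - 2)
  midc <- c(5, 5, -8)                      # basin floor away from pits
  # short-range occlusion: the narrow pit dominates
  a_pit <- brute_force_ao(ts$scene, pitc, up, 20000, seed = 1,
                          max_range = 2)
  a_mid <- brute_force_ao(ts$scene, midc, up, 20000, seed = 1,
                          max_range = 2)
  expect_gt(a_pit, a_mid)
  # long-range occlusion: the basin itself occludes the mid-floor point
  a_mid_far <- brute_force_ao(ts$scene, midc, up, 20000, seed = 1,
                              max_range = 20)
  expect_gt(a_mid_far, a_mid)
})

test_that("fixture generation is pure: identical specs give identical bytes", {
  f1 <- tempfile(fileext = ".mrc"); f2 <- tempfile(fileext = ".mrc")
  make_fixture("helix_map", f1, resolution = 6)
  make_fixture("helix_map", f2, resolution = 6)
  expect_identical(readBin(f1, "raw", file.info(f1)$size),
                   readBin(f2, "raw", file.info(f2)$size))
})
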