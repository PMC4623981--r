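#' Synthetic channel-protein stand-in: stacked atom rings
#'
#' A deterministic open cylindrical pore built from stacked rings of
#' atoms, emulating the geometry of a membrane channel viewed down its
#' axis: the pore interior is a deep cavity that ambient occlusion should
#' darken relative to the outer surface. Ring positions are jittered
#' reproducibly from the seed so the surface is not perfectly crystalline.
#'
#' @param ring_radius radius of each ring (Angstrom).
#' @param atom_radius sphere radius of every atom.
#' @param n_rings number of stacked rings along the pore (z) axis.
#' @param atoms_per_ring atoms per ring.
#' @param seed jitter seed.
#' @param jitter uniform jitter amplitude (Angstrom).
#' @return an [atom_set()].
#' @export
make_channel_atoms <- function(ring_radius = 6, atom_radius = 1.7,
                               n_rings = 6, atoms_per_ring = 16,
                               seed = 1L, jitter = 0.3) {
  stopifnot(ring_radius > 0, atom_radius > 0.2, n_rings >= 1,
            atoms_per_ring >= 3)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  spacing <- 1.6 * atom_radius
  pos <- NULL
  for (k in seq_len(n_rings)) {
    ang <- 2 * pi * (seq_len(atoms_per_ring) - 1) / atoms_per_ring +
      (k %% 2) * pi / atoms_per_ring       # stagger alternate rings
    ring <- cbind(ring_radius * cos(ang), ring_radius * sin(ang),
                  (k - (n_rings + 1) / 2) * spacing)
    pos <- rbind(pos, ring)
  }
  if (jitter > 0)
    pos <- pos + matrix(stats::runif(length(pos), -jitter, jitter),
                        nrow(pos), 3)
  atom_set(pos, rep(atom_radius, nrow(pos)),
           element_color(rep("C", nrow(pos))), rep("C", nrow(pos)))
}

#' Random cluster of van der Waals spheres
#'
#' @param n number of atoms.
#' @param extent half-width of the cubic region the centers fill.
#' @param seed RNG seed.
#' @param elements element symbols sampled for radii/colors.
#' @return an [atom_set()].
#' @export
make_sphere_cluster <- function(n = 50, extent = 12, seed = 1L,
                                elements = c("C", "N", "O", "S")) {
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  pos <- matrix(stats::runif(3 * n, -extent, extent), n, 3)
  el <- sample(elements, n, replace = TRUE)
  atom_set(pos, element_radius(el), element_color(el), el)
}

#' Idealized alpha-helix backbone atoms
#'
#' Canonical helix geometry (2.3 Angstrom radius, 1.5 Angstrom rise and
#' 100 degrees turn per residue), one carbon sphere per residue. At low
#' simulated resolution the helix blurs into a single tube; at high
#' resolution the individual turns resolve.
#'
#' @param n_res number of residues.
#' @param radius helix radius (Angstrom).
#' @param rise rise per residue (Angstrom).
#' @param twist turn per residue (degrees).
#' @return an [atom_set()].
#' @export
make_helix_atoms <- function(n_res = 18, radius = 2.3, rise = 1.5,
                             twist = 100) {
  i <- seq_len(n_res) - 1
  ang <- i * twist * pi / 180
  pos <- cbind(radius * cos(ang), radius * sin(ang),
               (i - (n_res - 1) / 2) * rise)
  atom_set(pos, rep(1.7, n_res), element_color(rep("C", n_res)),
           rep("C", n_res))
}

#' Pseudo-EM density map from an atom set
#'
#' Sum of unit-amplitude spherical Gaussians at the atom centers with
#' `sigma = resolution / (pi * sqrt(2))`, sampled on a cubic grid padded
#' by 3 sigma around the atoms. Emulates an EM reconstruction of the model
#' at the requested resolution; purely deterministic.
#'
#' @param atoms an [atom_set()].
#' @param resolution simulated resolution (Angstrom); must be at least
#'   twice the voxel size (Nyquist).
#' @param voxel_size grid spacing (Angstrom).
#' @return a [density_map()].
#' @export
make_gaussian_map <- function(atoms, resolution = 5, voxel_size = 1) {
  stopifnot(n_atoms(atoms) >= 1)
  if (resolution < 2 * voxel_size)
    stop("resolution must be >= 2 * voxel_size (Nyquist)")
  sigma <- resolution / (pi * sqrt(2))
  pad <- 3 * sigma
  lo <- apply(atoms$positions, 2, min) - pad
  hi <- apply(atoms$positions, 2, max) + pad
  n <- pmax(2L, as.integer(ceiling((hi - lo) / voxel_size)) + 1L)
  ax <- lapply(1:3, function(k) lo[k] + (seq_len(n[k]) - 1) * voxel_size)
  g <- array(0, dim = n)
  cutoff <- 5 * sigma
  for (a in seq_len(n_atoms(atoms))) {
    ctr <- atoms$positions[a, ]
    ix <- which(abs(ax[[1]] - ctr[1]) <= cutoff)
    iy <- which(abs(ax[[2]] - ctr[2]) <= cutoff)
    iz <- which(abs(ax[[3]] - ctr[3]) <= cutoff)
    if (!length(ix) || !length(iy) || !length(iz)) next
    gx <- exp(-(ax[[1]][ix] - ctr[1])^2 / (2 * sigma^2))
    gy <- exp(-(ax[[2]][iy] - ctr[2])^2 / (2 * sigma^2))
    gz <- exp(-(ax[[3]][iz] - ctr[3])^2 / (2 * sigma^2))
    g[ix, iy, iz] <- g[ix, iy, iz] + outer(gx, outer(gy, gz))
  }
  density_map(g, origin = lo, voxel_size = rep(voxel_size, 3))
}

#' Two-scale cavity test scene
#'
#' The multi-scale benchmark: a plane carrying a broad circular basin
#' (default 40 Angstrom wide, 8 deep) whose floor carries a 3 x 3 grid of
#' narrow pits (default 4 Angstrom wide, 2 deep). A small sampling-sphere
#' diameter should darken the pits but barely notice the basin; a large
#' diameter should darken the whole basin and wash out the pits.
#'
#' @param basin_width,basin_depth basin diameter and depth (Angstrom).
#' @param pit_width,pit_depth pit diameter and depth (Angstrom).
#' @param pit_spacing center-to-center pit spacing (Angstrom).
#' @param plane_depth distance of the top plane from the default camera.
#' @return a list with `scene` (an [analytic_scene()]), `camera(width,
#'   height)` (orthographic, looking straight down, sized so the basin
#'   fills most of the frame), and `regions(cam)` returning logical
#'   pixel masks `pit`, `floor` (basin floor away from pits) and `rim`
#'   (the surrounding plane), mutually disjoint.
#' @export
make_two_scale_scene <- function(basin_width = 40, basin_depth = 8,
                                 pit_width = 4, pit_depth = 2,
                                 pit_spacing = 10, plane_depth = 60) {
  up <- c(0, 0, 1)
  basin_r <- basin_width / 2
  pit_r <- pit_width / 2
  centers <- expand.grid(x = (-1:1) * pit_spacing,
                         y = (-1:1) * pit_spacing)
  prims <- list(
    prim_plane(c(0, 0, 0), up, hole_center = c(0, 0, 0),
               hole_radius = basin_r),
    prim_cylinder(c(0, 0, -basin_depth), up, basin_r, 0, basin_depth))
  floor_z <- -basin_depth
  # basin floor: disk with the nine pit mouths cut out; a disk primitive
  # has no holes, so build it from an annulus-free plane bounded to the
  # basin and cylinders+disks per pit
  for (i in seq_len(nrow(centers))) {
    cx <- centers$x[i]; cy <- centers$y[i]
    prims <- c(prims, list(
      prim_cylinder(c(cx, cy, floor_z - pit_depth), up, pit_r, 0,
                    pit_depth),
      prim_disk(c(cx, cy, floor_z - pit_depth), up, pit_r)))
  }
  prims <- c(prims, list(.basin_floor_prim(basin_r, floor_z, centers,
                                           pit_r)))
  scene <- analytic_scene(prims)
  eye <- c(0, 0, plane_depth)
  cam_factory <- function(width = 256, height = 256) {
    scale <- 1.4 * basin_width / min(width, height)
    camera(eye, c(0, 0, -1), c(0, 1, 0), width, height,
           mode = "orthographic", scale = scale)
  }
  regions <- function(cam) {
    W <- cam$width; H <- cam$height
    px <- rep(seq_len(W) - 0.5, each = H)
    py <- rep(seq_len(H) - 0.5, times = W)
    # world xy of each pixel under the downward orthographic camera
    wx <- (px - W / 2) * cam$scale * cam$right[1] +
      (py - H / 2) * cam$scale * cam$down[1] + cam$eye[1]
    wy <- (px - W / 2) * cam$scale * cam$right[2] +
      (py - H / 2) * cam$scale * cam$down[2] + cam$eye[2]
    rad <- sqrt(wx^2 + wy^2)
    dpit <- rep(Inf, length(wx))
    for (i in seq_len(nrow(centers)))
      dpit <- pmin(dpit, sqrt((wx - centers$x[i])^2 +
                                (wy - centers$y[i])^2))
    m <- function(v) matrix(v, H, W)
    list(pit = m(dpit < 0.8 * pit_r),
         floor = m(rad < 0.85 * basin_r & dpit > 1.8 * pit_r),
         rim = m(rad > 1.15 * basin_r))
  }
  list(scene = scene, camera = cam_factory, regions = regions,
       basin_radius = basin_r, pit_radius = pit_r,
       pit_centers = as.matrix(centers))
}

# basin floor plane bounded to the basin disk with pit mouths removed:
# approximate the multi-hole disk as a plane restricted by a custom test
.basin_floor_prim <- function(basin_r, floor_z, centers, pit_r) {
  p <- prim_plane(c(0, 0, floor_z), c(0, 0, 1))
  p$multi_hole <- list(basin_r = basin_r, centers = as.matrix(centers),
                       pit_r = pit_r)
  p
}

#' Generate a fixture by kind
#'
#' One entry point for all deterministic synthetic inputs: writes standard
#' PDB (atom kinds) or MRC2014 (map kinds) files, or a color+depth buffer
#' pair for the analytic two-scale cavity field. Identical arguments give
#' byte-identical output files.
#'
#' @param kind one of `"channel_ring"`, `"sphere_cluster"`,
#'   `"gaussian_blob_map"`, `"helix_map"`, `"two_scale_cavity_field"`.
#' @param out output path (for the buffer pair, the depth grid is written
#'   next to it with extension `.depth`).
#' @param seed RNG seed for the jittered kinds.
#' @param resolution map resolution (map kinds, Angstrom).
#' @param voxel_size map grid spacing (map kinds, Angstrom).
#' @return the primary output path, invisibly.
#' @export
make_fixture <- function(kind = c("channel_ring", "sphere_cluster",
                                  "gaussian_blob_map", "helix_map",
                                  "two_scale_cavity_field"),
                         out, seed = 1L, resolution = 5, voxel_size = 1) {
  kind <- match.arg(kind)
  if (kind == "channel_ring") {
    write_pdb_atoms(make_channel_atoms(seed = seed), out)
  } else if (kind == "sphere_cluster") {
    write_pdb_atoms(make_sphere_cluster(seed = seed), out)
  } else if (kind == "gaussian_blob_map") {
    atoms <- atom_set(matrix(0, 1, 3), 1.7)
    write_mrc(make_gaussian_map(atoms, resolution, voxel_size), out)
  } else if (kind == "helix_map") {
    write_mrc(make_gaussian_map(make_helix_atoms(), resolution,
                                voxel_size), out)
  } else {
    ts <- make_two_scale_scene()
    fb <- render_analytic_depth(ts$scene, ts$camera())
    write_framebuffer(fb, out, paste0(out, ".depth"))
  }
  invisible(out)
}
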