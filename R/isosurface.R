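#' Construct a triangle mesh
#'
#' @param vertices M x 3 matrix (Angstrom).
#' @param vertex_normals M x 3 matrix of unit normals.
#' @param triangles T x 3 integer matrix of 1-based vertex indices.
#' @param base_color RGB triple.
#' @return an object of class `"triangle_mesh"`.
#' @export
triangle_mesh <- function(vertices, vertex_normals, triangles,
                          base_color = c(0.6, 0.7, 0.8)) {
  vertices <- .as_mat3(vertices)
  vertex_normals <- .as_mat3(vertex_normals)
  triangles <- matrix(as.integer(triangles), ncol = 3)
  if (nrow(triangles) > 0)
    stopifnot(min(triangles) >= 1, max(triangles) <= nrow(vertices))
  structure(list(vertices = vertices, vertex_normals = vertex_normals,
                 triangles = triangles,
                 base_color = as.numeric(base_color)),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh> %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$triangles)))
  invisible(x)
}

#' Total surface area of a mesh
#' @param mesh a [triangle_mesh()].
#' @return area in square Angstrom.
#' @export
mesh_area <- function(mesh) {
  if (nrow(mesh$triangles) == 0) return(0)
  a <- mesh$vertices[mesh$triangles[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$triangles[, 2], , drop = FALSE]
  c_ <- mesh$vertices[mesh$triangles[, 3], , drop = FALSE]
  u <- b - a; v <- c_ - a
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

# 6-tetrahedron decomposition of the unit cube around the 0-7 diagonal.
# Cube corners are numbered by bits (x, y, z) -> 1*x + 2*y + 4*z. Every
# tetrahedron contains the main diagonal (0, 7); the middle pairs walk a
# closed path over face-adjacent corners, which makes the decomposition
# consistent across neighboring cubes (shared faces are split along the
# same diagonal), so the extracted surface is watertight.
.tet_path <- c(1L, 3L, 2L, 6L, 4L, 5L)
.cube_tets <- t(vapply(seq_len(6), function(i) {
  c(0L, .tet_path[i], .tet_path[if (i == 6) 1 else i + 1], 7L)
}, integer(4)))

#' Extract an isosurface mesh from a density map
#'
#' Marching tetrahedra: each grid cube is split into six tetrahedra sharing
#' the main diagonal, and the iso-level crossing inside each tetrahedron is
#' triangulated with vertices placed by linear interpolation along
#' tetrahedron edges. The decomposition is face-consistent between
#' neighboring cubes, so the resulting mesh is closed wherever the iso
#' surface does not meet the grid boundary. Vertex normals are the negated,
#' normalized central-difference density gradient, so they point toward
#' lower density (outward for a blob). Duplicate vertices on shared edges
#' are merged; zero-area triangles are dropped.
#'
#' @param map a [density_map()].
#' @param iso_level iso value; must lie strictly between the grid minimum
#'   and maximum for a non-empty result.
#' @param base_color mesh color.
#' @return a [triangle_mesh()] in Angstrom coordinates
#'   (`grid index * voxel_size + origin`). An out-of-range `iso_level`
#'   yields an empty mesh with a warning.
#' @export
extract_isosurface <- function(map, iso_level,
                               base_color = c(0.6, 0.7, 0.8)) {
  g <- map$grid
  d <- dim(g)
  empty <- triangle_mesh(matrix(numeric(0), 0, 3),
                         matrix(numeric(0), 0, 3),
                         matrix(integer(0), 0, 3), base_color)
  if (iso_level <= min(g) || iso_level >= max(g)) {
    warning("iso_level outside the grid value range; empty mesh")
    return(empty)
  }
  if (any(d < 2)) return(empty)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  # linear index of corner (1,1,1) of every cube
  ci <- as.vector(outer(outer(seq_len(nx - 1), (seq_len(ny - 1) - 1) * nx,
                              "+"), (seq_len(nz - 1) - 1) * nx * ny, "+"))
  corner_off <- c(0L, 1L, nx, nx + 1L, nx * ny, nx * ny + 1L,
                  nx * ny + nx, nx * ny + nx + 1L)  # bit order x,y,z
  above <- g > iso_level
  # accumulate triangles as parallel m x 3 matrices of grid-edge endpoint
  # indices (min, max), so identical grid edges share one mesh vertex
  kaL <- list(); kbL <- list()
  for (tet in seq_len(nrow(.cube_tets))) {
    corners <- .cube_tets[tet, ]
    off <- corner_off[corners + 1L]
    idx <- lapply(off, function(o) ci + o)
    ab <- vapply(idx, function(i) above[i], logical(length(ci)))
    case <- ab[, 1] + 2L * ab[, 2] + 4L * ab[, 3] + 8L * ab[, 4]
    for (cs in 1:14) {
      sel <- which(case == cs)
      if (length(sel) == 0) next
      inside <- which(bitwAnd(cs, c(1L, 2L, 4L, 8L)) > 0)
      for (tri in .tet_case_tris(inside)) {
        # tri: 3 edges, each edge = c(corner_in, corner_out)
        amat <- bmat <- matrix(0, length(sel), 3)
        for (e in 1:3) {
          aO <- idx[[tri[[e]][1]]][sel]
          bO <- idx[[tri[[e]][2]]][sel]
          amat[, e] <- pmin(aO, bO)
          bmat[, e] <- pmax(aO, bO)
        }
        kaL[[length(kaL) + 1L]] <- amat
        kbL[[length(kbL) + 1L]] <- bmat
      }
    }
  }
  if (length(kaL) == 0) return(empty)
  kaM <- do.call(rbind, kaL)
  kbM <- do.call(rbind, kbL)
  keyM <- kaM * (as.numeric(nx) * ny * nz + 1) + kbM
  uk <- unique(as.vector(keyM))
  tri_mat <- matrix(match(keyM, uk), ncol = 3)
  # interpolate unique vertices
  first <- match(uk, as.vector(keyM))
  aI <- as.vector(kaM)[first]; bI <- as.vector(kbM)[first]
  va <- g[aI]; vb <- g[bI]
  t <- (iso_level - va) / (vb - va)
  pa <- .lin_to_ijk(aI, d); pb <- .lin_to_ijk(bI, d)
  pos_grid <- pa + t * (pb - pa)            # 0-based grid coordinates
  verts <- sweep(sweep(pos_grid, 2, map$voxel_size, "*"), 2, map$origin, "+")
  normals <- .gradient_normals(g, pos_grid, map$voxel_size)
  # drop degenerate triangles (repeated vertices / zero area)
  m <- triangle_mesh(verts, normals, tri_mat, base_color)
  .clean_mesh(m)
}

# triangulations for marching-tetrahedra cases: given the set of corners
# (1..4 local) above the iso level, return triangles as lists of three
# edges (in_corner, out_corner). One corner in (or out): one triangle on
# its three incident edges. Two in: quad split into two triangles.
.tet_case_tris <- function(inside) {
  outside <- setdiff(1:4, inside)
  if (length(inside) == 1) {
    i <- inside
    return(list(list(c(i, outside[1]), c(i, outside[2]), c(i, outside[3]))))
  }
  if (length(inside) == 3) {
    o <- outside
    ins <- inside
    return(list(list(c(ins[1], o), c(ins[2], o), c(ins[3], o))))
  }
  # two in, two out: quad with corners (i1,o1) (i1,o2) (i2,o2) (i2,o1)
  i1 <- inside[1]; i2 <- inside[2]; o1 <- outside[1]; o2 <- outside[2]
  list(list(c(i1, o1), c(i1, o2), c(i2, o2)),
       list(c(i1, o1), c(i2, o2), c(i2, o1)))
}

.lin_to_ijk <- function(lin, d) {
  lin0 <- lin - 1L
  i <- lin0 %% d[1]
  j <- (lin0 %/% d[1]) %% d[2]
  k <- lin0 %/% (d[1] * d[2])
  cbind(i, j, k)
}

# central-difference gradient of the grid, trilinearly interpolated at
# 0-based grid positions, negated and normalized
.gradient_normals <- function(g, pos, voxel) {
  d <- dim(g)
  grad_axis <- function(ax) {
    n <- d[ax]
    idx_hi <- pmin(seq_len(n) + 1L, n)
    idx_lo <- pmax(seq_len(n) - 1L, 1L)
    denom <- (idx_hi - idx_lo) * voxel[ax]
    hi <- switch(ax, g[idx_hi, , , drop = FALSE],
                 g[, idx_hi, , drop = FALSE], g[, , idx_hi, drop = FALSE])
    lo <- switch(ax, g[idx_lo, , , drop = FALSE],
                 g[, idx_lo, , drop = FALSE], g[, , idx_lo, drop = FALSE])
    sweep(hi - lo, ax, denom, "/")
  }
  gx <- grad_axis(1); gy <- grad_axis(2); gz <- grad_axis(3)
  n <- cbind(.trilinear(gx, pos), .trilinear(gy, pos), .trilinear(gz, pos))
  n <- -n
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

# trilinear interpolation of a 3D array at 0-based coordinates
.trilinear <- function(a, pos) {
  d <- dim(a)
  i0 <- pmin(pmax(floor(pos[, 1]), 0), d[1] - 2); fx <- pos[, 1] - i0
  j0 <- pmin(pmax(floor(pos[, 2]), 0), d[2] - 2); fy <- pos[, 2] - j0
  k0 <- pmin(pmax(floor(pos[, 3]), 0), d[3] - 2); fz <- pos[, 3] - k0
  fx <- pmin(pmax(fx, 0), 1); fy <- pmin(pmax(fy, 0), 1)
  fz <- pmin(pmax(fz, 0), 1)
  at <- function(di, dj, dk)
    a[cbind(i0 + di + 1, j0 + dj + 1, k0 + dk + 1)]
  (1 - fz) * ((1 - fy) * ((1 - fx) * at(0, 0, 0) + fx * at(1, 0, 0)) +
              fy * ((1 - fx) * at(0, 1, 0) + fx * at(1, 1, 0))) +
    fz * ((1 - fy) * ((1 - fx) * at(0, 0, 1) + fx * at(1, 0, 1)) +
          fy * ((1 - fx) * at(0, 1, 1) + fx * at(1, 1, 1)))
}

.clean_mesh <- function(m) {
  tri <- m$triangles
  if (nrow(tri) == 0) return(m)
  dup <- tri[, 1] == tri[, 2] | tri[, 2] == tri[, 3] | tri[, 1] == tri[, 3]
  tri <- tri[!dup, , drop = FALSE]
  if (nrow(tri) > 0) {
    a <- m$vertices[tri[, 1], , drop = FALSE]
    b <- m$vertices[tri[, 2], , drop = FALSE]
    c_ <- m$vertices[tri[, 3], , drop = FALSE]
    u <- b - a; v <- c_ - a
    cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                u[, 3] * v[, 1] - u[, 1] * v[, 3],
                u[, 1] * v[, 2] - u[, 2] * v[, 1])
    area2 <- sqrt(rowSums(cr^2)) / 2
    tri <- tri[area2 > 1e-12, , drop = FALSE]
  }
  used <- sort(unique(as.vector(tri)))
  remap <- integer(nrow(m$vertices))
  remap[used] <- seq_along(used)
  triangle_mesh(m$vertices[used, , drop = FALSE],
                m$vertex_normals[used, , drop = FALSE],
                matrix(remap[tri], ncol = 3), m$base_color)
}
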