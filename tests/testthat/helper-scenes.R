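# shared helpers: small deterministic scenes and measures used across tests

# orthographic camera on +z looking straight down at the z = 0 plane
down_camera <- function(width = 128, height = 128, scale = 0.25,
                        dist = 50) {
  camera(c(0, 0, dist), c(0, 0, -1), c(0, 1, 0), width, height,
         mode = "orthographic", scale = scale)
}

# plane through the origin tilted by theta degrees about the y axis
tilted_plane_scene <- function(theta_deg) {
  th <- theta_deg * pi / 180
  analytic_scene(prim_plane(c(0, 0, 0), c(sin(th), 0, cos(th))))
}

# step edge of height h: floor z = 0 (x <= 0), slab top z = h (x >= 0)
step_scene <- function(h) {
  up <- c(0, 0, 1)
  analytic_scene(
    prim_plane(c(0, 0, 0), up,
               bounds = list(list(dir = c(1, 0, 0), max = 0))),
    prim_plane(c(0, 0, h), up,
               bounds = list(list(dir = c(-1, 0, 0), max = 0))),
    prim_plane(c(0, 0, 0), c(-1, 0, 0),
               bounds = list(list(dir = c(0, 0, 1), max = h),
                             list(dir = c(0, 0, -1), max = 0))))
}

# total variation of a matrix (sum of absolute neighbor differences)
total_variation <- function(m) {
  sum(abs(diff(m))) + sum(abs(t(diff(t(m)))))
}

n_distinct_vals <- function(m, digits = 10) {
  length(unique(as.vector(round(m, digits))))
}

# connected components of a triangle mesh (union-find over shared vertices)
mesh_components <- function(mesh) {
  n <- nrow(mesh$vertices)
  if (n == 0) return(0L)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (i in seq_len(nrow(mesh$triangles))) {
    tr <- mesh$triangles[i, ]
    for (pair in list(tr[1:2], tr[2:3])) {
      ra <- find(pair[1]); rb <- find(pair[2])
      if (ra != rb) parent[ra] <- rb
    }
  }
  length(unique(vapply(seq_len(n), find, 1L)))
}

# undirected edge -> incident triangle count table
mesh_edge_counts <- function(mesh) {
  tri <- mesh$triangles
  ed <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  table(key)
}
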