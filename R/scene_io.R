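#' Bundled per-element van der Waals radii (Angstrom)
#'
#' Fixed table used for sphere scenes so renders are reproducible; unknown
#' elements fall back to the carbon radius 1.70.
#' @export
vdw_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
               P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
               FE = 1.80, ZN = 1.39, MG = 1.73, CA = 1.74, "NA" = 2.27,
               K = 2.75)

.vdw_default <- 1.70

# CPK-style element colors, channels in [0,1]
.cpk_colors <- rbind(
  H  = c(1.00, 1.00, 1.00),
  C  = c(0.55, 0.55, 0.55),
  N  = c(0.20, 0.30, 0.95),
  O  = c(0.95, 0.15, 0.15),
  S  = c(0.95, 0.90, 0.15),
  P  = c(1.00, 0.55, 0.10),
  FE = c(0.85, 0.45, 0.10),
  ZN = c(0.45, 0.50, 0.55)
)
.cpk_default <- c(0.90, 0.50, 0.70)

#' Construct an atom set (sphere scene)
#'
#' @param positions N x 3 matrix of atom centers (Angstrom).
#' @param radii length-N vector of sphere radii, each in (0.2, 5).
#' @param colors N x 3 matrix of RGB in `[0,1]`, or a single RGB triple
#'   recycled.
#' @param elements length-N character vector of element symbols.
#' @return an object of class `"atom_set"`.
#' @export
atom_set <- function(positions, radii, colors = c(0.55, 0.55, 0.55),
                     elements = rep("C", NROW(positions))) {
  positions <- .as_mat3(positions)
  if (nrow(positions) == 0)
    positions <- matrix(numeric(0), 0, 3)
  radii <- as.numeric(radii)
  stopifnot(length(radii) == nrow(positions),
            all(is.finite(positions)),
            all(radii > 0.2 & radii < 5))
  if (is.null(dim(colors)))
    colors <- matrix(colors, nrow(positions), 3, byrow = TRUE)
  stopifnot(nrow(colors) == nrow(positions) || nrow(positions) == 0,
            all(colors >= 0 & colors <= 1))
  structure(list(positions = positions, radii = radii,
                 colors = colors, elements = as.character(elements)),
            class = "atom_set")
}

#' @export
print.atom_set <- function(x, ...) {
  cat(sprintf("<atom_set> %d atoms\n", n_atoms(x)))
  invisible(x)
}

#' Number of atoms in an atom set
#' @param atoms an [atom_set()].
#' @export
n_atoms <- function(atoms) nrow(atoms$positions)

element_color <- function(elements, scheme = c("cpk", "uniform"),
                          uniform = c(0.55, 0.55, 0.55)) {
  scheme <- match.arg(scheme)
  n <- length(elements)
  if (scheme == "uniform")
    return(matrix(uniform, n, 3, byrow = TRUE))
  key <- toupper(trimws(elements))
  out <- matrix(.cpk_default, n, 3, byrow = TRUE)
  hit <- key %in% rownames(.cpk_colors)
  out[hit, ] <- .cpk_colors[key[hit], , drop = FALSE]
  out
}

element_radius <- function(elements, table = vdw_radii) {
  key <- toupper(trimws(elements))
  r <- unname(table[key])
  r[is.na(r)] <- .vdw_default
  r
}

#' Read atoms from a PDB file
#'
#' Parses fixed-column ATOM/HETATM records (columns 31-54 for x, y, z,
#' columns 77-78 for the element symbol, falling back to the atom-name
#' column when the element field is blank). Records whose alternate
#' location indicator is neither blank nor `'A'` are skipped, so
#' alternate conformers do not produce doubled spheres. Radii come from
#' the bundled van der Waals table; colors from the CPK scheme or a
#' uniform color.
#'
#' @param path PDB file path.
#' @param radius_table named vector of per-element radii (Angstrom).
#' @param color_scheme `"cpk"` or `"uniform"`.
#' @param uniform_color RGB triple used when `color_scheme = "uniform"`.
#' @return an [atom_set()]; an empty file (no atom records) yields an
#'   empty atom set, not an error.
#' @export
read_pdb_atoms <- function(path, radius_table = vdw_radii,
                           color_scheme = c("cpk", "uniform"),
                           uniform_color = c(0.55, 0.55, 0.55)) {
  color_scheme <- match.arg(color_scheme)
  if (!file.exists(path)) stop("PDB file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  if (!any(is_atom))
    return(atom_set(matrix(numeric(0), 0, 3), numeric(0),
                    matrix(numeric(0), 0, 3), character(0)))
  ln <- which(is_atom)
  alt <- substr(lines[ln], 17, 17)
  keep <- alt %in% c(" ", "", "A")
  ln <- ln[keep]
  if (length(ln) == 0)
    return(atom_set(matrix(numeric(0), 0, 3), numeric(0),
                    matrix(numeric(0), 0, 3), character(0)))
  x <- suppressWarnings(as.numeric(substr(lines[ln], 31, 38)))
  y <- suppressWarnings(as.numeric(substr(lines[ln], 39, 46)))
  z <- suppressWarnings(as.numeric(substr(lines[ln], 47, 54)))
  bad <- which(is.na(x) | is.na(y) | is.na(z))
  if (length(bad) > 0)
    stop(sprintf("unparsable coordinate columns at line %d of %s",
                 ln[bad[1]], path))
  elem <- trimws(substr(lines[ln], 77, 78))
  name_fallback <- trimws(substr(lines[ln], 13, 14))
  elem[elem == ""] <- gsub("[0-9]", "", name_fallback[elem == ""])
  atom_set(cbind(x, y, z),
           element_radius(elem, radius_table),
           element_color(elem, color_scheme, uniform_color),
           elem)
}

#' Write an atom set to a PDB file
#'
#' Emits standard fixed-column ATOM records via [bio3d::write.pdb()] so
#' fixture scenes round-trip through the same dialect the reader expects
#' (coordinates at 1e-3 Angstrom column precision).
#'
#' @param atoms an [atom_set()].
#' @param path output path.
#' @export
write_pdb_atoms <- function(atoms, path) {
  n <- n_atoms(atoms)
  if (n == 0) { writeLines("END", path); return(invisible(path)) }
  el <- toupper(trimws(atoms$elements))
  el[el == ""] <- "C"
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(atoms$positions)),
                   type = rep("ATOM", n),
                   resno = seq_len(n), resid = rep("MOL", n),
                   eleno = seq_len(n), elety = el,
                   chain = rep("A", n), elesy = el)
  invisible(path)
}

#' Construct a density map
#'
#' @param grid 3D numeric array of density values, canonical `[x, y, z]`
#'   axis order.
#' @param origin position (Angstrom) of the center of voxel `[1,1,1]`.
#' @param voxel_size length-3 voxel spacing (Angstrom), all > 0.
#' @return an object of class `"density_map"`.
#' @export
density_map <- function(grid, origin = c(0, 0, 0), voxel_size = c(1, 1, 1)) {
  stopifnot(length(dim(grid)) == 3, all(dim(grid) >= 1),
            all(is.finite(grid)), all(voxel_size > 0),
            length(origin) == 3, all(is.finite(origin)))
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  structure(list(grid = grid, origin = as.numeric(origin),
                 voxel_size = as.numeric(voxel_size)),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<density_map> %dx%dx%d voxels, %g x %g x %g Angstrom/voxel\n",
              d[1], d[2], d[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

#' Read an MRC2014 / CCP4 density map
#'
#' Supports modes 0 (int8), 1 (int16) and 2 (float32). The data block is
#' converted from the file's axis order (MAPC/MAPR/MAPS) to canonical
#' `(x, y, z)` order, so downstream code sees a single convention
#' regardless of how the map was deposited. The origin is taken from the
#' ORIGIN header fields, falling back to NxSTART offsets when ORIGIN is
#' all-zero and the start indices are not.
#'
#' @param path MRC/CCP4 file path.
#' @return a [density_map()].
#' @export
read_mrc <- function(path) {
  if (!file.exists(path)) stop("MRC file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  h_int1 <- readBin(con, "integer", 10, size = 4, endian = "little")
  nxyz <- h_int1[1:3]; mode <- h_int1[4]; nstart <- h_int1[5:7]
  mxyz <- h_int1[8:10]
  cella <- readBin(con, "numeric", 3, size = 4, endian = "little")
  cellb <- readBin(con, "numeric", 3, size = 4, endian = "little")
  mapcrs <- readBin(con, "integer", 3, size = 4, endian = "little")
  dstats <- readBin(con, "numeric", 3, size = 4, endian = "little")
  ispg <- readBin(con, "integer", 2, size = 4, endian = "little")
  nsymbt <- ispg[2]
  readBin(con, "raw", 100)                 # EXTRA block (words 26-49)
  origin <- readBin(con, "numeric", 3, size = 4, endian = "little")
  map_id <- rawToChar(readBin(con, "raw", 4))
  readBin(con, "raw", 4)                   # MACHST
  readBin(con, "numeric", 1, size = 4, endian = "little")  # RMS
  readBin(con, "raw", 4 + 800)             # NLABL + labels
  if (!identical(substr(map_id, 1, 3), "MAP"))
    stop("not an MRC2014 map (missing MAP stamp)")
  if (any(nxyz < 1) || any(mxyz < 1)) stop("inconsistent MRC header dimensions")
  if (!setequal(mapcrs, 1:3)) stop("inconsistent MRC axis-correspondence fields")
  if (nsymbt > 0) readBin(con, "raw", nsymbt)
  nvox <- prod(nxyz)
  vals <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", nvox, size = 1, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", nvox, size = 2, signed = TRUE,
                             endian = "little")),
    "2" = readBin(con, "numeric", nvox, size = 4, endian = "little"),
    stop("unsupported MRC mode ", mode, " (modes 0, 1, 2 supported)"))
  if (length(vals) != nvox) stop("truncated MRC data block")
  arr <- array(vals, dim = nxyz)           # file order: column axis fastest
  perm <- match(1:3, mapcrs)               # file axis holding crystal axis i
  arr <- aperm(arr, perm)
  voxel <- cella / mxyz
  voxel[!is.finite(voxel) | voxel <= 0] <- 1
  nstart_xyz <- nstart[perm]
  org <- if (any(origin != 0)) origin else nstart_xyz * voxel
  density_map(arr, org, voxel)
}

#' Write a density map as an MRC2014 file (mode 2, float32)
#'
#' @param map a [density_map()].
#' @param path output path.
#' @param axis_order permutation of 1:3 written to MAPC/MAPR/MAPS; the data
#'   block is permuted to match, so any order round-trips to the same
#'   canonical map. Default `c(1, 2, 3)`.
#' @export
write_mrc <- function(map, path, axis_order = c(1, 2, 3)) {
  stopifnot(setequal(axis_order, 1:3))
  d <- dim(map$grid)
  arr <- aperm(map$grid, axis_order)       # file axes hold crystal axes
  con <- file(path, "wb")
  on.exit(close(con))
  wint <- function(x) writeBin(as.integer(x), con, size = 4,
                               endian = "little")
  wflt <- function(x) writeBin(as.numeric(x), con, size = 4,
                               endian = "little")
  wint(dim(arr)); wint(2L); wint(c(0L, 0L, 0L)); wint(d)
  wflt(d * map$voxel_size); wflt(c(90, 90, 90))
  wint(axis_order)
  wflt(c(min(map$grid), max(map$grid), mean(map$grid)))
  wint(c(1L, 0L))                          # ISPG, NSYMBT
  writeBin(raw(100), con)                  # EXTRA
  wflt(map$origin)
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wflt(stats::sd(as.numeric(map$grid)))
  wint(0L)
  writeBin(raw(800), con)
  wflt(as.numeric(arr))
  invisible(path)
}
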