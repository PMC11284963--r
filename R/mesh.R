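#' Triangulated bone-surface mesh
#'
#' The container every stage of the pipeline consumes and produces: a vertex
#' matrix in millimetres and a face index matrix with counter-clockwise
#' (outward-normal) winding.
#'
#' @param vertices Numeric n x 3 matrix of vertex coordinates (mm).
#' @param faces Integer m x 3 matrix of 1-based vertex indices.
#' @return A `surface_mesh` object.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  mesh <- structure(list(vertices = vertices, faces = faces),
                    class = "surface_mesh")
  validate_mesh(mesh)
  mesh
}

validate_mesh <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  if (!is.matrix(v) || ncol(v) != 3L || nrow(v) < 4L) {
    stop("mesh must have an n x 3 vertex matrix with at least 4 vertices",
         call. = FALSE)
  }
  if (!all(is.finite(v))) {
    stop("mesh vertices must be finite", call. = FALSE)
  }
  if (!is.matrix(f) || ncol(f) != 3L || nrow(f) < 1L) {
    stop("mesh must have an m x 3 face matrix", call. = FALSE)
  }
  if (min(f) < 1L || max(f) > nrow(v)) {
    stop("face indices out of range", call. = FALSE)
  }
  if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3])) {
    stop("mesh contains a face with a repeated vertex", call. = FALSE)
  }
  invisible(mesh)
}

#' @export
print.surface_mesh <- function(x, ...) {
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("<surface_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  cat(sprintf("  bounds (mm): x [%.2f, %.2f]  y [%.2f, %.2f]  z [%.2f, %.2f]\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

#' Number of vertices / faces of a mesh
#' @param mesh A [surface_mesh()].
#' @return Integer count.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' @rdname n_vertices
#' @export
n_faces <- function(mesh) nrow(mesh$faces)

#' Merge coincident vertices
#'
#' Welds vertices closer than `tol` (exact duplicates after rounding to the
#' tolerance grid) and re-indexes faces; faces that collapse to fewer than
#' three distinct vertices are dropped. STL files store one vertex per face
#' corner, so welding is required to recover shared topology.
#'
#' @param mesh A [surface_mesh()].
#' @param tol Welding tolerance in mm.
#' @return A welded `surface_mesh`.
#' @export
weld_vertices <- function(mesh, tol = 1e-6) {
  v <- mesh$vertices
  key <- paste(round(v[, 1] / tol), round(v[, 2] / tol), round(v[, 3] / tol))
  first <- !duplicated(key)
  map <- match(key, key[first])
  new_v <- v[first, , drop = FALSE]
  new_f <- matrix(map[mesh$faces], ncol = 3L)
  keep <- new_f[, 1] != new_f[, 2] & new_f[, 2] != new_f[, 3] &
    new_f[, 1] != new_f[, 3]
  new_f <- new_f[keep, , drop = FALSE]
  surface_mesh(new_v, new_f)
}

# directed edges as m x 6 index pairs
mesh_edges <- function(mesh) {
  f <- mesh$faces
  rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
}

#' Check closed (watertight) topology
#'
#' A closed orientable triangulated surface has every undirected edge shared
#' by exactly two faces, with opposite directions.
#'
#' @param mesh A [surface_mesh()].
#' @return Logical scalar.
#' @export
is_watertight <- function(mesh) {
  e <- mesh_edges(mesh)
  und <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(und)
  if (any(tab != 2L)) return(FALSE)
  # consistent orientation: each directed edge appears exactly once
  dir <- paste(e[, 1], e[, 2])
  !anyDuplicated(dir)
}

#' Euler characteristic V - E + F
#' @param mesh A [surface_mesh()].
#' @return Integer; 2 for a sphere-topology surface.
#' @export
euler_characteristic <- function(mesh) {
  e <- mesh_edges(mesh)
  und <- unique(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  nrow(mesh$vertices) - length(und) + nrow(mesh$faces)
}

#' Enclosed volume of a closed mesh
#'
#' Signed volume by the divergence theorem (sum of signed tetrahedra against
#' the origin); positive for outward-oriented closed surfaces.
#'
#' @param mesh A [surface_mesh()].
#' @return Volume in mm^3 (signed).
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  cross <- cbind(b[, 2] * c_[, 3] - b[, 3] * c_[, 2],
                 b[, 3] * c_[, 1] - b[, 1] * c_[, 3],
                 b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  sum(rowSums(a * cross)) / 6
}

# Area-weighted per-vertex normals (used for surface noise displacement).
vertex_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n <- matrix(0, nrow(v), 3)
  for (j in 1:3) {
    acc <- rowsum(fn, group = f[, j])
    idx <- as.integer(rownames(acc))
    n[idx, ] <- n[idx, ] + acc
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}
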