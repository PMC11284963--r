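#' Read a surface mesh from STL, PLY or OBJ
#'
#' Supports binary and ASCII STL, ASCII PLY, and OBJ with triangular faces.
#' Coordinates are taken to be millimetres. STL vertices (stored per facet)
#' are welded into shared topology on load.
#'
#' @param path Path to a `.stl`, `.ply` or `.obj` file.
#' @param weld Weld coincident vertices after reading (default `TRUE`).
#' @param weld_tol Welding tolerance in mm.
#' @return A [surface_mesh()].
#' @export
load_mesh <- function(path, weld = TRUE, weld_tol = 1e-6) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  mesh <- switch(ext,
    stl = read_stl(path),
    ply = read_ply(path),
    obj = read_obj(path),
    stop("unsupported mesh format: .", ext, " (expected stl, ply or obj)",
         call. = FALSE)
  )
  if (weld) mesh <- weld_vertices(mesh, tol = weld_tol)
  mesh
}

#' Write a surface mesh to STL, PLY or OBJ
#'
#' @param mesh A [surface_mesh()].
#' @param path Output path; the extension selects the format.
#' @param binary For STL, write the binary dialect (default) or ASCII.
#' @return `path`, invisibly.
#' @export
save_mesh <- function(mesh, path, binary = TRUE) {
  validate_mesh(mesh)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    stl = if (binary) write_stl_binary(mesh, path) else write_stl_ascii(mesh, path),
    ply = write_ply(mesh, path),
    obj = write_obj(mesh, path),
    stop("unsupported mesh format: .", ext, call. = FALSE)
  )
  invisible(path)
}

# ---- STL ----

read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", 80L)
  n_tri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  size <- file.info(path)$size
  is_binary <- length(header) == 80L && length(n_tri) == 1L &&
    !is.na(n_tri) && size == 84 + 50 * as.numeric(n_tri)
  close(con)
  on.exit()
  if (is_binary) read_stl_binary(path, n_tri) else read_stl_ascii(path)
}

read_stl_binary <- function(path, n_tri) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 84L)
  if (n_tri < 1L) stop("empty STL mesh", call. = FALSE)
  raw <- readBin(con, "raw", 50L * n_tri)
  m <- matrix(raw, nrow = 50L)
  # each record: 12 floats (48 bytes) + 2-byte attribute
  floats <- readBin(as.vector(m[1:48, ]), "numeric", n = 12L * n_tri,
                    size = 4L, endian = "little")
  fm <- matrix(floats, nrow = 12L)  # per-facet: normal xyz, v1, v2, v3
  verts <- rbind(t(fm[4:6, , drop = FALSE]),
                 t(fm[7:9, , drop = FALSE]),
                 t(fm[10:12, , drop = FALSE]))
  # reorder so facet i owns rows (3i-2, 3i-1, 3i)
  idx <- as.vector(rbind(seq_len(n_tri), seq_len(n_tri) + n_tri,
                         seq_len(n_tri) + 2L * n_tri))
  verts <- verts[idx, , drop = FALSE]
  faces <- matrix(seq_len(3L * n_tri), ncol = 3L, byrow = TRUE)
  surface_mesh(verts, faces)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) < 3L || length(vl) %% 3L != 0L) {
    stop("unreadable ASCII STL: vertex count not a multiple of 3",
         call. = FALSE)
  }
  nums <- lapply(strsplit(trimws(vl), "\\s+"), function(p) as.numeric(p[2:4]))
  verts <- do.call(rbind, nums)
  if (any(!is.finite(verts))) stop("unreadable ASCII STL: bad coordinates",
                                   call. = FALSE)
  faces <- matrix(seq_len(nrow(verts)), ncol = 3L, byrow = TRUE)
  surface_mesh(verts, faces)
}

write_stl_binary <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  header <- raw(80L)
  txt <- charToRaw("deltafr binary STL")
  header[seq_along(txt)] <- txt
  writeBin(header, con)
  f <- mesh$faces
  writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
  v <- mesh$vertices
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  nrm <- face_unit_normals(a, b, c_)
  rec <- t(cbind(nrm, a, b, c_))  # 12 floats per facet, column-per-facet
  fl <- writeBin(as.numeric(rec), raw(), size = 4L, endian = "little")
  fm <- matrix(fl, nrow = 48L)
  out <- rbind(fm, matrix(as.raw(0L), nrow = 2L, ncol = ncol(fm)))
  writeBin(as.vector(out), con)
  invisible(path)
}

write_stl_ascii <- function(mesh, path) {
  f <- mesh$faces
  v <- mesh$vertices
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  nrm <- face_unit_normals(a, b, c_)
  fmt <- function(m) sprintf("%.9g %.9g %.9g", m[, 1], m[, 2], m[, 3])
  body <- paste0("  facet normal ", fmt(nrm), "\n",
                 "    outer loop\n",
                 "      vertex ", fmt(a), "\n",
                 "      vertex ", fmt(b), "\n",
                 "      vertex ", fmt(c_), "\n",
                 "    endloop\n",
                 "  endfacet")
  writeLines(c("solid deltafr", body, "endsolid deltafr"), path)
  invisible(path)
}

face_unit_normals <- function(a, b, c_) {
  e1 <- b - a
  e2 <- c_ - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

# ---- OBJ ----

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  if (length(vl) == 0L || length(fl) == 0L) {
    stop("unreadable OBJ: no vertices or faces", call. = FALSE)
  }
  verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                 function(p) as.numeric(p[2:4])))
  faces <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(p) {
    ids <- vapply(p[-1], function(tok) as.integer(strsplit(tok, "/")[[1]][1]),
                  integer(1))
    if (length(ids) != 3L) stop("OBJ faces must be triangles", call. = FALSE)
    ids
  }))
  surface_mesh(verts, faces)
}

write_obj <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  lines <- c("# deltafr OBJ",
             sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
             sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]))
  writeLines(lines, path)
  invisible(path)
}

# ---- PLY (ASCII) ----

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L || trimws(lines[1]) != "ply") {
    stop("unreadable PLY: missing magic", call. = FALSE)
  }
  end <- match("end_header", trimws(lines))
  if (is.na(end)) stop("unreadable PLY: no end_header", call. = FALSE)
  header <- trimws(lines[seq_len(end)])
  if (!any(grepl("^format ascii", header))) {
    stop("only ASCII PLY is supported", call. = FALSE)
  }
  nv <- as.integer(sub("^element vertex\\s+", "",
                       grep("^element vertex", header, value = TRUE)[1]))
  nf <- as.integer(sub("^element face\\s+", "",
                       grep("^element face", header, value = TRUE)[1]))
  if (is.na(nv) || is.na(nf)) stop("unreadable PLY header", call. = FALSE)
  body <- lines[(end + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  vt <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                              function(p) as.numeric(p[1:3])))
  ft <- do.call(rbind, lapply(strsplit(trimws(body[nv + seq_len(nf)]), "\\s+"),
                              function(p) {
    n <- as.integer(p[1])
    if (n != 3L) stop("PLY faces must be triangles", call. = FALSE)
    as.integer(p[2:4]) + 1L
  }))
  surface_mesh(vt, ft)
}

write_ply <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  header <- c("ply", "format ascii 1.0", "comment deltafr",
              sprintf("element vertex %d", nrow(v)),
              "property float x", "property float y", "property float z",
              sprintf("element face %d", nrow(f)),
              "property list uchar int vertex_indices",
              "end_header")
  lines <- c(header,
             sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
             sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L))
  writeLines(lines, path)
  invisible(path)
}
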