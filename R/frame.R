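#' Bone coordinate frame from principal axes
#'
#' A `bone_frame` holds the long axis and two transverse axes of a bone, its
#' axial length, an origin on the long axis at the distal end, and a
#' `proximal_sign` telling which direction along `axis_long` points toward
#' the hip. Axes are orthonormal and right-handed
#' (`det[axis_long axis_2 axis_3] = +1`).
#'
#' @param origin Distal-end axis point (mm).
#' @param axis_long,axis_2,axis_3 Orthonormal unit vectors.
#' @param length Axial extent of the bone (mm).
#' @param proximal_sign +1 if `axis_long` points proximally, -1 otherwise.
#' @return A `bone_frame` object.
#' @export
bone_frame <- function(origin, axis_long, axis_2, axis_3, length,
                       proximal_sign = 1) {
  A <- cbind(axis_long, axis_2, axis_3)
  if (max(abs(crossprod(A) - diag(3))) > 1e-9 || abs(det(A) - 1) > 1e-9) {
    stop("frame axes must be orthonormal and right-handed", call. = FALSE)
  }
  stopifnot_scalar(length, "length", positive = TRUE)
  if (!proximal_sign %in% c(-1, 1)) {
    stop("`proximal_sign` must be +1 or -1", call. = FALSE)
  }
  structure(list(origin = as.numeric(origin),
                 axis_long = as.numeric(axis_long),
                 axis_2 = as.numeric(axis_2),
                 axis_3 = as.numeric(axis_3),
                 length = length,
                 proximal_sign = proximal_sign),
            class = "bone_frame")
}

#' @export
print.bone_frame <- function(x, ...) {
  cat(sprintf("<bone_frame> length %.2f mm, proximal_sign %+d\n",
              x$length, x$proximal_sign))
  cat(sprintf("  long axis: (%.4f, %.4f, %.4f)\n",
              x$axis_long[1], x$axis_long[2], x$axis_long[3]))
  invisible(x)
}

# Right-handed basis used for angle components and the twist: columns are
# (e_x, e_y, e_z) with e_z the proximal direction and e_x the middle
# principal axis. B maps bone-frame coordinates to world coordinates.
frame_basis <- function(frame) {
  e_z <- frame$proximal_sign * frame$axis_long
  e_x <- frame$axis_2
  e_y <- c(e_z[2] * e_x[3] - e_z[3] * e_x[2],
           e_z[3] * e_x[1] - e_z[1] * e_x[3],
           e_z[1] * e_x[2] - e_z[2] * e_x[1])
  cbind(e_x, e_y, e_z, deparse.level = 0)
}

#' Principal-axis bone frame of a mesh
#'
#' The long axis is the eigenvector of the vertex covariance with the largest
#' eigenvalue; length is the extent of vertex projections on it. If no
#' `proximal_hint` is given, the bone half whose vertices lie further (on
#' average) from the long axis is taken as proximal — for a femur the offset
#' head, neck and greater trochanter outweigh the condyles.
#'
#' The transverse axis `axis_2` is anchored on anatomy rather than on the
#' transverse covariance eigenvectors: an elongated bone is nearly tubular,
#' so those eigenvectors are ill-conditioned and can swing by tens of
#' degrees between two scans of the same subject. Instead, `axis_2` is the
#' mean transverse direction of the most radially distant vertices in the
#' proximal quarter of the bone (the head/neck/trochanter apex, a sharp and
#' stable landmark); when the proximal quarter has no clear apex (a
#' transversely symmetric shape), the second eigenvector — signed by the
#' third central moment of its projections — is used as a fallback. Either way the frame is equivariant under rigid
#' motions of the mesh.
#'
#' @param mesh A [surface_mesh()].
#' @param proximal_hint Optional direction (length-3); the proximal end is the
#'   one this vector points toward.
#' @return A [bone_frame()].
#' @export
principal_frame <- function(mesh, proximal_hint = NULL) {
  validate_mesh(mesh)
  v <- mesh$vertices
  ctr <- colMeans(v)
  x <- sweep(v, 2, ctr)
  C <- crossprod(x) / nrow(x)
  eg <- eigen(C, symmetric = TRUE)
  if (eg$values[3] <= 1e-10 * eg$values[1]) {
    stop("degenerate geometry: vertex covariance has rank < 3", call. = FALSE)
  }
  a1 <- deterministic_sign(eg$vectors[, 1], x)
  s <- as.vector(x %*% a1)
  len <- max(s) - min(s)
  if (!is.null(proximal_hint)) {
    ps <- if (sum(as.numeric(proximal_hint) * a1) >= 0) 1 else -1
  } else {
    # mean radial distance from the long axis, split at the axial midpoint
    r <- sqrt(pmax(rowSums(x^2) - s^2, 0))
    mid <- (max(s) + min(s)) / 2
    ps <- if (mean(r[s > mid]) >= mean(r[s <= mid])) 1 else -1
  }
  d <- ps * a1
  s_d <- as.vector(x %*% d)
  origin <- ctr + min(s_d) * d
  # transverse anchor: mean direction of the most radially distant vertices
  # of the proximal quarter (head/trochanter apex), a sharp landmark
  slab <- x[s_d >= min(s_d) + 0.75 * len, , drop = FALSE]
  a2 <- NULL
  if (nrow(slab) >= 30L) {
    t_comp <- slab - outer(as.vector(slab %*% a1), a1)
    r <- sqrt(rowSums(t_comp^2))
    top <- r >= stats::quantile(r, 0.9)
    if (mean(r[top]) > 1.25 * stats::median(r)) {
      dir <- colSums(t_comp[top, , drop = FALSE] / r[top])
      if (sqrt(sum(dir^2)) > 1e-8) a2 <- dir / sqrt(sum(dir^2))
    }
  }
  if (is.null(a2)) {
    a2 <- deterministic_sign(eg$vectors[, 2], x)
    a2 <- a2 - sum(a2 * a1) * a1
    a2 <- a2 / sqrt(sum(a2^2))
  }
  a3 <- c(a1[2] * a2[3] - a1[3] * a2[2],
          a1[3] * a2[1] - a1[1] * a2[3],
          a1[1] * a2[2] - a1[2] * a2[1])
  bone_frame(origin = origin, axis_long = a1, axis_2 = a2, axis_3 = a3,
             length = len, proximal_sign = ps)
}

# Fix an eigenvector's sign from the skewness of the centred projections;
# falls back to the largest-magnitude component when symmetric.
deterministic_sign <- function(axis, x) {
  p <- as.vector(x %*% axis)
  m3 <- mean(p^3)
  scale3 <- mean(p^2)^1.5
  if (abs(m3) > 1e-8 * max(scale3, 1e-12)) {
    if (m3 < 0) axis <- -axis
  } else {
    k <- which.max(abs(axis))
    if (axis[k] < 0) axis <- -axis
  }
  axis
}

#' Axial fraction of a point along a bone
#'
#' Signed distance from the distal end along the proximal direction, divided
#' by bone length: 0 at the distal tip, 1 at the proximal tip. Points outside
#' the bone give values below 0 or above 1.
#'
#' @param frame A [bone_frame()].
#' @param point A length-3 point or an n x 3 matrix of points.
#' @return Numeric vector of fractions.
#' @export
axial_fraction <- function(frame, point) {
  stopifnot(inherits(frame, "bone_frame"))
  d <- frame$proximal_sign * frame$axis_long
  if (is.matrix(point)) {
    as.vector(sweep(point, 2, frame$origin) %*% d) / frame$length
  } else {
    sum((as.numeric(point) - frame$origin) * d) / frame$length
  }
}

#' Extract a proximal or distal section of a bone mesh
#'
#' Keeps the faces whose three vertices all lie within the requested axial
#' fraction of the bone (`u >= 1 - fraction` for proximal, `u <= fraction`
#' for distal), then drops unreferenced vertices. No face is split, so the
#' section boundary follows existing triangle edges.
#'
#' @param mesh A [surface_mesh()].
#' @param frame The [bone_frame()] defining axial fractions.
#' @param end `"proximal"` or `"distal"`.
#' @param fraction Fraction of the bone length in (0, 1].
#' @return A [surface_mesh()] submesh.
#' @export
extract_section <- function(mesh, frame, end = c("proximal", "distal"),
                            fraction) {
  end <- match.arg(end)
  validate_mesh(mesh)
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("`fraction` must lie in (0, 1]", call. = FALSE)
  }
  u <- axial_fraction(frame, mesh$vertices)
  tol <- 1e-9
  ok <- if (end == "proximal") u >= 1 - fraction - tol else u <= fraction + tol
  f <- mesh$faces
  keep <- ok[f[, 1]] & ok[f[, 2]] & ok[f[, 3]]
  if (!any(keep)) {
    stop("empty section: no face lies entirely within the requested fraction",
         call. = FALSE)
  }
  f <- f[keep, , drop = FALSE]
  used <- sort(unique(as.vector(f)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  surface_mesh(mesh$vertices[used, , drop = FALSE],
               matrix(remap[f], ncol = 3L))
}
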