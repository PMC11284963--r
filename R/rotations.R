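#' Elementary rotation matrices
#'
#' Right-handed rotations about the fixed x, y and z axes, in degrees.
#'
#' @param angle Rotation angle in degrees.
#' @return A 3x3 rotation matrix.
#' @export
rot_x <- function(angle) {
  a <- deg2rad(angle)
  matrix(c(1, 0, 0,
           0, cos(a), sin(a),
           0, -sin(a), cos(a)), 3, 3)
}

#' @rdname rot_x
#' @export
rot_y <- function(angle) {
  a <- deg2rad(angle)
  matrix(c(cos(a), 0, -sin(a),
           0, 1, 0,
           sin(a), 0, cos(a)), 3, 3)
}

#' @rdname rot_x
#' @export
rot_z <- function(angle) {
  a <- deg2rad(angle)
  matrix(c(cos(a), sin(a), 0,
           -sin(a), cos(a), 0,
           0, 0, 1), 3, 3)
}

is_rotation_matrix <- function(R, tol = 1e-9) {
  is.matrix(R) && all(dim(R) == c(3L, 3L)) && all(is.finite(R)) &&
    max(abs(crossprod(R) - diag(3))) <= tol && abs(det(R) - 1) <= tol
}

assert_rotation <- function(R, tol = 1e-6) {
  if (!is_rotation_matrix(R, tol)) {
    stop("`R` must be a proper orthonormal 3x3 rotation matrix", call. = FALSE)
  }
  invisible(R)
}

#' Angle triples describing a 3D rotation
#'
#' A `rotation_triple` stores three angular components, in degrees, under one
#' of two conventions: `"euler-XYZ-extrinsic"` (angles \eqn{\alpha, \beta,
#' \gamma} such that \eqn{R = R_z(\gamma) R_y(\beta) R_x(\alpha)} about fixed
#' axes) or `"rotation-vector"` (the matrix logarithm, i.e. axis times angle,
#' scaled to degrees).
#'
#' @param angle_x,angle_y,angle_z Components in degrees.
#' @param convention `"euler-XYZ-extrinsic"` or `"rotation-vector"`.
#' @param gimbal_lock Flag set by [rotation_to_components()] when the Euler
#'   decomposition is degenerate (pitch within numerical reach of +/-90 deg).
#' @return A `rotation_triple` object.
#' @export
rotation_triple <- function(angle_x, angle_y, angle_z,
                            convention = c("euler-XYZ-extrinsic",
                                           "rotation-vector"),
                            gimbal_lock = FALSE) {
  convention <- match.arg(convention)
  ang <- c(angle_x = angle_x, angle_y = angle_y, angle_z = angle_z)
  if (!all(is.finite(ang))) stop("angle components must be finite", call. = FALSE)
  structure(list(angle_x = unname(angle_x), angle_y = unname(angle_y),
                 angle_z = unname(angle_z), convention = convention,
                 gimbal_lock = isTRUE(gimbal_lock)),
            class = "rotation_triple")
}

#' @export
print.rotation_triple <- function(x, ...) {
  cat(sprintf("<rotation_triple [%s]> x=%.4f y=%.4f z=%.4f deg%s\n",
              x$convention, x$angle_x, x$angle_y, x$angle_z,
              if (x$gimbal_lock) " (gimbal lock)" else ""))
  invisible(x)
}

# `as.numeric` dispatches through `as.double`, so the method carries that
# name; a plain helper is used internally.
#' @export
as.double.rotation_triple <- function(x, ...) {
  c(x = x$angle_x, y = x$angle_y, z = x$angle_z)
}

triple_components <- function(x) c(x$angle_x, x$angle_y, x$angle_z)

#' Decompose a rotation matrix into angle components
#'
#' For the `"euler-XYZ-extrinsic"` convention the components \eqn{(\alpha,
#' \beta, \gamma)} satisfy \eqn{R = R_z(\gamma) R_y(\beta) R_x(\alpha)} about
#' the fixed axes. For `"rotation-vector"` the triple is the rotation axis
#' scaled by the rotation angle in degrees. Both round-trip through
#' [components_to_rotation()].
#'
#' When the Euler decomposition hits gimbal lock (\eqn{|\beta|} within 1e-6
#' degrees of 90), only \eqn{\alpha \mp \gamma} is identifiable; the shared
#' angle is assigned to the x-component (\eqn{\gamma = 0}) and the result is
#' flagged.
#'
#' @param R A 3x3 proper rotation matrix.
#' @param convention Output convention.
#' @return A [rotation_triple()].
#' @export
rotation_to_components <- function(R,
                                   convention = c("euler-XYZ-extrinsic",
                                                  "rotation-vector")) {
  convention <- match.arg(convention)
  assert_rotation(R)
  if (convention == "rotation-vector") {
    v <- rotation_log(R)
    return(rotation_triple(v[1], v[2], v[3], "rotation-vector"))
  }
  # R = Rz(g) Ry(b) Rx(a); R[3,1] = -sin(b)
  sb <- -R[3, 1]
  sb <- max(-1, min(1, sb))
  beta <- asin(sb)
  lock_tol <- deg2rad(1e-6)
  if (abs(abs(beta) - pi / 2) < lock_tol) {
    # degenerate: assign the identifiable angle to alpha, gamma = 0
    if (beta > 0) {
      alpha <- atan2(R[1, 2], R[1, 3])
    } else {
      alpha <- atan2(-R[1, 2], -R[1, 3])
    }
    return(rotation_triple(rad2deg(alpha), rad2deg(beta), 0,
                           "euler-XYZ-extrinsic", gimbal_lock = TRUE))
  }
  alpha <- atan2(R[3, 2], R[3, 3])
  gamma <- atan2(R[2, 1], R[1, 1])
  rotation_triple(rad2deg(alpha), rad2deg(beta), rad2deg(gamma),
                  "euler-XYZ-extrinsic")
}

#' Build a rotation matrix from angle components
#'
#' Inverse of [rotation_to_components()] for both conventions.
#'
#' @param triple A [rotation_triple()], or a numeric length-3 vector
#'   interpreted under `convention`.
#' @param convention Used only when `triple` is a bare numeric vector.
#' @return A 3x3 rotation matrix.
#' @export
components_to_rotation <- function(triple,
                                   convention = c("euler-XYZ-extrinsic",
                                                  "rotation-vector")) {
  if (is.numeric(triple) && length(triple) == 3L) {
    convention <- match.arg(convention)
    triple <- rotation_triple(triple[1], triple[2], triple[3], convention)
  }
  stopifnot(inherits(triple, "rotation_triple"))
  if (triple$convention == "euler-XYZ-extrinsic") {
    rot_z(triple$angle_z) %*% rot_y(triple$angle_y) %*% rot_x(triple$angle_x)
  } else {
    rotation_exp(c(triple$angle_x, triple$angle_y, triple$angle_z))
  }
}

# Matrix logarithm of a rotation, returned as axis*angle in degrees.
rotation_log <- function(R) {
  tr <- max(-1, min(3, sum(diag(R))))
  angle <- acos((tr - 1) / 2)
  if (angle < 1e-12) return(c(0, 0, 0))
  if (pi - angle > 1e-6) {
    axis <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
      (2 * sin(angle))
  } else {
    # near pi the skew part vanishes; take the invariant axis (eigenvalue 1)
    e <- eigen(R)
    k <- which.min(abs(e$values - 1))
    axis <- Re(e$vectors[, k])
    axis <- axis / sqrt(sum(axis^2))
    skew <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
    if (sum(abs(skew)) > 1e-12 && sum(axis * skew) < 0) axis <- -axis
  }
  axis * rad2deg(angle)
}

# Rodrigues formula; `v` is axis*angle in degrees.
rotation_exp <- function(v) {
  theta <- sqrt(sum(v^2))
  if (theta < 1e-12) return(diag(3))
  k <- v / theta
  th <- deg2rad(theta)
  K <- matrix(c(0, k[3], -k[2],
                -k[3], 0, k[1],
                k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
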