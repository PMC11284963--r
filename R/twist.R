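#' Virtual twist specification
#'
#' Describes a simulated derotation of the distal femur: nominal angles about
#' the bone-frame X, Y and Z axes, applied with a smooth ramp along the bone.
#' The twist is zero proximal to `ramp_start_fraction` (default 0.40 of the
#' bone length from the distal end), reaches the full nominal angles at
#' `ramp_full_fraction` (default 0.20), and interpolates in between with a
#' C1 cosine profile (or linearly). Because the ramp saturates proximal to
#' the distal assessment section, that section undergoes one exact rigid
#' rotation by the nominal angles.
#'
#' @param angles Length-3 numeric (degrees about bone-frame X, Y, Z) or a
#'   [rotation_triple()] in the Euler convention.
#' @param ramp_start_fraction Axial fraction where the twist begins.
#' @param ramp_full_fraction Axial fraction where the full angle is reached;
#'   must satisfy `0 <= ramp_full < ramp_start <= 1`.
#' @param profile `"cosine"` or `"linear"`.
#' @param pivot Optional fixed rotation pivot; defaults to the long-axis
#'   point at `ramp_start_fraction`.
#' @return A `twist_spec` object.
#' @export
twist_spec <- function(angles, ramp_start_fraction = 0.40,
                       ramp_full_fraction = 0.20,
                       profile = c("cosine", "linear"), pivot = NULL) {
  profile <- match.arg(profile)
  if (inherits(angles, "rotation_triple")) {
    stopifnot(angles$convention == "euler-XYZ-extrinsic")
    angles <- triple_components(angles)
  }
  angles <- as.numeric(angles)
  if (length(angles) != 3L || !all(is.finite(angles))) {
    stop("`angles` must be three finite degrees", call. = FALSE)
  }
  if (!(ramp_full_fraction >= 0 && ramp_full_fraction < ramp_start_fraction &&
        ramp_start_fraction <= 1)) {
    stop("need 0 <= ramp_full_fraction < ramp_start_fraction <= 1",
         call. = FALSE)
  }
  structure(list(angles = angles,
                 ramp_start_fraction = ramp_start_fraction,
                 ramp_full_fraction = ramp_full_fraction,
                 profile = profile,
                 pivot = if (is.null(pivot)) NULL else as.numeric(pivot)),
            class = "twist_spec")
}

#' Twist ramp weight at an axial fraction
#'
#' Weight of the nominal twist angles applied at axial fraction `u`: 0 for
#' `u >= ramp_start_fraction`, 1 for `u <= ramp_full_fraction`, and a
#' monotone non-increasing interpolation in between
#' (`w = (1 + cos(pi (u - full) / (start - full))) / 2` for the cosine
#' profile).
#'
#' @param u Axial fraction(s).
#' @param spec A [twist_spec()].
#' @return Weights in `[0, 1]`.
#' @export
ramp_weight <- function(u, spec) {
  stopifnot(inherits(spec, "twist_spec"))
  lo <- spec$ramp_full_fraction
  hi <- spec$ramp_start_fraction
  w <- numeric(length(u))
  w[u <= lo] <- 1
  mid <- u > lo & u < hi
  if (any(mid)) {
    s <- (u[mid] - lo) / (hi - lo)
    w[mid] <- if (spec$profile == "cosine") (1 + cos(pi * s)) / 2 else 1 - s
  }
  w
}

#' Apply a virtual twist to a bone mesh
#'
#' Rotates each vertex about the fixed pivot by
#' \eqn{R_z(w a_z) R_y(w a_y) R_x(w a_x)} expressed in bone-frame axes, where
#' `w` is the ramp weight of the vertex's pre-twist axial fraction. Vertices
#' proximal to the ramp start are returned bitwise unchanged; vertices at or
#' below the saturation fraction undergo one common rigid rotation by the
#' nominal angles. Faces are unchanged.
#'
#' @param mesh A [surface_mesh()].
#' @param frame The [bone_frame()] supplying axes and axial fractions.
#' @param spec A [twist_spec()].
#' @return The twisted [surface_mesh()].
#' @export
apply_virtual_twist <- function(mesh, frame, spec) {
  validate_mesh(mesh)
  stopifnot(inherits(frame, "bone_frame"), inherits(spec, "twist_spec"))
  u <- axial_fraction(frame, mesh$vertices)
  w <- ramp_weight(u, spec)
  B <- frame_basis(frame)
  d <- frame$proximal_sign * frame$axis_long
  pivot <- if (is.null(spec$pivot)) {
    frame$origin + spec$ramp_start_fraction * frame$length * d
  } else {
    spec$pivot
  }
  v <- mesh$vertices
  out <- v
  if (all(spec$angles == 0)) return(mesh)
  active <- which(w > 0)
  if (length(active)) {
    # group identical weights (grid meshes share rings) to reuse rotations
    uw <- unique(w[active])
    for (wi in uw) {
      rows <- active[w[active] == wi]
      Rw <- B %*% components_to_rotation(wi * spec$angles,
                                         "euler-XYZ-extrinsic") %*% t(B)
      shifted <- sweep(v[rows, , drop = FALSE], 2, pivot)
      out[rows, ] <- sweep(shifted %*% t(Rw), 2, pivot, "+")
    }
  }
  res <- mesh
  res$vertices <- out
  res
}
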