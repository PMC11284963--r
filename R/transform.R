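#' Similarity transform (scale, rotation, translation)
#'
#' Maps a point `v` to `scale * rotation %*% v + translation`. The rotation
#' must be proper orthonormal; the scale strictly positive.
#'
#' @param scale Positive scalar.
#' @param rotation 3x3 proper rotation matrix.
#' @param translation Length-3 numeric vector (mm).
#' @return A `similarity_transform` object.
#' @export
similarity_transform <- function(scale = 1, rotation = diag(3),
                                 translation = c(0, 0, 0)) {
  stopifnot_scalar(scale, "scale", positive = TRUE)
  assert_rotation(rotation, tol = 1e-9)
  translation <- as.numeric(translation)
  if (length(translation) != 3L || !all(is.finite(translation))) {
    stop("`translation` must be a finite length-3 vector", call. = FALSE)
  }
  structure(list(scale = scale, rotation = rotation,
                 translation = translation),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  rv <- rotation_to_components(x$rotation, "rotation-vector")
  cat(sprintf(
    "<similarity_transform> scale %.6g, rotation %.3f deg, translation (%.3f, %.3f, %.3f) mm\n",
    x$scale, sqrt(rv$angle_x^2 + rv$angle_y^2 + rv$angle_z^2),
    x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Identity similarity transform
#' @return A [similarity_transform()] with unit scale, identity rotation and
#'   zero translation.
#' @export
identity_transform <- function() similarity_transform()

#' Apply a similarity transform to a mesh or point matrix
#'
#' @param mesh A [surface_mesh()] (or an n x 3 point matrix for
#'   [transform_points()]).
#' @param transform A [similarity_transform()].
#' @return The transformed mesh (faces unchanged) or point matrix.
#' @export
apply_similarity <- function(mesh, transform) {
  validate_mesh(mesh)
  stopifnot(inherits(transform, "similarity_transform"))
  out <- mesh
  out$vertices <- transform_points(mesh$vertices, transform)
  out
}

#' @rdname apply_similarity
#' @param points n x 3 matrix of points.
#' @export
transform_points <- function(points, transform) {
  t(transform$scale * (transform$rotation %*% t(points)) +
      transform$translation)
}

#' Compose two similarity transforms
#'
#' `compose_similarity(t2, t1)` is the transform that applies `t1` first and
#' then `t2` (function composition order).
#'
#' @param t2,t1 [similarity_transform()] objects.
#' @return The composed [similarity_transform()].
#' @export
compose_similarity <- function(t2, t1) {
  similarity_transform(
    scale = t2$scale * t1$scale,
    rotation = t2$rotation %*% t1$rotation,
    translation = t2$scale * as.vector(t2$rotation %*% t1$translation) +
      t2$translation
  )
}

#' Invert a similarity transform
#' @param transform A [similarity_transform()].
#' @return The inverse [similarity_transform()].
#' @export
invert_similarity <- function(transform) {
  Rt <- t(transform$rotation)
  similarity_transform(
    scale = 1 / transform$scale,
    rotation = Rt,
    translation = -as.vector(Rt %*% transform$translation) / transform$scale
  )
}

#' Draw a random similarity transform
#'
#' Rotation axis uniform on the sphere, rotation angle uniform in
#' `[0, max_angle]` degrees, scale uniform in `scale_range`, translation
#' components uniform in `[-max_translation, max_translation]` mm.
#' Deterministic given `seed`.
#'
#' @param max_angle Maximum rotation angle (degrees).
#' @param scale_range Length-2 range for the uniform scale.
#' @param max_translation Maximum absolute translation per axis (mm).
#' @param seed Integer seed.
#' @return A [similarity_transform()].
#' @export
random_similarity <- function(max_angle = 25, scale_range = c(1, 1),
                              max_translation = 20, seed = 1) {
  with_seed(seed, {
    ax <- rnorm(3)
    ax <- ax / sqrt(sum(ax^2))
    ang <- runif(1, 0, max_angle)
    s <- runif(1, scale_range[1], scale_range[2])
    tr <- runif(3, -max_translation, max_translation)
    similarity_transform(scale = s, rotation = rotation_exp(ax * ang),
                         translation = tr)
  })
}
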