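#' ICP parameter set
#'
#' Free parameters of the iterative-closest-point registration. Defaults:
#' at most 100 iterations, stop when the relative change of the
#' correspondence RMS between successive iterations drops below 1e-7, draw
#' 2000 source vertices (all vertices if fewer), no scale, no trimming.
#'
#' @param max_iterations Maximum number of ICP iterations (>= 1).
#' @param rms_tolerance Relative RMS-change stopping threshold (> 0).
#' @param sample_size Number of source vertices used for correspondences.
#' @param with_scale Estimate a uniform scale (similarity) rather than a
#'   rigid transform.
#' @param trim_fraction Fraction in `[0, 0.5)` of worst correspondences
#'   discarded each iteration.
#' @param correspondence `"surface"` (default) projects each sampled source
#'   vertex onto the closest point of the target triangulated surface;
#'   `"vertex"` matches the nearest target vertex. Vertex matching
#'   quantizes the correspondence to the mesh lattice, which stalls the
#'   azimuthal convergence of tube-like bones at the vertex pitch.
#' @param scale_bounds Length-2 clamp for the scale when `with_scale` is on.
#' @param rot_tolerance,trans_tolerance Stop when the per-iteration update
#'   of the transform falls below these thresholds (degrees of rotation and
#'   mm of translation). Tangential sliding on smooth surfaces makes the
#'   RMS alone a poor convergence signal.
#' @param seed Integer seed for the source vertex subsample.
#' @return An `icp_params` object.
#' @export
icp_params <- function(max_iterations = 200L, rms_tolerance = 1e-7,
                       sample_size = 2000L, with_scale = FALSE,
                       trim_fraction = 0, correspondence = c("surface", "vertex"),
                       scale_bounds = c(0.5, 2),
                       rot_tolerance = 2e-4, trans_tolerance = 2e-5,
                       seed = 1L) {
  correspondence <- match.arg(correspondence)
  if (max_iterations < 1L) stop("`max_iterations` must be >= 1", call. = FALSE)
  if (sample_size < 3L) stop("`sample_size` must be >= 3", call. = FALSE)
  stopifnot_scalar(rms_tolerance, "rms_tolerance", positive = TRUE)
  if (trim_fraction < 0 || trim_fraction >= 0.5) {
    stop("`trim_fraction` must lie in [0, 0.5)", call. = FALSE)
  }
  structure(list(max_iterations = as.integer(max_iterations),
                 rms_tolerance = rms_tolerance,
                 sample_size = as.integer(sample_size),
                 with_scale = isTRUE(with_scale),
                 trim_fraction = trim_fraction,
                 correspondence = correspondence,
                 scale_bounds = scale_bounds,
                 rot_tolerance = rot_tolerance,
                 trans_tolerance = trans_tolerance,
                 seed = as.integer(seed)),
            class = "icp_params")
}

registration_result <- function(transform, rms, iterations, converged,
                                rms_history = numeric()) {
  structure(list(transform = transform, rms = rms,
                 iterations = as.integer(iterations),
                 converged = isTRUE(converged),
                 rms_history = rms_history),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result> rms %.6g mm, %d iterations, %s\n",
              x$rms, x$iterations,
              if (x$converged) "converged" else "not converged"))
  print(x$transform)
  invisible(x)
}

#' Closed-form least-squares similarity fit for paired points
#'
#' Given paired source and target points, returns the similarity (or rigid,
#' when `with_scale = FALSE`) transform minimizing
#' \eqn{\sum_i \| s R p_i + t - q_i \|^2}. The rotation is constrained to be
#' proper (det +1), so reflections are never returned. This is the inner
#' least-squares step of each ICP iteration (SVD of the cross-covariance with
#' a sign-corrected smallest singular direction).
#'
#' @param source_points,target_points Paired n x 3 matrices, n >= 3.
#' @param with_scale Estimate the uniform scale.
#' @param scale_bounds Optional length-2 clamp for the estimated scale;
#'   guards similarity ICP against the shrink-collapse failure mode of
#'   open correspondences.
#' @return A [similarity_transform()].
#' @export
closed_form_fit <- function(source_points, target_points, with_scale = FALSE,
                            scale_bounds = NULL) {
  p <- as.matrix(source_points)
  q <- as.matrix(target_points)
  if (nrow(p) != nrow(q) || ncol(p) != 3L || ncol(q) != 3L || nrow(p) < 3L) {
    stop("need paired n x 3 point matrices with n >= 3", call. = FALSE)
  }
  mu_p <- colMeans(p)
  mu_q <- colMeans(q)
  x <- sweep(p, 2, mu_p)
  y <- sweep(q, 2, mu_q)
  S <- crossprod(y, x) / nrow(p)
  sv <- svd(S)
  if (sv$d[2] <= 1e-12 * max(sv$d[1], 1e-300)) {
    stop("degenerate fit: source points are (near-)collinear", call. = FALSE)
  }
  sgn <- diag(c(1, 1, sign(det(sv$u %*% t(sv$v)))))
  R <- sv$u %*% sgn %*% t(sv$v)
  if (with_scale) {
    var_p <- mean(rowSums(x^2))
    s <- sum(diag(diag(sv$d) %*% sgn)) / var_p
    if (s <= 0) stop("degenerate fit: non-positive scale", call. = FALSE)
    if (!is.null(scale_bounds)) {
      s <- min(max(s, scale_bounds[1]), scale_bounds[2])
    }
  } else {
    s <- 1
  }
  t_ <- mu_q - s * as.vector(R %*% mu_p)
  similarity_transform(scale = s, rotation = R, translation = t_)
}

# Nearest-neighbour indices and distances from each query point into the
# target point set (exact, kd-tree backed).
nearest_points <- function(target_points, query_points) {
  .nn_match(as.matrix(target_points), as.matrix(query_points))
}

# Cached projection index for a target mesh (kd-tree + vertex-face
# adjacency); memoised on the mesh object so repeated registrations against
# the same target rebuild nothing.
surface_index <- function(mesh) {
  cached <- attr(mesh, "surface_index", exact = TRUE)
  if (!is.null(cached)) return(cached)
  .surface_build(mesh$vertices, mesh$faces)
}

#' Attach a cached projection index to a mesh
#'
#' Precomputes the kd-tree and vertex-face adjacency used for point-to-
#' surface correspondences, so that many registrations against the same
#' target (as in the verification/validation harnesses) share one index.
#'
#' @param mesh A [surface_mesh()].
#' @return The mesh with a `surface_index` attribute.
#' @export
index_mesh <- function(mesh) {
  attr(mesh, "surface_index") <- .surface_build(mesh$vertices, mesh$faces)
  mesh
}

# Symmetric nearest-neighbour RMS between two vertex sets, subsampled for
# speed; used to rank prealignment candidates. `trim` drops that fraction of
# the worst pooled distances first: a locally deformed region (e.g. a
# twisted distal segment) is an outlier *block* whose squared distances
# would otherwise outvote an exact fit of the remaining anatomy.
symmetric_rms <- function(a, b, max_points = 1000L, trim = 0) {
  sub <- function(m) {
    if (nrow(m) > max_points) {
      m[round(seq(1, nrow(m), length.out = max_points)), , drop = FALSE]
    } else {
      m
    }
  }
  a_s <- sub(a)
  b_s <- sub(b)
  d1 <- nearest_points(b, a_s)$distance
  d2 <- nearest_points(a, b_s)$distance
  d2all <- c(d1^2, d2^2)
  if (trim > 0) {
    d2all <- sort(d2all)[seq_len(ceiling(length(d2all) * (1 - trim)))]
  }
  sqrt(mean(d2all))
}

# Rotation by `theta` degrees about the line through `point` with unit
# direction `dir`, as a similarity transform.
rotate_about_axis <- function(point, dir, theta) {
  R <- rotation_exp(dir / sqrt(sum(dir^2)) * theta)
  similarity_transform(rotation = R,
                       translation = as.numeric(point) -
                         as.vector(R %*% as.numeric(point)))
}

#' Principal-axis prealignment
#'
#' Coarse alignment of `source` onto `target` by matching their principal
#' axes. The long axes are matched in both orientations, the scale is the
#' ratio of the axial lengths and the translation matches the centroids.
#' Two refinements deal with the ways principal axes mislead on bones: the
#' transverse eigenvectors of an elongated bone are near-degenerate (so the
#' azimuth about the long axis is scanned over the full circle, which
#' subsumes the transverse sign flips of the right-handed axis assignments),
#' and a locally rotated or remodelled region drags the long axis itself by
#' several degrees (so a small tilt grid is scanned on top). Candidates are
#' ranked by trimmed nearest-neighbour RMS — trimming stops a deformed
#' outlier block from outvoting an exact fit of the remaining anatomy — and
#' the winner is returned with its symmetric trimmed RMS.
#'
#' @param source,target [surface_mesh()] objects.
#' @param azimuth_step Azimuthal scan step in degrees.
#' @param tilt_grid Long-axis tilt offsets scanned in degrees.
#' @param trim Fraction of worst distances ignored when ranking candidates.
#' @return A [registration_result()] with `iterations = 0`.
#' @export
prealign <- function(source, target, azimuth_step = 10,
                     tilt_grid = c(-8, 0, 8), trim = 0.35) {
  fs <- principal_frame(source)
  ft <- principal_frame(target)
  As <- cbind(fs$axis_long, fs$axis_2, fs$axis_3)
  At <- cbind(ft$axis_long, ft$axis_2, ft$axis_3)
  cs <- colMeans(source$vertices)
  ct <- colMeans(target$vertices)
  s <- ft$length / fs$length
  ss <- source$vertices
  if (nrow(ss) > 400L) {
    ss <- ss[round(seq(1, nrow(ss), length.out = 400L)), , drop = FALSE]
  }
  cands <- list()
  for (s1 in c(1, -1)) {
    R0 <- At %*% diag(c(s1, 1, s1)) %*% t(As)
    tr0 <- ct - s * as.vector(R0 %*% cs)
    cand0 <- similarity_transform(scale = s, rotation = R0, translation = tr0)
    for (tx in tilt_grid) {
      for (ty in tilt_grid) {
        tilt <- compose_similarity(rotate_about_axis(ct, ft$axis_2, tx),
                                   rotate_about_axis(ct, ft$axis_3, ty))
        for (theta in seq(0, 360 - azimuth_step, by = azimuth_step)) {
          cands[[length(cands) + 1L]] <- compose_similarity(
            tilt,
            compose_similarity(rotate_about_axis(ct, ft$axis_long, theta),
                               cand0))
        }
      }
    }
  }
  # one batched nearest-neighbour pass over all candidates
  q <- do.call(rbind, lapply(cands, function(cand) transform_points(ss, cand)))
  d <- nearest_points(target$vertices, q)$distance
  dm <- matrix(d^2, nrow = nrow(ss))
  keep <- ceiling(nrow(ss) * (1 - trim))
  scores <- apply(dm, 2, function(col) sqrt(mean(sort(col)[seq_len(keep)])))
  best <- cands[[which.min(scores)]]
  rms <- symmetric_rms(transform_points(source$vertices, best),
                       target$vertices, trim = trim)
  res <- registration_result(best, rms, 0L, TRUE)
  # azimuth sector bookkeeping for multi-start coverage
  n_az <- length(seq(0, 360 - azimuth_step, by = azimuth_step))
  az_of <- rep(seq(0, 360 - azimuth_step, by = azimuth_step),
               times = length(cands) / n_az)
  res$candidates <- prealign_pick(cands, scores, az_of)
  res
}

# Pick the best-scoring candidate within each azimuth sector: the refinement
# basin of a tube-like bone is tens of degrees wide in azimuth, so sector
# coverage guarantees one start lands inside the true basin even when the
# coarse scores mis-rank a flat landscape.
prealign_pick <- function(cands, scores, az_of, sector = 45) {
  sec <- floor((az_of %% 360) / sector)
  picked <- list()
  for (sc in sort(unique(sec))) {
    in_sec <- which(sec == sc)
    picked <- c(picked, list(cands[[in_sec[which.min(scores[in_sec])]]]))
  }
  picked
}

#' Iterative closest point registration
#'
#' Point-to-point ICP: each iteration matches a fixed, seeded subsample of
#' source vertices to their nearest target vertices, optionally discards the
#' worst `trim_fraction` of pairs, and refits the cumulative transform with
#' [closed_form_fit()]. Stops when the relative change of the correspondence
#' RMS falls below `rms_tolerance` or after `max_iterations`. With no
#' trimming the recorded RMS sequence is non-increasing. Deterministic for
#' identical inputs and seed.
#'
#' @param source,target [surface_mesh()] objects.
#' @param params An [icp_params()].
#' @param init Optional initial [similarity_transform()] (e.g. from
#'   [prealign()]); defaults to the identity.
#' @return A [registration_result()]; `transform` maps original source
#'   coordinates onto the target.
#' @export
icp <- function(source, target, params = icp_params(), init = NULL) {
  validate_mesh(source)
  validate_mesh(target)
  stopifnot(inherits(params, "icp_params"))
  n <- nrow(source$vertices)
  idx <- if (n > params$sample_size) {
    with_seed(params$seed, sort(sample.int(n, params$sample_size)))
  } else {
    seq_len(n)
  }
  p0 <- source$vertices[idx, , drop = FALSE]
  current <- if (is.null(init)) identity_transform() else init
  tv <- target$vertices
  rms_prev <- Inf
  rms_hist <- numeric(0)
  converged <- FALSE
  iters <- 0L
  n_keep <- max(3L, floor(length(idx) * (1 - params$trim_fraction)))
  surface <- is.null(params$correspondence) ||
    params$correspondence == "surface"
  handle <- if (surface) surface_index(target) else NULL
  for (k in seq_len(params$max_iterations)) {
    iters <- k
    moved <- transform_points(p0, current)
    if (surface) {
      nn <- .surface_query(handle, moved)
    } else {
      nn <- nearest_points(tv, moved)
    }
    ord <- if (n_keep < length(idx)) {
      order(nn$distance)[seq_len(n_keep)]
    } else {
      seq_along(idx)
    }
    d_kept <- nn$distance[ord]
    rms <- sqrt(mean(d_kept^2))
    rms_hist <- c(rms_hist, rms)
    q <- if (surface) {
      nn$point[ord, , drop = FALSE]
    } else {
      tv[nn$index[ord], , drop = FALSE]
    }
    previous <- current
    current <- closed_form_fit(p0[ord, , drop = FALSE], q,
                               with_scale = params$with_scale,
                               scale_bounds = params$scale_bounds)
    rot_step <- sqrt(sum(rotation_log(t(previous$rotation) %*%
                                        current$rotation)^2))
    trans_step <- sqrt(sum((current$translation - previous$translation)^2))
    small_step <- k > 1L && rot_step < params$rot_tolerance &&
      trans_step < params$trans_tolerance
    if (rms < 1e-12 || small_step ||
        (is.finite(rms_prev) &&
         abs(rms_prev - rms) <= params$rms_tolerance * max(rms_prev, 1e-12))) {
      converged <- TRUE
      break
    }
    rms_prev <- rms
  }
  registration_result(current, rms_hist[length(rms_hist)], iters, converged,
                      rms_hist)
}
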