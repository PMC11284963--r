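#' Initial whole-bone alignment
#'
#' Registers the baseline mesh `w0` onto the follow-up mesh `w12` with a
#' similarity transform: principal-axis prealignment followed by ICP with a
#' uniform scale (growth compensation). The returned mesh `w0t` is the
#' transformed baseline ("W0 registered on top of W12"); being a similarity
#' image, it preserves the baseline's shape.
#'
#' @param w0,w12 [surface_mesh()] objects (baseline and follow-up).
#' @param params An [icp_params()]; the scale flag is forced on.
#' @return A list with `w0t` (the aligned mesh) and `result` (the
#'   [registration_result()]).
#' @export
initial_align <- function(w0, w12, params = icp_params()) {
  params$with_scale <- TRUE
  pre <- prealign(w0, w12)
  starts <- pre$candidates
  if (is.null(starts)) starts <- list(pre$transform)
  # the coarse scan cannot rank a flat cost landscape reliably, so run a
  # cheap ICP from one candidate per azimuth sector and refine the best fit
  scout <- params
  scout$sample_size <- min(params$sample_size, 500L)
  scout$max_iterations <- min(params$max_iterations, 40L)
  scouted <- lapply(starts, function(s) icp(w0, w12, params = scout, init = s))
  refine <- params
  refine$sample_size <- min(params$sample_size, 1200L)
  refine$max_iterations <- min(params$max_iterations, 120L)
  # coarse stage: the sections redo the precision work, so a looser step
  # tolerance is its honest convergence level
  refine$rot_tolerance <- max(params$rot_tolerance, 2e-3)
  refine$trans_tolerance <- max(params$trans_tolerance, 2e-4)
  ord <- order(vapply(scouted, function(r) r$rms, numeric(1)))
  res <- NULL
  for (k in ord[seq_len(min(2L, length(ord)))]) {
    r <- icp(w0, w12, params = refine, init = scouted[[k]]$transform)
    if (is.null(res) || r$rms < res$rms) res <- r
  }
  res <- consensus_polish(w0, w12, res, params)
  list(w0t = apply_similarity(w0, res$transform), result = res)
}

# Refit the similarity on consensus correspondences only: each pass projects
# the sample, keeps the best half of the correspondences (on a femur whose
# distal part was derotated, always a subset of the agreeing anatomy) and
# refits scale, rotation and translation on them. Fixed-fraction ICP
# trimming alone still lets a deformed block drag the scale by a few tenths
# of a percent, which would bias the later rigid section fits.
consensus_polish <- function(w0, w12, res, params, passes = 6L) {
  n <- nrow(w0$vertices)
  idx <- if (n > params$sample_size) {
    with_seed(params$seed, sort(sample.int(n, params$sample_size)))
  } else {
    seq_len(n)
  }
  p0 <- w0$vertices[idx, , drop = FALSE]
  handle <- surface_index(w12)
  transform <- res$transform
  rms <- res$rms
  step <- Inf
  for (k in seq_len(passes)) {
    nn <- .surface_query(handle, transform_points(p0, transform))
    keep <- order(nn$distance)[seq_len(floor(length(nn$distance) / 2))]
    if (length(keep) < 100L) break
    previous <- transform
    transform <- closed_form_fit(p0[keep, , drop = FALSE],
                                 nn$point[keep, , drop = FALSE],
                                 with_scale = TRUE)
    step <- sqrt(sum(rotation_log(t(previous$rotation) %*%
                                    transform$rotation)^2))
    rms <- sqrt(mean(nn$distance[keep]^2))
  }
  # the polish is the finishing step of the whole-bone stage: judge
  # convergence by its final update (it plateaus at ~0.02 deg/pass from
  # correspondence-selection churn), not by the capped coarse ICP
  registration_result(transform, rms, res$iterations,
                      res$converged || step < 0.05,
                      res$rms_history)
}

#' Assess the 3D femoral rotation change between two scans
#'
#' The headline pipeline. The baseline mesh is aligned onto the follow-up
#' mesh with a similarity transform (initial alignment), sectioned by its own
#' principal-axis bone frame into a proximal segment (default 40% of the bone
#' length) and a distal segment (default 15% from the distal end), and each
#' section is registered rigidly to the full follow-up mesh. The rotation
#' change is the relative rotation of the distal over the proximal section
#' registration, \eqn{R_D R_P^{-1}}, expressed in the bone frame of the
#' aligned baseline transported by the proximal registration (so components
#' map onto anatomical axes of the un-twisted anatomy). Components are
#' reported as extrinsic XYZ Euler angles and as a rotation vector; a result
#' of (0, 0, 0) degrees means no rotational difference.
#'
#' @param w0,w12 [surface_mesh()] objects at the two time points.
#' @param proximal_fraction,distal_fraction Section fractions in (0, 1) with
#'   sum at most 1; defaults 0.40 and 0.15.
#' @param params An [icp_params()] used for all three registrations (scale is
#'   enabled for the initial alignment and, by default, disabled for the
#'   section registrations).
#' @param section_scale Fit a uniform scale (clamped to [0.9, 1.1]) in the
#'   section registrations (default `TRUE`). The initial alignment resolves
#'   the growth scale only to a few tenths of a percent when part of the
#'   anatomy changed; a rigid section fit of a slightly mis-scaled copy
#'   biases the recovered rotation, while a clamped similarity fit absorbs
#'   the residual.
#' @param initial_trim Trim fraction used only for the initial whole-bone
#'   alignment (default 0.25). A twisted or locally remodelled region acts
#'   as a block of outliers there; trimming lets the alignment lock onto the
#'   consistent majority anatomy instead of splitting the difference. The
#'   measure itself is invariant to how the initial alignment distributes
#'   residual rotation, so this only improves the section starting points.
#' @param proximal_hint Optional length-3 direction overriding the built-in
#'   proximal-end heuristic when the aligned baseline is sectioned.
#' @return A `delta_fr` object; see [tidy.delta_fr()] and
#'   [glance.delta_fr()].
#' @export
assess_delta_fr <- function(w0, w12, proximal_fraction = 0.40,
                            distal_fraction = 0.15, params = icp_params(),
                            section_scale = TRUE, initial_trim = 0.25,
                            proximal_hint = NULL) {
  if (proximal_fraction <= 0 || distal_fraction <= 0 ||
      proximal_fraction + distal_fraction > 1) {
    stop("section fractions must be positive with sum <= 1", call. = FALSE)
  }
  w12 <- index_mesh(w12)
  ini_params <- params
  ini_params$trim_fraction <- max(params$trim_fraction, initial_trim)
  ia <- initial_align(w0, w12, ini_params)
  w0t <- ia$w0t
  frame <- principal_frame(w0t, proximal_hint = proximal_hint)
  prox <- extract_section(w0t, frame, "proximal", proximal_fraction)
  dist <- extract_section(w0t, frame, "distal", distal_fraction)
  warn_if_axisymmetric(prox, "proximal")
  warn_if_axisymmetric(dist, "distal")
  sec_params <- params
  sec_params$with_scale <- isTRUE(section_scale)
  sec_params$scale_bounds <- c(0.9, 1.1)
  sec_params$sample_size <- min(params$sample_size, 900L)
  reg_p <- register_section(prox, w12, frame, sec_params, "proximal",
                            proximal_fraction)
  reg_d <- register_section(dist, w12, frame, sec_params, "distal",
                            distal_fraction)
  r_rel <- reg_d$transform$rotation %*% t(reg_p$transform$rotation)
  # anatomy frame: source bone frame carried along by the proximal fit
  b_anat <- reg_p$transform$rotation %*% frame_basis(frame)
  r_fr <- t(b_anat) %*% r_rel %*% b_anat
  structure(list(rotation_matrix = r_fr,
                 components_euler = rotation_to_components(r_fr,
                                                           "euler-XYZ-extrinsic"),
                 components_rotvec = rotation_to_components(r_fr,
                                                            "rotation-vector"),
                 initial_result = ia$result,
                 proximal_result = reg_p,
                 distal_result = reg_d,
                 frame = frame,
                 fractions = c(proximal = proximal_fraction,
                               distal = distal_fraction)),
            class = "delta_fr")
}

# Register a proximal or distal section of the aligned baseline to the full
# follow-up mesh. A section can sit tens of degrees from its counterpart (a
# derotated distal segment), far outside a single ICP basin, and growth can
# shift its anatomy along the axis, so candidate starts span the
# physiologic search space: rotations expressed in the source bone frame
# (the derotation family, a grid of tilts and azimuths) plus the four
# right-handed principal-axis assignments of the section onto the matching
# end chunk of the target, every candidate translated so the section
# centroid lands on the chunk centroid (which absorbs differential axial
# growth). Candidates are ranked by a batched nearest-neighbour scan, the
# best few well-separated ones are scouted with a short ICP, the best scout
# is refined with the full budget, and a gated vertex-snap polish follows.
register_section <- function(section, target, frame, params, end, fraction,
                             chunk_margin = 0.02,
                             tilt_grid = c(-24, -12, 0, 12, 24),
                             azim_grid = seq(-40, 40, by = 10)) {
  tf <- principal_frame(target)
  # cut the target chunk to the same physical axial extent as the section,
  # so the two pieces are near-congruent and their principal-axis eigenvalue
  # order matches (a fraction of a longer bone can otherwise swap the
  # second and third axes)
  sec_height <- 0.15
  u_sec <- axial_fraction(frame, section$vertices)
  sec_height <- (max(u_sec) - min(u_sec)) * frame$length
  chunk <- extract_section(target, tf, end,
                           min(1, sec_height / tf$length + chunk_margin))
  fs <- principal_frame(section)
  fc <- principal_frame(chunk)
  As <- cbind(fs$axis_long, fs$axis_2, fs$axis_3)
  Ac <- cbind(fc$axis_long, fc$axis_2, fc$axis_3)
  cs <- colMeans(section$vertices)
  cc <- colMeans(chunk$vertices)
  Bf <- frame_basis(frame)
  rots <- list(diag(3))
  # 4 right-handed sign assignments of section axes onto chunk axes, plus
  # the 4 with the transverse axes swapped (covers eigenvalue-order swaps
  # between near-equal transverse spreads)
  p23 <- rbind(c(1, 0, 0), c(0, 0, 1), c(0, 1, 0))
  for (s1 in c(1, -1)) {
    for (s2 in c(1, -1)) {
      rots[[length(rots) + 1L]] <- Ac %*% diag(c(s1, s2, s1 * s2)) %*% t(As)
      rots[[length(rots) + 1L]] <- Ac %*% (p23 %*% diag(c(s1, s2, -s1 * s2))) %*% t(As)
    }
  }
  n_fixed <- length(rots)
  for (a in tilt_grid) {
    for (b in tilt_grid) {
      for (c_ in azim_grid) {
        rots[[length(rots) + 1L]] <- Bf %*%
          components_to_rotation(c(a, b, c_), "euler-XYZ-extrinsic") %*% t(Bf)
      }
    }
  }
  cands <- lapply(rots, function(R) {
    similarity_transform(rotation = R,
                         translation = cc - as.vector(R %*% cs))
  })
  # batched scan of all candidates on a subsample
  v <- section$vertices
  if (nrow(v) > 250L) {
    v <- v[round(seq(1, nrow(v), length.out = 250L)), , drop = FALSE]
  }
  q <- do.call(rbind, lapply(cands, function(tr) transform_points(v, tr)))
  d <- nearest_points(target$vertices, q)$distance
  scores <- sqrt(colMeans(matrix(d^2, nrow = nrow(v))))
  # scout the congruence candidates plus the best-ranked grid candidates;
  # grid picks are mutually separated so they probe distinct basins, but are
  # not suppressed by a nearby congruence candidate (which may itself sit
  # just outside the shared basin)
  picked <- seq_len(n_fixed)
  grid_picked <- integer(0)
  for (k in n_fixed + order(scores[-seq_len(n_fixed)])) {
    if (length(grid_picked) >= 4L) break
    sep <- vapply(grid_picked, function(j) {
      sqrt(sum(rotation_log(t(rots[[j]]) %*% rots[[k]])^2))
    }, numeric(1))
    if (all(sep > 10)) grid_picked <- c(grid_picked, k)
  }
  picked <- c(picked, grid_picked)
  scout <- params
  scout$sample_size <- min(params$sample_size, 400L)
  scout$max_iterations <- min(params$max_iterations, 30L)
  scouted <- lapply(picked, function(k) {
    icp(section, target, params = scout, init = cands[[k]])
  })
  srms <- vapply(scouted, function(r) r$rms, numeric(1))
  best <- NULL
  for (k in order(srms)[seq_len(min(2L, length(srms)))]) {
    res <- icp(section, target, params = params,
               init = scouted[[k]]$transform)
    if (is.null(best) || res$rms < best$rms) best <- res
  }
  # vertex-snap polish: when the two meshes share vertex layout (same-mesh
  # comparisons), nearest-vertex correspondences from a sub-pitch start are
  # exact and the fit snaps to machine precision; on independently meshed
  # targets the snap does not lower the surface RMS and is discarded
  pol_params <- params
  pol_params$correspondence <- "vertex"
  pol_params$max_iterations <- 30L
  polished <- icp(section, target, params = pol_params,
                  init = best$transform)
  handle <- surface_index(target)
  sub <- section$vertices
  if (nrow(sub) > 500L) {
    sub <- sub[round(seq(1, nrow(sub), length.out = 500L)), , drop = FALSE]
  }
  srms <- function(tr) {
    sqrt(mean(.surface_query(handle, transform_points(sub, tr))$distance^2))
  }
  if (srms(polished$transform) <= srms(best$transform)) {
    polished$rms <- srms(polished$transform)
    best <- polished
  }
  best
}

# Near-axisymmetric sections make the long-axis rotation ill-conditioned.
warn_if_axisymmetric <- function(section, label, tol = 0.05) {
  f <- tryCatch(principal_frame(section), error = function(e) NULL)
  if (is.null(f)) return(invisible(NULL))
  x <- sweep(section$vertices, 2, colMeans(section$vertices))
  ev <- eigen(crossprod(x) / nrow(x), symmetric = TRUE)$values
  if (abs(ev[2] - ev[3]) < tol * ev[2]) {
    warning(sprintf(
      "%s section is nearly axisymmetric (transverse eigenvalues within %.0f%%); long-axis rotation may be ill-conditioned",
      label, 100 * tol), call. = FALSE)
  }
  invisible(NULL)
}

#' @export
print.delta_fr <- function(x, ...) {
  e <- x$components_euler
  r <- x$components_rotvec
  cat("<delta_fr> 3D rotation of distal vs proximal femoral section\n")
  cat(sprintf("  Euler XYZ (extrinsic): x %.3f  y %.3f  z %.3f deg\n",
              e$angle_x, e$angle_y, e$angle_z))
  cat(sprintf("  rotation vector:       x %.3f  y %.3f  z %.3f deg\n",
              r$angle_x, r$angle_y, r$angle_z))
  cat(sprintf("  registration rms (mm): initial %.4g, proximal %.4g, distal %.4g\n",
              x$initial_result$rms, x$proximal_result$rms,
              x$distal_result$rms))
  invisible(x)
}

#' Tidy a fitted rotation change
#'
#' One row per axis and convention, with the angle in degrees.
#'
#' @param x A `delta_fr` object.
#' @param ... Unused.
#' @return A tibble with columns `convention`, `axis`, `angle_deg`.
#' @method tidy delta_fr
#' @export
tidy.delta_fr <- function(x, ...) {
  tibble::tibble(
    convention = rep(c("euler-XYZ-extrinsic", "rotation-vector"), each = 3L),
    axis = rep(c("x", "y", "z"), 2L),
    angle_deg = c(triple_components(x$components_euler),
                  triple_components(x$components_rotvec))
  )
}

#' Glance at a fitted rotation change
#'
#' @param x A `delta_fr` object.
#' @param ... Unused.
#' @return A one-row tibble with registration diagnostics.
#' @method glance delta_fr
#' @export
glance.delta_fr <- function(x, ...) {
  tibble::tibble(
    initial_rms = x$initial_result$rms,
    initial_scale = x$initial_result$transform$scale,
    proximal_rms = x$proximal_result$rms,
    distal_rms = x$distal_result$rms,
    iterations = x$initial_result$iterations +
      x$proximal_result$iterations + x$distal_result$iterations,
    converged = x$initial_result$converged && x$proximal_result$converged &&
      x$distal_result$converged
  )
}

#' Correct a twisted rotation change for growth effects
#'
#' Removes the baseline (untwisted) rotation change from the one measured
#' after a virtual twist. The default `"compose"` mode decomposes
#' \eqn{R_{twisted} R_{baseline}^{-1}}; the `"subtract"` mode subtracts the
#' Euler components axis by axis. The two agree for commuting (same-axis)
#' rotations and differ slightly otherwise.
#'
#' @param delta_twisted,delta_baseline `delta_fr` objects measured with and
#'   without the virtual twist, expressed in the same bone frame.
#' @param mode `"compose"` or `"subtract"`.
#' @return A [rotation_triple()] in the Euler convention.
#' @export
growth_correct <- function(delta_twisted, delta_baseline,
                           mode = c("compose", "subtract")) {
  mode <- match.arg(mode)
  stopifnot(inherits(delta_twisted, "delta_fr"),
            inherits(delta_baseline, "delta_fr"))
  if (delta_twisted$components_euler$convention !=
      delta_baseline$components_euler$convention) {
    stop("convention mismatch between the two rotation changes",
         call. = FALSE)
  }
  if (mode == "compose") {
    R <- delta_twisted$rotation_matrix %*% t(delta_baseline$rotation_matrix)
    rotation_to_components(R, "euler-XYZ-extrinsic")
  } else {
    a <- delta_twisted$components_euler
    b <- delta_baseline$components_euler
    rotation_triple(a$angle_x - b$angle_x, a$angle_y - b$angle_y,
                    a$angle_z - b$angle_z, "euler-XYZ-extrinsic")
  }
}
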