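#' Parameters of the synthetic immature femur
#'
#' Stylized geometry of a growing (porcine-like) femur used in place of CT
#' segmentations: an elongated, slightly bowed shaft tube with an offset
#' head/neck, a greater-trochanter bump and a bicondylar distal end. All
#' lengths in millimetres. The defaults describe a roughly three-month-old
#' animal (shaft 140 mm). The shape has no rotational symmetry about the
#' long axis, which is what makes long-axis rotation observable.
#'
#' @param shaft_length Total bone length (mm).
#' @param shaft_radius Mid-shaft radius (mm).
#' @param curvature Sagittal bow amplitude (mm).
#' @param head_radius Femoral head radius (mm).
#' @param neck_length Neck length (mm).
#' @param neck_angle Neck-shaft angle in degrees (135 = typical valgus).
#' @param anteversion Anteversion of the neck in degrees (rotation of the
#'   neck direction about the long axis).
#' @param condyle_radius Condylar lobe radius (mm).
#' @param condyle_separation Distance between the two condylar lobes (mm).
#' @param trochanter_bump Greater-trochanter bump height (mm).
#' @param mesh_resolution Target vertex count (>= 500).
#' @param noise_sd Gaussian surface noise along vertex normals (mm);
#'   0.1 mm is sub-voxel for 0.8 mm CT slices.
#' @param seed Integer seed; generation is deterministic per seed.
#' @return A `bone_params` object (a named list).
#' @export
bone_params <- function(shaft_length = 140, shaft_radius = 12, curvature = 6,
                        head_radius = 14, neck_length = 18, neck_angle = 135,
                        anteversion = 20, condyle_radius = 13,
                        condyle_separation = 22, trochanter_bump = 8,
                        mesh_resolution = 4000, noise_sd = 0.1, seed = 1L) {
  p <- list(shaft_length = shaft_length, shaft_radius = shaft_radius,
            curvature = curvature, head_radius = head_radius,
            neck_length = neck_length, neck_angle = neck_angle,
            anteversion = anteversion, condyle_radius = condyle_radius,
            condyle_separation = condyle_separation,
            trochanter_bump = trochanter_bump,
            mesh_resolution = as.integer(mesh_resolution),
            noise_sd = noise_sd, seed = as.integer(seed))
  lin <- c("shaft_length", "shaft_radius", "head_radius", "neck_length",
           "condyle_radius", "condyle_separation", "trochanter_bump")
  if (any(unlist(p[lin]) <= 0)) stop("all lengths must be > 0", call. = FALSE)
  if (p$mesh_resolution < 500L) {
    stop("`mesh_resolution` must be >= 500", call. = FALSE)
  }
  structure(p, class = "bone_params")
}

#' Parameters of 12-week growth between two scans
#'
#' Emulates the interval between a baseline and a 12-week follow-up scan of a
#' rapidly growing animal whose body weight roughly doubles: a uniform size
#' increase, extra axial elongation, a natural change of femoral torsion, a
#' small relative perturbation of the radii (shape drift), fresh surface
#' noise and — by default — an independent re-meshing so the two scans share
#' no vertex correspondence (as two independent CT segmentations would not).
#'
#' @param scale Uniform linear scale factor (>= 1); 1.35 gives a volume
#'   ratio of about 2.7, matching a doubling of body weight.
#' @param elongation_extra Additional axial stretch applied to the shaft
#'   length only.
#' @param natural_torsion Degrees of distal-over-proximal long-axis rotation
#'   accrued over the interval; `NULL` (default) draws one value per subject
#'   from N(mean 3, sd 2).
#' @param shape_jitter Relative standard deviation of per-parameter radius
#'   perturbations.
#' @param remesh Re-mesh the follow-up bone independently (default `TRUE`).
#' @param seed Integer seed.
#' @return A `growth_params` object.
#' @export
growth_params <- function(scale = 1.35, elongation_extra = 1.08,
                          natural_torsion = NULL, shape_jitter = 0.03,
                          remesh = TRUE, seed = 1L) {
  if (scale < 1) stop("`scale` must be >= 1", call. = FALSE)
  structure(list(scale = scale, elongation_extra = elongation_extra,
                 natural_torsion = natural_torsion,
                 shape_jitter = shape_jitter, remesh = isTRUE(remesh),
                 seed = as.integer(seed)),
            class = "growth_params")
}

# wrapped angular distance
ang_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

# Core parametric construction: rings of vertices along a bowed long axis
# with a direction- and height-dependent radius, closed by two pole caps.
# `theta_phase` rotates the sampling grid (not the shape) for re-meshing.
build_femur_mesh <- function(p, theta_phase = 0) {
  L <- p$shaft_length
  n_theta <- max(24L, as.integer(round(sqrt(p$mesh_resolution / 3))))
  n_u <- max(30L, as.integer(round((p$mesh_resolution - 2) / n_theta)))
  u <- (seq_len(n_u) - 0.5) / n_u
  theta <- 2 * pi * ((seq_len(n_theta) - 1) / n_theta + theta_phase)
  U <- rep(u, each = n_theta)
  TH <- rep(theta, times = n_u)

  # radius field: shaft + metaphyseal flares + ellipticity + feature bumps
  r <- p$shaft_radius * (1 + 0.30 * exp(-((1 - U) / 0.12)^2) +
                           0.22 * exp(-(U / 0.12)^2) +
                           0.06 * cos(2 * (TH - 0.4)))
  th_head <- pi / 2 + deg2rad(p$anteversion)
  tilt <- deg2rad(p$neck_angle - 90)
  u_head <- 1 - (p$neck_length * cos(tilt)) / L
  amp_head <- p$neck_length * sin(tilt) + p$head_radius - p$shaft_radius
  r <- r + amp_head * exp(-((U - u_head) / 0.07)^2) *
    exp(-(ang_diff(TH, th_head) / 0.9)^2)
  th_troch <- th_head + pi
  r <- r + p$trochanter_bump * exp(-((U - 0.96) / 0.05)^2) *
    exp(-(ang_diff(TH, th_troch) / 0.8)^2)
  delta <- atan2(p$condyle_separation / 2,
                 p$shaft_radius + 0.5 * p$condyle_radius)
  amp_con <- 0.65 * p$condyle_radius
  for (thc in c(-pi / 2 - delta, -pi / 2 + delta)) {
    r <- r + amp_con * exp(-((U - 0.045) / 0.05)^2) *
      exp(-(ang_diff(TH, thc) / 0.38)^2)
  }
  # rounded end caps
  u_cap <- 0.035
  taper <- rep(1, length(U))
  lo <- U < u_cap
  taper[lo] <- sqrt(pmax(0, 1 - ((u_cap - U[lo]) / u_cap)^2))
  hi <- U > 1 - u_cap
  taper[hi] <- sqrt(pmax(0, 1 - ((U[hi] - (1 - u_cap)) / u_cap)^2))
  r <- r * taper
  if (any(r <= 0.05 * p$shaft_radius)) {
    stop("generation error: resolution/parameters collapse the surface",
         call. = FALSE)
  }

  bow <- p$curvature * sin(pi * U)
  verts <- cbind(bow + r * cos(TH), r * sin(TH), U * L)
  poles <- rbind(c(0, 0, 0), c(0, 0, L))
  verts <- rbind(verts, poles)
  i_bot <- nrow(verts) - 1L
  i_top <- nrow(verts)

  vid <- function(i, j) (i - 1L) * n_theta + ((j - 1L) %% n_theta) + 1L
  ii <- rep(seq_len(n_u - 1L), each = n_theta)
  jj <- rep(seq_len(n_theta), times = n_u - 1L)
  f1 <- cbind(vid(ii, jj), vid(ii, jj + 1L), vid(ii + 1L, jj + 1L))
  f2 <- cbind(vid(ii, jj), vid(ii + 1L, jj + 1L), vid(ii + 1L, jj))
  jjs <- seq_len(n_theta)
  fan_bot <- cbind(rep(i_bot, n_theta), vid(1L, jjs + 1L), vid(1L, jjs))
  fan_top <- cbind(rep(i_top, n_theta), vid(n_u, jjs), vid(n_u, jjs + 1L))
  mesh <- surface_mesh(verts, rbind(f1, f2, fan_bot, fan_top))
  if (mesh_volume(mesh) < 0) mesh$faces <- mesh$faces[, c(1L, 3L, 2L)]
  mesh
}

#' Generate a synthetic immature femur
#'
#' Builds a watertight triangulated femur-like surface from [bone_params()]
#' and returns it with its ground-truth bone frame (long axis +z, distal tip
#' at the origin, proximal sign +1). Deterministic per seed.
#'
#' @param params A [bone_params()].
#' @return A list with `mesh` ([surface_mesh()]) and `frame`
#'   ([bone_frame()]).
#' @export
generate_femur <- function(params = bone_params()) {
  stopifnot(inherits(params, "bone_params"))
  mesh <- build_femur_mesh(params)
  if (params$noise_sd > 0) {
    nrm <- vertex_normals(mesh)
    disp <- with_seed(params$seed, rnorm(nrow(mesh$vertices), 0,
                                         params$noise_sd))
    mesh$vertices <- mesh$vertices + disp * nrm
  }
  frame <- bone_frame(origin = c(0, 0, 0), axis_long = c(0, 0, 1),
                      axis_2 = c(1, 0, 0), axis_3 = c(0, 1, 0),
                      length = params$shaft_length, proximal_sign = 1)
  list(mesh = mesh, frame = frame)
}

# Scale every linear parameter of a bone by `s` (shape-preserving).
scale_bone_params <- function(p, s) {
  lin <- c("shaft_length", "shaft_radius", "curvature", "head_radius",
           "neck_length", "condyle_radius", "condyle_separation",
           "trochanter_bump")
  for (nm in lin) p[[nm]] <- p[[nm]] * s
  p
}

#' Grow a synthetic femur over the scan interval
#'
#' Regenerates the bone at grown dimensions (uniform scale plus extra axial
#' elongation), perturbs the radii by the shape jitter, applies the natural
#' torsion through the virtual-twist ramp about the long axis, re-meshes
#' independently (when `remesh = TRUE`) and adds fresh surface noise.
#'
#' @param params The baseline [bone_params()].
#' @param growth A [growth_params()].
#' @return A list with `mesh`, `frame` and `torsion` (the applied natural
#'   torsion as a [rotation_triple()], the ground truth for validation).
#' @export
grow_femur <- function(params = bone_params(), growth = growth_params()) {
  stopifnot(inherits(params, "bone_params"), inherits(growth, "growth_params"))
  p2 <- scale_bone_params(params, growth$scale)
  p2$shaft_length <- p2$shaft_length * growth$elongation_extra
  jit <- with_seed(derive_seed(growth$seed, 1L), rnorm(6))
  if (growth$shape_jitter > 0) {
    jn <- c("shaft_radius", "head_radius", "neck_length", "condyle_radius",
            "condyle_separation", "trochanter_bump")
    for (k in seq_along(jn)) {
      p2[[jn[k]]] <- p2[[jn[k]]] * (1 + growth$shape_jitter * jit[k])
    }
  }
  torsion <- growth$natural_torsion
  if (is.null(torsion)) {
    torsion <- with_seed(derive_seed(growth$seed, 2L), rnorm(1, 3, 2))
  }
  if (growth$remesh) {
    p2$mesh_resolution <- as.integer(round(p2$mesh_resolution * 1.21))
    phase <- 0.37
  } else {
    phase <- 0
  }
  mesh <- build_femur_mesh(p2, theta_phase = phase)
  frame <- bone_frame(origin = c(0, 0, 0), axis_long = c(0, 0, 1),
                      axis_2 = c(1, 0, 0), axis_3 = c(0, 1, 0),
                      length = p2$shaft_length, proximal_sign = 1)
  if (torsion != 0) {
    mesh <- apply_virtual_twist(mesh, frame,
                                twist_spec(c(0, 0, torsion)))
  }
  if (p2$noise_sd > 0) {
    nrm <- vertex_normals(mesh)
    disp <- with_seed(derive_seed(growth$seed, 3L),
                      rnorm(nrow(mesh$vertices), 0, p2$noise_sd))
    mesh$vertices <- mesh$vertices + disp * nrm
  }
  list(mesh = mesh, frame = frame,
       torsion = rotation_triple(0, 0, torsion, "euler-XYZ-extrinsic"))
}

#' Generate a cohort of growing synthetic femurs
#'
#' Emulates a study cohort: `n` subjects, each with a baseline (W0) and a
#' grown 12-week (W12) mesh, with per-subject jitter of up to +/-10% on the
#' base radii and lengths and per-subject seeds derived from `master_seed`.
#' Fully deterministic.
#'
#' @param n Number of subjects (>= 1).
#' @param master_seed Integer master seed.
#' @param params Baseline [bone_params()] template.
#' @param growth [growth_params()] template.
#' @return A tibble with one row per subject: `subject`, list-columns `w0`,
#'   `w12`, `frame0`, `frame12`, and the ground-truth `torsion_z` (degrees).
#' @export
generate_cohort <- function(n, master_seed = 1L, params = bone_params(),
                            growth = growth_params()) {
  stopifnot(n >= 1)
  rows <- lapply(seq_len(n), function(i) {
    jseed <- derive_seed(master_seed, i)
    jit <- with_seed(jseed, runif(8, -0.1, 0.1))
    p_i <- params
    jn <- c("shaft_length", "shaft_radius", "head_radius", "neck_length",
            "condyle_radius", "condyle_separation", "trochanter_bump",
            "curvature")
    for (k in seq_along(jn)) p_i[[jn[k]]] <- p_i[[jn[k]]] * (1 + jit[k])
    p_i$seed <- derive_seed(master_seed, 100L + i)
    g_i <- growth
    g_i$seed <- derive_seed(master_seed, 200L + i)
    w0 <- generate_femur(p_i)
    w12 <- grow_femur(p_i, g_i)
    tz <- w12$torsion$angle_z
    tibble::tibble(subject = sprintf("S%02d", i),
                   w0 = list(w0$mesh), w12 = list(w12$mesh),
                   frame0 = list(w0$frame), frame12 = list(w12$frame),
                   torsion_z = tz,
                   params = list(p_i))
  })
  dplyr::bind_rows(rows)
}
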