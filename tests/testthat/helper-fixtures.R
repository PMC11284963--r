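# Fixtures are built in code; nothing is read from disk.

# Axis-aligned box mesh (8 vertices, 12 outward-oriented triangles),
# centred at the origin.
box_mesh <- function(lx = 100, ly = 20, lz = 20) {
  v <- as.matrix(expand.grid(x = c(-1, 1) * lx / 2,
                             y = c(-1, 1) * ly / 2,
                             z = c(-1, 1) * lz / 2))
  f <- rbind(
    c(1, 3, 4), c(1, 4, 2),   # z = -lz/2
    c(5, 6, 8), c(5, 8, 7),   # z = +lz/2
    c(1, 2, 6), c(1, 6, 5),   # y = -ly/2
    c(3, 7, 8), c(3, 8, 4),   # y = +ly/2
    c(1, 5, 7), c(1, 7, 3),   # x = -lx/2
    c(2, 4, 8), c(2, 8, 6)    # x = +lx/2
  )
  m <- surface_mesh(v, f)
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

# Open cylinder of `n_rings` evenly spaced vertex rings along +z.
cylinder_mesh <- function(n_rings = 100, n_theta = 12, radius = 10,
                          length = 100) {
  z <- seq(0, length, length.out = n_rings)
  th <- 2 * pi * (seq_len(n_theta) - 1) / n_theta
  v <- cbind(radius * cos(rep(th, n_rings)),
             radius * sin(rep(th, n_rings)),
             rep(z, each = n_theta))
  vid <- function(i, j) (i - 1L) * n_theta + ((j - 1L) %% n_theta) + 1L
  ii <- rep(seq_len(n_rings - 1L), each = n_theta)
  jj <- rep(seq_len(n_theta), times = n_rings - 1L)
  f <- rbind(cbind(vid(ii, jj), vid(ii, jj + 1L), vid(ii + 1L, jj + 1L)),
             cbind(vid(ii, jj), vid(ii + 1L, jj + 1L), vid(ii + 1L, jj)))
  surface_mesh(v, f)
}

# Small synthetic femur shared across tests (cached per resolution/seed).
test_femur <- local({
  cache <- list()
  function(resolution = 1200, seed = 42, noise_sd = 0.1) {
    key <- paste(resolution, seed, noise_sd)
    if (is.null(cache[[key]])) {
      cache[[key]] <<- generate_femur(bone_params(
        mesh_resolution = resolution, seed = seed, noise_sd = noise_sd))
    }
    cache[[key]]
  }
})

# Independent matrix exponential of a rotation vector (degrees) by power
# series; oracle for the Rodrigues-based implementation.
series_expm_rotvec <- function(v, terms = 40) {
  th <- v * pi / 180
  K <- matrix(c(0, th[3], -th[2],
                -th[3], 0, th[1],
                th[2], -th[1], 0), 3, 3)
  out <- diag(3)
  term <- diag(3)
  for (k in seq_len(terms)) {
    term <- term %*% K / k
    out <- out + term
  }
  out
}

# Geodesic angle (degrees) between two rotations.
rotation_angle_between <- function(R1, R2) {
  tr <- sum(diag(t(R1) %*% R2))
  acos(max(-1, min(1, (tr - 1) / 2))) * 180 / pi
}

euler_vec <- function(fit) {
  e <- fit$components_euler
  c(e$angle_x, e$angle_y, e$angle_z)
}
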