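test_that("generation is deterministic per seed", {
  a <- generate_femur(bone_params(mesh_resolution = 800, seed = 3))
  b <- generate_femur(bone_params(mesh_resolution = 800, seed = 3))
  expect_identical(a$mesh$vertices, b$mesh$vertices)
  expect_identical(a$mesh$faces, b$mesh$faces)
  c_ <- generate_femur(bone_params(mesh_resolution = 800, seed = 4))
  expect_false(identical(a$mesh$vertices, c_$mesh$vertices))
})

test_that("generated bones are watertight with sphere topology", {
  for (seed in c(1, 8)) {
    fem <- generate_femur(bone_params(mesh_resolution = 900, seed = seed))
    expect_true(is_watertight(fem$mesh))
    expect_equal(euler_characteristic(fem$mesh), 2L)
    expect_gt(mesh_volume(fem$mesh), 0)
  }
  grown <- grow_femur(bone_params(mesh_resolution = 900, seed = 1),
                      growth_params(seed = 2))
  expect_true(is_watertight(grown$mesh))
  expect_equal(euler_characteristic(grown$mesh), 2L)
})

test_that("long-axis rotation is identifiable (no rotational symmetry)", {
  fem <- test_femur(1000)
  d <- fem$frame$proximal_sign * fem$frame$axis_long
  rot <- apply_similarity(fem$mesh,
                          similarity_transform(rotation = rotation_exp(d * 10)))
  res <- icp(fem$mesh, rot, icp_params(), init = prealign(fem$mesh, rot)$transform)
  expect_lt(rotation_angle_between(res$transform$rotation, rotation_exp(d * 10)),
            0.1)
  # and the displacement it causes clearly exceeds the noise floor
  nn <- deltafr:::nearest_points(rot$vertices, fem$mesh$vertices)
  expect_gt(sqrt(mean(nn$distance^2)), 5 * 0.1)
})

test_that("null growth is a pure similarity and yields a null rotation change", {
  p <- bone_params(mesh_resolution = 1500, noise_sd = 0, seed = 5)
  w0 <- generate_femur(p)
  g <- growth_params(scale = 1.3, elongation_extra = 1, natural_torsion = 0,
                     shape_jitter = 0, remesh = FALSE, seed = 1)
  w12 <- grow_femur(p, g)
  expect_lt(max(abs(w12$mesh$vertices - 1.3 * w0$mesh$vertices)), 1e-9)
  fit <- assess_delta_fr(w0$mesh, w12$mesh)
  expect_lt(max(abs(euler_vec(fit))), 0.1)
})

test_that("growth hits the expected length and volume ratio", {
  p <- bone_params(mesh_resolution = 900, seed = 2)
  g <- growth_params(seed = 3)
  w0 <- generate_femur(p)
  w12 <- grow_femur(p, g)
  len <- function(m) diff(range(m$vertices[, 3]))
  expect_equal(len(w12$mesh), p$shaft_length * g$scale * g$elongation_extra,
               tolerance = 0.02)
  ratio <- mesh_volume(w12$mesh) / mesh_volume(w0$mesh)
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 3.2)
})

test_that("a known natural torsion is recovered by the assessment", {
  p <- bone_params(mesh_resolution = 2500, seed = 7)
  w0 <- generate_femur(p)
  w12 <- grow_femur(p, growth_params(natural_torsion = 4, seed = 3))
  fit <- assess_delta_fr(w0$mesh, w12$mesh)
  expect_lt(abs(euler_vec(fit)[3] - 4), 0.7)
})

test_that("cohorts are reproducible with recorded ground truth", {
  co1 <- generate_cohort(3, master_seed = 11,
                         params = bone_params(mesh_resolution = 700))
  co2 <- generate_cohort(3, master_seed = 11,
                         params = bone_params(mesh_resolution = 700))
  expect_equal(nrow(co1), 3L)
  expect_identical(co1$w0[[2]]$vertices, co2$w0[[2]]$vertices)
  expect_identical(co1$torsion_z, co2$torsion_z)
  expect_true(all(is.finite(co1$torsion_z)))
  # distinct subjects
  expect_false(identical(co1$w0[[1]]$vertices, co1$w0[[2]]$vertices))
  for (i in 1:3) {
    expect_true(is_watertight(co1$w0[[i]]))
    expect_true(is_watertight(co1$w12[[i]]))
  }
})
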