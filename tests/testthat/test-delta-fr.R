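# minimal delta_fr stub for the pure matrix arithmetic of growth_correct
fake_delta <- function(R) {
  structure(list(rotation_matrix = R,
                 components_euler = rotation_to_components(R),
                 components_rotvec = rotation_to_components(R,
                                                            "rotation-vector")),
            class = "delta_fr")
}

test_that("self-comparison yields a null rotation change", {
  fem <- test_femur(1500)$mesh
  fit <- assess_delta_fr(fem, fem)
  expect_lt(max(abs(euler_vec(fit))), 0.05)
})

test_that("a long-axis virtual twist is detected on the twisted axis only", {
  fem <- test_femur(2000)$mesh
  f <- principal_frame(fem)
  tw <- apply_virtual_twist(fem, f, twist_spec(c(0, 0, 10)))
  fit <- assess_delta_fr(fem, tw)
  e <- euler_vec(fit)
  expect_lt(abs(e[3] - 10), 0.5)
  expect_lt(max(abs(e[1:2])), 0.5)
})

test_that("whole-bone similarity motions cancel (null invariance)", {
  fem <- test_femur(1500)$mesh
  tr <- random_similarity(20, c(1.1, 1.4), 25, seed = 21)
  fit <- assess_delta_fr(fem, apply_similarity(fem, tr))
  expect_lt(max(abs(euler_vec(fit))), 0.1)
})

test_that("re-posing both scans together leaves the components unchanged", {
  fem <- test_femur(1500)$mesh
  f <- principal_frame(fem)
  tw <- apply_virtual_twist(fem, f, twist_spec(c(0, 0, 8)))
  base <- euler_vec(assess_delta_fr(fem, tw))
  pose <- random_similarity(45, c(1, 1), 30, seed = 33)
  moved <- euler_vec(assess_delta_fr(apply_similarity(fem, pose),
                                     apply_similarity(tw, pose)))
  expect_lt(max(abs(moved - base)), 0.1)
})

test_that("swapping the two scans negates the measured twist", {
  fem <- test_femur(1500)$mesh
  f <- principal_frame(fem)
  tw <- apply_virtual_twist(fem, f, twist_spec(c(0, 0, 10)))
  fwd <- euler_vec(assess_delta_fr(fem, tw))
  bwd <- euler_vec(assess_delta_fr(tw, fem))
  expect_lt(max(abs(fwd + bwd)), 0.2)
})

test_that("growth correction composes and subtracts as documented", {
  tw15 <- fake_delta(rot_z(15) %*% rot_z(3))
  b3 <- fake_delta(rot_z(3))
  corr <- growth_correct(tw15, b3, mode = "compose")
  expect_equal(c(corr$angle_x, corr$angle_y, corr$angle_z), c(0, 0, 15),
               tolerance = 1e-6)
  sub <- growth_correct(tw15, b3, mode = "subtract")
  expect_equal(sub$angle_z, 15, tolerance = 1e-6)

  # identity baseline returns the twisted components unchanged
  tw <- fake_delta(rot_z(9) %*% rot_y(2))
  idb <- fake_delta(diag(3))
  corr_id <- growth_correct(tw, idb)
  expect_equal(c(corr_id$angle_x, corr_id$angle_y, corr_id$angle_z),
               euler_vec(list(components_euler = tw$components_euler)),
               tolerance = 1e-9)

  # small non-commuting case against direct matrix arithmetic
  base <- fake_delta(rot_x(3))
  twisted <- fake_delta(rot_z(10) %*% rot_x(3))
  comp <- growth_correct(twisted, base, mode = "compose")
  expect_equal(c(comp$angle_x, comp$angle_y, comp$angle_z), c(0, 0, 10),
               tolerance = 1e-6)
  sub2 <- growth_correct(twisted, base, mode = "subtract")
  expect_lt(max(abs(c(sub2$angle_x, sub2$angle_y, sub2$angle_z) -
                      c(0, 0, 10))), 0.2)
})

test_that("tidy and glance expose components and diagnostics", {
  fem <- test_femur(1500)$mesh
  fit <- assess_delta_fr(fem, fem)
  td <- tidy(fit)
  expect_equal(nrow(td), 6L)
  expect_setequal(unique(td$convention),
                  c("euler-XYZ-extrinsic", "rotation-vector"))
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_lt(gl$proximal_rms, 0.05)
  expect_equal(gl$initial_scale, 1, tolerance = 1e-3)
})

test_that("fraction validation and section defaults are enforced", {
  fem <- test_femur(800)$mesh
  expect_error(assess_delta_fr(fem, fem, proximal_fraction = 0.7,
                               distal_fraction = 0.4), "sum")
  expect_error(assess_delta_fr(fem, fem, proximal_fraction = 0), "positive")
})
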