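default_spec <- function(angles = c(0, 0, 10)) twist_spec(angles)

test_that("ramp weights hit the stated anchor values and are monotone", {
  sp <- default_spec()
  expect_equal(ramp_weight(0.40, sp), 0)
  expect_equal(ramp_weight(0.20, sp), 1)
  expect_equal(ramp_weight(0.30, sp), 0.5, tolerance = 1e-12)
  u <- seq(0, 1, by = 0.001)
  expect_true(all(diff(ramp_weight(u, sp)) <= 1e-12))
  lin <- twist_spec(c(0, 0, 10), profile = "linear")
  expect_equal(ramp_weight(0.30, lin), 0.5, tolerance = 1e-12)
  expect_error(twist_spec(c(0, 0, 5), ramp_start_fraction = 0.2,
                          ramp_full_fraction = 0.4), "ramp")
})

test_that("zero twist is the bitwise identity", {
  fem <- test_femur(1000)
  out <- apply_virtual_twist(fem$mesh, fem$frame, twist_spec(c(0, 0, 0)))
  expect_identical(out$vertices, fem$mesh$vertices)
})

test_that("vertices proximal to the ramp start are bitwise unchanged", {
  fem <- test_femur(1000)
  sp <- twist_spec(c(5, 5, 5))
  out <- apply_virtual_twist(fem$mesh, fem$frame, sp)
  u <- axial_fraction(fem$frame, fem$mesh$vertices)
  prox <- u >= sp$ramp_start_fraction
  expect_true(any(prox))
  expect_identical(out$vertices[prox, ], fem$mesh$vertices[prox, ])
})

test_that("long-axis twists compose additively in the same frame", {
  fem <- test_femur(1000)
  a <- apply_virtual_twist(fem$mesh, fem$frame, twist_spec(c(0, 0, 4)))
  ab <- apply_virtual_twist(a, fem$frame, twist_spec(c(0, 0, 6)))
  direct <- apply_virtual_twist(fem$mesh, fem$frame, twist_spec(c(0, 0, 10)))
  expect_lt(max(abs(ab$vertices - direct$vertices)), 1e-9)
})

test_that("the saturated distal zone is one exact rigid rotation", {
  fem <- test_femur(1000)
  sp <- twist_spec(c(5, 5, 5))
  out <- apply_virtual_twist(fem$mesh, fem$frame, sp)
  u <- axial_fraction(fem$frame, fem$mesh$vertices)
  zone <- u <= sp$ramp_full_fraction
  expect_gt(sum(zone), 30)
  fit <- closed_form_fit(fem$mesh$vertices[zone, ], out$vertices[zone, ])
  resid <- transform_points(fem$mesh$vertices[zone, ], fit) -
    out$vertices[zone, ]
  expect_lt(max(abs(resid)), 1e-9)
  # decompose in the bone frame: components equal the nominal angles
  B <- deltafr:::frame_basis(fem$frame)
  comp <- rotation_to_components(t(B) %*% fit$rotation %*% B)
  expect_equal(c(comp$angle_x, comp$angle_y, comp$angle_z), c(5, 5, 5),
               tolerance = 1e-9)
})

test_that("a pure long-axis twist matches the per-vertex closed form", {
  fem <- test_femur(1000)
  sp <- twist_spec(c(0, 0, 10))
  out <- apply_virtual_twist(fem$mesh, fem$frame, sp)
  u <- axial_fraction(fem$frame, fem$mesh$vertices)
  zone <- which(u <= 0.1)
  d <- fem$frame$proximal_sign * fem$frame$axis_long
  pivot <- fem$frame$origin + 0.4 * fem$frame$length * d
  R <- rotation_exp(d * 10)
  expected <- sweep(sweep(fem$mesh$vertices[zone, , drop = FALSE], 2, pivot) %*%
                      t(R), 2, pivot, "+")
  expect_lt(max(abs(out$vertices[zone, ] - expected)), 1e-9)
})

test_that("the displacement field is continuous along the bone axis", {
  fem <- test_femur(2000, noise_sd = 0)
  sp <- twist_spec(c(10, 10, 10))
  out <- apply_virtual_twist(fem$mesh, fem$frame, sp)
  disp <- sqrt(rowSums((out$vertices - fem$mesh$vertices)^2))
  u <- axial_fraction(fem$frame, fem$mesh$vertices)
  # mean displacement per vertex ring varies smoothly from ring to ring
  ring <- round(u, 6)
  ring_mean <- tapply(disp, ring, mean)
  ring_mean <- ring_mean[order(as.numeric(names(ring_mean)))]
  # a tear would jump by the order of the full displacement; the smooth
  # ramp changes ring displacement by far less between adjacent rings
  expect_lt(max(abs(diff(ring_mean))), 0.15 * max(disp))
})
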