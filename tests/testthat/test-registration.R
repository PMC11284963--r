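test_that("closed-form fit recovers a constructed similarity exactly", {
  set.seed(11)
  p <- matrix(rnorm(60, sd = 20), ncol = 3)
  expect_equal(closed_form_fit(p, p)$scale, 1)
  expect_lt(max(abs(closed_form_fit(p, p)$rotation - diag(3))), 1e-12)

  tr <- similarity_transform(scale = 1.5, rotation = rot_z(20),
                             translation = c(3, 4, 5))
  q <- transform_points(p, tr)
  fit <- closed_form_fit(p, q, with_scale = TRUE)
  expect_equal(fit$scale, 1.5, tolerance = 1e-9)
  expect_lt(max(abs(fit$rotation - rot_z(20))), 1e-9)
  expect_equal(fit$translation, c(3, 4, 5), tolerance = 1e-9)
})

test_that("reflections are never returned (det stays +1)", {
  set.seed(2)
  p <- matrix(rnorm(45, sd = 10), ncol = 3)
  q <- p
  q[, 1] <- -q[, 1]
  fit <- closed_form_fit(p, q)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  resid <- sqrt(mean(rowSums((transform_points(p, fit) - q)^2)))
  expect_gt(resid, 0.1)
})

test_that("collinear point sets raise a degenerate-fit error", {
  p <- cbind(1:10, 2 * (1:10), -1 * (1:10))
  expect_error(closed_form_fit(p, p), "collinear")
})

test_that("prealignment undoes a 180-degree long-axis flip and a scaling", {
  fem <- test_femur(1000)$mesh
  f <- principal_frame(fem)
  flip <- rot_about <- rotation_exp(f$axis_long * 180)
  flipped <- apply_similarity(fem, similarity_transform(rotation = flip))
  pre <- prealign(flipped, fem)
  res <- icp(flipped, fem, icp_params(), init = pre$transform)
  expect_lt(rotation_angle_between(res$transform$rotation, t(flip)), 0.1)

  scaled <- apply_similarity(fem, similarity_transform(scale = 1.4))
  pre2 <- prealign(fem, scaled)
  expect_lt(abs(pre2$transform$scale - 1.4) / 1.4, 0.05)
})

test_that("self-registration is the identity and scaled copies are resolved", {
  fem <- test_femur(1000)$mesh
  res <- icp(fem, fem, icp_params())
  expect_lt(res$rms, 1e-6)
  expect_lt(rotation_angle_between(res$transform$rotation, diag(3)), 1e-6)

  tw <- apply_similarity(fem, similarity_transform(rotation = rot_z(10)))
  pre <- prealign(fem, tw)
  res2 <- icp(fem, tw, icp_params(), init = pre$transform)
  expect_lt(rotation_angle_between(res2$transform$rotation, rot_z(10)), 0.1)

  sc <- apply_similarity(fem, similarity_transform(scale = 1.5))
  res3 <- icp(fem, sc, icp_params(with_scale = TRUE),
              init = prealign(fem, sc)$transform)
  expect_lt(abs(res3$transform$scale - 1.5) / 1.5, 0.001)
})

test_that("correspondence RMS is non-increasing without trimming", {
  fem <- test_femur(1000)$mesh
  tgt <- apply_similarity(fem, random_similarity(15, c(1, 1), 10, seed = 3))
  res <- icp(fem, tgt, icp_params(trim_fraction = 0))
  expect_true(all(diff(res$rms_history) <= 1e-9))
})

test_that("registration is deterministic for identical inputs and seed", {
  fem <- test_femur(1000)$mesh
  tgt <- apply_similarity(fem, random_similarity(20, c(1, 1), 15, seed = 9))
  r1 <- icp(fem, tgt, icp_params(seed = 4), init = prealign(fem, tgt)$transform)
  r2 <- icp(fem, tgt, icp_params(seed = 4), init = prealign(fem, tgt)$transform)
  expect_identical(r1$transform, r2$transform)
  expect_identical(r1$rms_history, r2$rms_history)
})

test_that("any initial rigid pose is recovered by prealign + ICP", {
  fem <- test_femur(1000)$mesh
  for (k in 1:6) {
    tr <- random_similarity(25, c(0.8, 1.6), 25, seed = 200 + k)
    tgt <- apply_similarity(fem, tr)
    pre <- prealign(fem, tgt)
    res <- icp(fem, tgt, icp_params(with_scale = TRUE), init = pre$transform)
    expect_lt(rotation_angle_between(res$transform$rotation, tr$rotation), 0.1)
    expect_lt(abs(res$transform$scale - tr$scale) / tr$scale, 0.001)
    expect_lt(max(abs(res$transform$translation - tr$translation)), 0.1)
  }
})
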