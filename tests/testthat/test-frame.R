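test_that("principal frame of an elongated box recovers the analytic axes", {
  m <- box_mesh(100, 20, 20)
  f <- principal_frame(m)
  expect_equal(abs(f$axis_long), c(1, 0, 0), tolerance = 1e-9)
  expect_equal(f$length, 100, tolerance = 1e-9)
  # after a known rotation the long axis follows (up to sign)
  R <- rot_z(30) %*% rot_x(20)
  m2 <- apply_similarity(m, similarity_transform(rotation = R))
  f2 <- principal_frame(m2)
  expect_lt(min(sum((f2$axis_long - R[, 1])^2),
                sum((f2$axis_long + R[, 1])^2)), 1e-12)
})

test_that("frame is equivariant under rigid motions of a femur", {
  fem <- test_femur(1000)
  f0 <- principal_frame(fem$mesh)
  for (k in 1:5) {
    tr <- random_similarity(60, c(1, 1), 40, seed = k)
    f1 <- principal_frame(apply_similarity(fem$mesh, tr))
    expect_lt(max(abs(f1$axis_long - as.vector(tr$rotation %*% f0$axis_long))),
              1e-6)
    expect_lt(max(abs(f1$axis_2 - as.vector(tr$rotation %*% f0$axis_2))),
              1e-6)
    expect_equal(f1$proximal_sign, f0$proximal_sign)
  }
})

test_that("the proximal end is identified from the head/trochanter offset", {
  for (seed in c(1, 5, 9)) {
    fem <- test_femur(1000, seed = seed)
    f <- principal_frame(fem$mesh)
    d <- f$proximal_sign * f$axis_long
    truth <- fem$frame$proximal_sign * fem$frame$axis_long
    expect_gt(sum(d * truth), 0.9)
  }
})

test_that("axial fractions are linear from distal (0) to proximal (1)", {
  f <- bone_frame(origin = c(0, 0, 0), axis_long = c(0, 0, 1),
                  axis_2 = c(1, 0, 0), axis_3 = c(0, 1, 0),
                  length = 100, proximal_sign = 1)
  expect_equal(axial_fraction(f, c(0, 0, 0)), 0)
  expect_equal(axial_fraction(f, c(3, -2, 100)), 1)
  expect_equal(axial_fraction(f, c(0, 0, 15)), 0.15)
  expect_equal(axial_fraction(f, c(0, 0, -10)), -0.1)
})

test_that("sectioning keeps exactly the faces inside the fraction", {
  cyl <- cylinder_mesh(n_rings = 100, n_theta = 12, length = 100)
  f <- principal_frame(cyl, proximal_hint = c(0, 0, 1))
  whole <- extract_section(cyl, f, "proximal", 1.0)
  expect_equal(n_faces(whole), n_faces(cyl))

  dist <- extract_section(cyl, f, "distal", 0.15)
  # brute-force per-vertex filter: rings live at u = (i-1)/99
  u <- axial_fraction(f, cyl$vertices)
  ok <- u <= 0.15
  keep <- ok[cyl$faces[, 1]] & ok[cyl$faces[, 2]] & ok[cyl$faces[, 3]]
  expect_equal(n_faces(dist), sum(keep))
  expect_equal(n_vertices(dist), length(unique(as.vector(cyl$faces[keep, ]))))
  expect_lte(max(axial_fraction(f, dist$vertices)), 0.15 + 1e-12)
})

test_that("proximal and distal sections are disjoint when fractions sum <= 1", {
  fem <- test_femur(1000)$mesh
  f <- principal_frame(fem)
  for (fr in list(c(0.40, 0.15), c(0.5, 0.5), c(0.3, 0.6))) {
    p <- extract_section(fem, f, "proximal", fr[1])
    d <- extract_section(fem, f, "distal", fr[2])
    key <- function(v) paste(round(v[, 1], 9), round(v[, 2], 9),
                             round(v[, 3], 9))
    expect_length(intersect(key(p$vertices), key(d$vertices)), 0)
  }
})

test_that("degenerate geometry and empty sections raise errors", {
  flat <- surface_mesh(cbind(c(0, 1, 0, 1), c(0, 0, 1, 1), 0),
                       rbind(c(1L, 2L, 3L), c(2L, 4L, 3L)))
  expect_error(principal_frame(flat), "degenerate")
  cyl <- cylinder_mesh(n_rings = 10, length = 100)
  f <- principal_frame(cyl, proximal_hint = c(0, 0, 1))
  expect_error(extract_section(cyl, f, "distal", 0.001), "empty section")
  expect_error(extract_section(cyl, f, "distal", 0), "fraction")
})
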