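fake_records <- function(detected, true = rep(10, length(detected))) {
  tibble::tibble(
    protocol = "verification",
    subject_w0 = sprintf("S%02d", seq_along(detected)),
    subject_w12 = sprintf("S%02d", seq_along(detected)),
    same_subject = TRUE,
    angle = true,
    true_x = true, true_y = 0, true_z = 0,
    detected_x = detected, detected_y = 0, detected_z = 0
  )
}

test_that("normalized detection is 100 * detected / true, NA at zero truth", {
  rec <- normalized_detection(fake_records(c(5.13, 5, 9.5),
                                           true = c(5, 5, 10)))
  expect_equal(rec$normalized_x, c(102.6, 100, 95))
  expect_true(all(is.na(rec$normalized_y)))
  long <- records_long(rec)
  expect_equal(nrow(long), 3L)  # zero-truth axes dropped
})

test_that("summary statistics match hand computation", {
  rec <- normalized_detection(fake_records(c(9.0, 10.0, 11.0)))
  s <- summarize_records(rec)
  expect_equal(s$mean_normalized_pct, 100)
  expect_equal(s$sd_normalized_pct, 10)
  expect_equal(s$cov_pct, 10)
  expect_equal(s$detection_error_pct, 0)
  expect_equal(s$mean_absolute_error_pct, 20 / 3, tolerance = 1e-12)

  const <- normalized_detection(fake_records(c(10, 10, 10)))
  sc <- summarize_records(const)
  expect_equal(sc$detection_error_pct, 0)
  expect_equal(sc$mean_absolute_error_pct, 0)
  expect_equal(sc$cov_pct, 0)

  expect_error(summarize_records(fake_records(5)), "fewer than 2")
})

test_that("the coefficient of variance uses the sample sd over the mean", {
  expect_equal(coefficient_of_variance(c(90, 100, 110)), 10)
  expect_error(coefficient_of_variance(1), "at least 2")
})

test_that("Bland-Altman limits are mean +/- 1.96 sample sd", {
  ba0 <- bland_altman(c(5, 10, 15), c(5, 10, 15))
  expect_equal(unlist(ba0[c("mean_diff", "loa_low", "loa_high")]),
               c(mean_diff = 0, loa_low = 0, loa_high = 0))
  ba <- bland_altman(c(10, 10, 10), c(11, 10, 9))
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$loa_low, -1.96)
  expect_equal(ba$loa_high, 1.96)
  bar <- bland_altman(c(10, 20), c(9, 18), relative = TRUE)
  expect_equal(bar$mean_diff, 10)
  expect_error(bland_altman(1, 1), "n >= 2")
})

test_that("summaries agree with a brute-force recomputation from records", {
  co <- generate_cohort(2, master_seed = 6,
                        params = bone_params(mesh_resolution = 700))
  cheap <- icp_params(max_iterations = 25, sample_size = 300)
  rec <- run_verification(co, angles = c(5, 10), params = cheap)
  long <- records_long(rec)
  s <- summarize_records(rec)
  # independent arithmetic straight from the long table
  norm <- 100 * long$detected / long$true
  expect_equal(s$mean_normalized_pct, mean(norm))
  expect_equal(s$sd_normalized_pct, sd(norm))
  expect_equal(s$mean_absolute_error_pct, mean(abs(norm - 100)))
  expect_equal(s$cov_pct, 100 * sd(norm) / mean(norm))
  ba <- bland_altman(long$true, long$detected)
  d <- long$true - long$detected
  expect_equal(ba$mean_diff, mean(d))
  expect_equal(ba$loa_high, mean(d) + 1.96 * sd(d))
})

test_that("harness design counts and baseline reuse hold on a tiny cohort", {
  co <- generate_cohort(2, master_seed = 4,
                        params = bone_params(mesh_resolution = 700))
  cheap <- icp_params(max_iterations = 25, sample_size = 300)
  rec_v <- run_verification(co, angles = 10, params = cheap)
  expect_equal(nrow(rec_v), 2L)          # n_subjects x n_angles
  expect_true(all(rec_v$same_subject))

  rec <- run_validation(co, angles = c(5, 10), params = cheap)
  expect_equal(nrow(rec), 2 * 2 * 2)     # n^2 x n_angles
  expect_equal(sum(rec$same_subject), 4L)
  # the untwisted baseline is computed once per pair and shared across angles
  key <- paste(rec$subject_w0, rec$subject_w12)
  for (k in unique(key)) {
    expect_equal(length(unique(rec$baseline_z[key == k])), 1L)
  }
})

test_that("single-axis mode produces one record per axis with matched truth", {
  co <- generate_cohort(1, master_seed = 9,
                        params = bone_params(mesh_resolution = 700))
  cheap <- icp_params(max_iterations = 25, sample_size = 300)
  rec <- run_verification(co, angles = 10, params = cheap, axes = "single")
  expect_equal(nrow(rec), 3L)
  truth <- rbind(c(10, 0, 0), c(0, 10, 0), c(0, 0, 10))
  expect_equal(as.matrix(rec[, c("true_x", "true_y", "true_z")]),
               truth, ignore_attr = TRUE)
  long <- records_long(rec)
  expect_equal(nrow(long), 3L)  # only the twisted axis carries a truth
})

test_that("near-axisymmetric sections trigger a conditioning warning", {
  cyl <- cylinder_mesh(n_rings = 40, n_theta = 16, radius = 10, length = 100)
  expect_warning(deltafr:::warn_if_axisymmetric(cyl, "distal"),
                 "axisymmetric")
})

test_that("plot builders return ggplot objects", {
  rec <- normalized_detection(fake_records(c(9.6, 10.2, 10.1, 9.9)))
  expect_s3_class(plot_detection(rec), "ggplot")
  expect_s3_class(plot_bland_altman(rec), "ggplot")
  expect_s3_class(plot_normalized(rec), "ggplot")
})
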