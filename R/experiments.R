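#' Run the verification protocol
#'
#' Twist-recovery on the same bone: for each follow-up (W12) mesh and each
#' nominal angle `a`, a virtual twist is applied (simultaneously about all
#' three bone-frame axes by default, `(a, a, a)`) and the rotation change
#' between the untwisted and twisted mesh is assessed. A perfect method
#' detects exactly the nominal angles.
#'
#' @param cohort A cohort tibble from [generate_cohort()] (uses the `w12`
#'   list-column and `subject`), or a bare list of [surface_mesh()] objects.
#' @param angles Nominal twist angles in degrees; default `c(5, 10, 15, 20)`.
#' @param params An [icp_params()].
#' @param axes `"triaxial"` applies `(a, a, a)` in one twist; `"single"`
#'   applies each angle about one axis at a time (three records per angle).
#' @return A tibble of experiment records, one row per trial, with true,
#'   detected and normalized per-axis columns plus registration diagnostics.
#' @export
run_verification <- function(cohort, angles = c(5, 10, 15, 20),
                             params = icp_params(),
                             axes = c("triaxial", "single")) {
  axes <- match.arg(axes)
  if (any(angles <= 0)) stop("`angles` must be positive", call. = FALSE)
  meshes <- cohort_meshes(cohort, "w12")
  rows <- list()
  for (s in seq_along(meshes$mesh)) {
    w12 <- meshes$mesh[[s]]
    frame <- principal_frame(w12)
    for (a in angles) {
      specs <- if (axes == "triaxial") {
        list(c(a, a, a))
      } else {
        list(c(a, 0, 0), c(0, a, 0), c(0, 0, a))
      }
      for (tr in specs) {
        twisted <- apply_virtual_twist(w12, frame, twist_spec(tr))
        fit <- assess_delta_fr(w12, twisted, params = params)
        det <- triple_components(fit$components_euler)
        g <- glance(fit)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          protocol = "verification",
          subject_w0 = meshes$id[s], subject_w12 = meshes$id[s],
          same_subject = TRUE, angle = a,
          true_x = tr[1], true_y = tr[2], true_z = tr[3],
          detected_x = det[1], detected_y = det[2], detected_z = det[3],
          initial_rms = g$initial_rms, proximal_rms = g$proximal_rms,
          distal_rms = g$distal_rms, converged = g$converged
        )
      }
    }
  }
  normalized_detection(dplyr::bind_rows(rows))
}

#' Run the validation protocol
#'
#' Cross-time-point, cross-subject twist recovery with growth correction:
#' for every ordered pair (baseline W0 of subject i, follow-up W12 of
#' subject j) the untwisted rotation change is measured once (the growth
#' baseline, shared across angles), then for each nominal angle the W12 mesh
#' is virtually twisted and the twisted rotation change is corrected for the
#' baseline. With `n` subjects and `k` angles this executes
#' `n * n * k` registration experiments.
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @param angles Nominal twist angles in degrees.
#' @param params An [icp_params()].
#' @param axes `"triaxial"` (default) or `"single"`; see
#'   [run_verification()].
#' @param correction `"compose"` (default) or `"subtract"`, passed to
#'   [growth_correct()]; the other mode is reported alongside.
#' @return A tibble of experiment records with baseline, detected (growth
#'   corrected) and normalized per-axis columns.
#' @export
run_validation <- function(cohort, angles = c(5, 10, 15, 20),
                           params = icp_params(),
                           axes = c("triaxial", "single"),
                           correction = c("compose", "subtract")) {
  axes <- match.arg(axes)
  correction <- match.arg(correction)
  if (any(angles <= 0)) stop("`angles` must be positive", call. = FALSE)
  w0s <- cohort_meshes(cohort, "w0")
  w12s <- cohort_meshes(cohort, "w12")
  rows <- list()
  for (i in seq_along(w0s$mesh)) {
    for (j in seq_along(w12s$mesh)) {
      w0 <- w0s$mesh[[i]]
      w12 <- w12s$mesh[[j]]
      frame <- principal_frame(w12)
      baseline <- assess_delta_fr(w0, w12, params = params)
      base <- triple_components(baseline$components_euler)
      for (a in angles) {
        specs <- if (axes == "triaxial") {
          list(c(a, a, a))
        } else {
          list(c(a, 0, 0), c(0, a, 0), c(0, 0, a))
        }
        for (tr in specs) {
          twisted_mesh <- apply_virtual_twist(w12, frame, twist_spec(tr))
          fit <- assess_delta_fr(w0, twisted_mesh, params = params)
          corr <- growth_correct(fit, baseline, mode = correction)
          alt <- growth_correct(fit, baseline,
                                mode = setdiff(c("compose", "subtract"),
                                               correction))
          det <- triple_components(corr)
          alt_det <- triple_components(alt)
          g <- glance(fit)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            protocol = "validation",
            subject_w0 = w0s$id[i], subject_w12 = w12s$id[j],
            same_subject = w0s$id[i] == w12s$id[j], angle = a,
            true_x = tr[1], true_y = tr[2], true_z = tr[3],
            detected_x = det[1], detected_y = det[2], detected_z = det[3],
            alt_detected_x = alt_det[1], alt_detected_y = alt_det[2],
            alt_detected_z = alt_det[3],
            baseline_x = base[1], baseline_y = base[2], baseline_z = base[3],
            initial_rms = g$initial_rms, proximal_rms = g$proximal_rms,
            distal_rms = g$distal_rms, converged = g$converged
          )
        }
      }
    }
  }
  normalized_detection(dplyr::bind_rows(rows))
}

cohort_meshes <- function(cohort, which) {
  if (is.data.frame(cohort)) {
    list(mesh = cohort[[which]], id = cohort$subject)
  } else {
    list(mesh = cohort, id = sprintf("S%02d", seq_along(cohort)))
  }
}

#' Normalized detection percentages
#'
#' Adds (or recomputes) the per-axis normalized detection,
#' `100 * detected / true`, leaving `NA` on axes whose true angle is zero.
#'
#' @param records A records tibble from [run_verification()] or
#'   [run_validation()].
#' @return The records tibble with `normalized_x/y/z` columns.
#' @export
normalized_detection <- function(records) {
  for (ax in c("x", "y", "z")) {
    tru <- records[[paste0("true_", ax)]]
    det <- records[[paste0("detected_", ax)]]
    records[[paste0("normalized_", ax)]] <-
      ifelse(tru != 0, 100 * det / tru, NA_real_)
  }
  records
}

#' Long form of an experiment-records tibble
#'
#' One row per record and axis, keeping only axes with a non-zero true
#' angle.
#'
#' @param records A records tibble.
#' @return A tibble with columns `protocol`, `subject_w0`, `subject_w12`,
#'   `same_subject`, `angle`, `axis`, `true`, `detected`, `normalized`.
#' @export
records_long <- function(records) {
  out <- lapply(c("x", "y", "z"), function(ax) {
    tibble::tibble(
      protocol = records$protocol,
      subject_w0 = records$subject_w0,
      subject_w12 = records$subject_w12,
      same_subject = records$same_subject,
      angle = records$angle,
      axis = ax,
      true = records[[paste0("true_", ax)]],
      detected = records[[paste0("detected_", ax)]],
      normalized = records[[paste0("normalized_", ax)]]
    )
  })
  dplyr::filter(dplyr::bind_rows(out), .data$true != 0)
}

#' Summary metrics of detection accuracy
#'
#' For each group, computes the mean and sample standard deviation of the
#' normalized detected angles (percent of truth), the detection error
#' (absolute difference between the mean normalized angle and 100%), the
#' mean absolute error `mean(|normalized - 100|)` with its sample sd, and
#' the coefficient of variance `100 * sd / mean` of the normalized angles.
#' Sample (n-1) standard deviations are used throughout.
#'
#' @param records A records tibble.
#' @param group_by Character vector of grouping keys among `"protocol"`,
#'   `"axis"`, `"angle"`; `NULL` pools everything.
#' @return A tibble of `metrics_summary` rows.
#' @export
summarize_records <- function(records, group_by = NULL) {
  if (is.null(records[["normalized_x"]])) {
    records <- normalized_detection(records)
  }
  long <- records_long(records)
  if (!is.null(group_by)) {
    bad <- setdiff(group_by, c("protocol", "axis", "angle"))
    if (length(bad)) stop("unknown grouping keys: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    long <- dplyr::group_by(long, dplyr::across(dplyr::all_of(group_by)))
  }
  counts <- dplyr::summarise(long, n = dplyr::n(), .groups = "drop")
  if (any(counts$n < 2L)) {
    stop("sd undefined: a summary group has fewer than 2 records",
         call. = FALSE)
  }
  out <- dplyr::summarise(
    long,
    n = dplyr::n(),
    mean_normalized_pct = mean(.data$normalized),
    sd_normalized_pct = stats::sd(.data$normalized),
    detection_error_pct = abs(mean(.data$normalized) - 100),
    mean_absolute_error_pct = mean(abs(.data$normalized - 100)),
    sd_absolute_error_pct = stats::sd(abs(.data$normalized - 100)),
    cov_pct = coefficient_of_variance(.data$normalized),
    mean_detected = mean(.data$detected),
    sd_detected = stats::sd(.data$detected),
    mean_signed_error_deg = mean(.data$detected - .data$true),
    .groups = "drop"
  )
  if (any(out$n < 2L)) {
    stop("sd undefined: a summary group has fewer than 2 records",
         call. = FALSE)
  }
  out
}

#' Coefficient of variance (percent)
#'
#' `100 * sd(x) / mean(x)` with the sample (n-1) standard deviation.
#'
#' @param x Numeric vector (n >= 2).
#' @return Percent dispersion around the mean.
#' @export
coefficient_of_variance <- function(x) {
  if (length(x) < 2L) stop("need at least 2 values", call. = FALSE)
  100 * stats::sd(x) / mean(x)
}

#' Bland-Altman agreement statistics
#'
#' Differences are `true - detected` (or `100 * (true - detected) / true`
#' when `relative = TRUE`); limits of agreement are the mean difference
#' +/- 1.96 sample standard deviations.
#'
#' @param true_values,detected_values Equal-length paired vectors, n >= 2.
#' @param relative Use relative (percent-of-true) differences.
#' @return A one-row tibble: `mean_diff`, `loa_low`, `loa_high`, `sd_diff`,
#'   `n`.
#' @export
bland_altman <- function(true_values, detected_values, relative = FALSE) {
  if (length(true_values) != length(detected_values) ||
      length(true_values) < 2L) {
    stop("need equal-length paired vectors with n >= 2", call. = FALSE)
  }
  d <- if (relative) {
    100 * (true_values - detected_values) / true_values
  } else {
    true_values - detected_values
  }
  m <- mean(d)
  s <- stats::sd(d)
  tibble::tibble(mean_diff = m, loa_low = m - 1.96 * s,
                 loa_high = m + 1.96 * s, sd_diff = s,
                 n = length(d))
}
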