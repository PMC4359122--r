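.hum2 <- generate_default_humanoid(1.80, 90.3)
.scan2 <- sample_surface(.hum2, n_points = 2000, seed = 202)

test_that("the pro-rata factor closes random mass budgets to machine precision", {
  expect_equal(scaling_factor(80, c(30, 30, 20)), 1)
  expect_equal(scaling_factor(73.4, c(40, 25, 15)), 73.4 / 80)
  set.seed(12)
  for (k in 1:50) {
    m <- runif(14, 0.2, 30)
    s <- scaling_factor(70, m)
    expect_lt(abs(sum(m * s) - 70) / 70, 1e-12)
  }
  expect_error(scaling_factor(70, c(1, -2, 3)))
  expect_error(scaling_factor(0, c(1, 2)))
})

test_that("subdividing a straight cylinder is volume-neutral", {
  cl <- sample_surface(primitive_spec("cylinder", list(r = 0.05, length = 0.4)),
                       n_points = 8000, seed = 33)
  whole <- validate_mesh(convex_hull(cl))$signed_volume
  parts <- subdivide_along_axis(cl, fractions = 0.5, axis = "z")
  expect_length(parts, 2L)
  vols <- vapply(parts, function(p)
    validate_mesh(convex_hull(p))$signed_volume, 0)
  expect_lt(rel_err(sum(vols), whole), 0.01)
  # quartering partitions the cloud
  q <- subdivide_along_axis(cl, n_parts = 4, axis = "z")
  expect_length(q, 4L)
  expect_equal(sum(vapply(q, function(p) nrow(p$points), 0L)), nrow(cl$points))
  # a part receiving no volume-spanning points errors, naming the part
  sparse <- point_cloud(rbind(matrix(runif(12, 0, 0.05), ncol = 3),
                              matrix(runif(12, 0.95, 1), ncol = 3)), "seg")
  err <- tryCatch(subdivide_along_axis(sparse, n_parts = 5, axis = "z"),
                  error = function(e) e)
  expect_s3_class(err, "bodyhull_insufficient_points")
  expect_match(conditionMessage(err), "part 2")
})

test_that("subdividing a bent cylinder reduces hull overestimation towards truth", {
  bc <- primitive_spec("bent_cylinder",
                       list(r = 0.04, length = 0.4, bend_angle = pi / 3))
  truth <- bent_cylinder_grid_properties(0.04, 0.4, pi / 3, resolution = 0.002)
  cl <- sample_surface(bc, n_points = 8000, seed = 44)
  v_ch <- validate_mesh(convex_hull(cl))$signed_volume
  parts <- subdivide_along_axis(cl, fractions = 0.5, axis = "z")
  v_chd <- sum(vapply(parts, function(p)
    validate_mesh(convex_hull(p))$signed_volume, 0))
  expect_gt(v_ch, v_chd)            # subdivision strictly helps
  expect_gte(v_chd, truth$volume * 0.995)  # but hulls never undercut truth
  ov <- overestimation_report(truth$volume, list(CH = v_ch, CHD = v_chd))
  expect_gt(ov[["CH"]], ov[["CHD"]])
  expect_gte(ov[["CHD"]], 0)
})

test_that("overestimation_report computes relative volume differences", {
  expect_equal(unname(overestimation_report(1, list(same = 1))), 0)
  expect_equal(unname(overestimation_report(1, list(hull = 1.31))), 31,
               tolerance = 1e-12)
  expect_error(overestimation_report(0, list(a = 1)))
})

test_that("body_bsp closes mass exactly and recovers generator truth", {
  fit <- body_bsp(.scan2$cloud, .scan2$landmarks, .hum2$segmentation,
                  subject_record("VH", 90.3, 1.80), foot_factor = 1)
  expect_s3_class(fit, "body_bsp")
  expect_lt(abs(sum(fit$segments$mass_kg) - 90.3) / 90.3, 1e-12)
  expect_equal(sum(fit$segments$mass_pct), 100, tolerance = 1e-9)
  truth <- .hum2$true_properties
  for (nm in fit$segments$name) {
    row <- fit$segments[fit$segments$name == nm, ]
    expect_lt(rel_err(row$mass_kg, truth[[nm]]$mass), 0.03)
  }
})

test_that("doubling subject mass doubles masses and inertia but not volumes", {
  f1 <- body_bsp(.scan2$cloud, .scan2$landmarks, .hum2$segmentation,
                 subject_record("a", 90.3), foot_factor = 1)
  f2 <- body_bsp(.scan2$cloud, .scan2$landmarks, .hum2$segmentation,
                 subject_record("b", 180.6), foot_factor = 1)
  expect_equal(f2$scaling_factor, 2 * f1$scaling_factor, tolerance = 1e-12)
  expect_equal(f2$segments$mass_kg, 2 * f1$segments$mass_kg, tolerance = 1e-12)
  icols <- c("Ixx", "Iyy", "Izz", "Ixy", "Ixz", "Iyz")
  expect_equal(as.matrix(f2$segments[icols]),
               2 * as.matrix(f1$segments[icols]), tolerance = 1e-12)
  expect_equal(f2$segments$volume_m3, f1$segments$volume_m3, tolerance = 1e-12)
  expect_equal(f2$segments$mass_pct, f1$segments$mass_pct, tolerance = 1e-12)
})

test_that("trunk density 940 and limb density 1000 shape the pre-scaling masses", {
  fit <- body_bsp(.scan2$cloud, .scan2$landmarks, .hum2$segmentation,
                  subject_record("VH", 90.3), foot_factor = 1)
  d <- fit$details
  for (nm in names(d)) {
    dens <- if (grepl("trunk", nm)) 940 else 1000
    expect_equal(d[[nm]]$hull_properties$mass,
                 dens * d[[nm]]$hull_properties$volume, tolerance = 1e-9)
  }
})

test_that("uniform hull-volume inflation cancels out of the final masses", {
  # inflate every density by 10%: identical reported masses (pro-rata identity)
  seg_hi <- .hum2$segmentation
  seg_hi$segments <- lapply(seg_hi$segments, function(s) {
    s$density <- s$density * 1.1
    s
  })
  class(seg_hi) <- "body_segmentation"
  f0 <- body_bsp(.scan2$cloud, .scan2$landmarks, .hum2$segmentation,
                 subject_record("x", 90.3), foot_factor = 1)
  f1 <- body_bsp(.scan2$cloud, .scan2$landmarks, seg_hi,
                 subject_record("x", 90.3), foot_factor = 1)
  expect_equal(f1$segments$mass_kg, f0$segments$mass_kg, tolerance = 1e-10)
  expect_equal(f1$scaling_factor, f0$scaling_factor / 1.1, tolerance = 1e-12)
})

test_that("the foot correction rescales foot mass, volume and inertia before closure", {
  f_raw <- body_bsp(.scan2$cloud, .scan2$landmarks, .hum2$segmentation,
                    subject_record("x", 90.3), foot_factor = 1)
  f_cor <- body_bsp(.scan2$cloud, .scan2$landmarks, .hum2$segmentation,
                    subject_record("x", 90.3), foot_factor = 0.51)
  raw_foot <- f_raw$details$foot_left$hull_properties
  cor_foot <- f_cor$details$foot_left$hull_properties
  expect_equal(cor_foot$mass, 0.51 * raw_foot$mass, tolerance = 1e-12)
  expect_equal(cor_foot$volume, 0.51 * raw_foot$volume, tolerance = 1e-12)
  expect_equal(cor_foot$inertia_com, 0.51 * raw_foot$inertia_com,
               tolerance = 1e-12)
  # s is computed from corrected masses: totals still close exactly
  expect_lt(abs(sum(f_cor$segments$mass_kg) - 90.3) / 90.3, 1e-12)
  expect_gt(f_cor$scaling_factor, f_raw$scaling_factor)
  expect_match(f_cor$segments$corrections[
    f_cor$segments$name == "foot_right"], "foot_factor_0.51")
})

test_that("scaling all coordinates by k scales volumes k^3 and inertia k^2 at fixed mass", {
  k <- 1.15
  scaled_cloud <- point_cloud(k * .scan2$cloud$points, "world")
  scaled_lms <- .scan2$landmarks
  scaled_lms[, c("x", "y", "z")] <- k * scaled_lms[, c("x", "y", "z")]
  f0 <- body_bsp(.scan2$cloud, .scan2$landmarks, .hum2$segmentation,
                 subject_record("x", 90.3), foot_factor = 1)
  f1 <- body_bsp(scaled_cloud, scaled_lms, .hum2$segmentation,
                 subject_record("x", 90.3), foot_factor = 1)
  expect_equal(f1$segments$volume_m3, k^3 * f0$segments$volume_m3,
               tolerance = 1e-9)
  expect_equal(f1$segments$mass_pct, f0$segments$mass_pct, tolerance = 1e-9)
  icols <- c("Ixx", "Iyy", "Izz")
  expect_equal(as.matrix(f1$segments[icols]),
               k^2 * as.matrix(f0$segments[icols]), tolerance = 1e-7)
})

test_that("body_bsp S3 methods print, summarise, tabulate and plot", {
  fit <- body_bsp(.scan2$cloud, .scan2$landmarks, .hum2$segmentation,
                  subject_record("VH", 90.3, 1.80), foot_factor = 1)
  expect_output(print(fit), "pro-rata factor")
  expect_output(print(summary(fit)), "Inertia about the segment CoM")
  expect_s3_class(as.data.frame(fit), "data.frame")
  f <- tempfile(fileext = ".png")
  grDevices::png(f)
  expect_invisible(plot(fit))
  grDevices::dev.off()
  unlink(f)
})
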