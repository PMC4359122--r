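# shared fixture: one small sampled humanoid per test file run
.hum <- generate_default_humanoid(1.81, 73.4)
.scan <- sample_surface(.hum, n_points = 1500, seed = 101)

test_that("scale_and_orient recovers metric scale and the vertical axis", {
  raw_scale <- 1 / 7.24
  R <- rotation_about("y", 0.63) %*% rotation_about("x", -0.2)
  rawmap <- function(p) raw_scale * p %*% t(R)
  raw_cloud <- point_cloud(rawmap(.scan$cloud$points), "raw")
  raw_lms <- .scan$landmarks
  pm <- rawmap(as.matrix(raw_lms[, c("x", "y", "z")]))
  raw_lms$x <- pm[, 1]; raw_lms$y <- pm[, 2]; raw_lms$z <- pm[, 3]

  so <- scale_and_orient(raw_cloud, raw_lms, c("floor", "vertex"), 1.81)
  expect_equal(so$scale, 7.24, tolerance = 1e-9)
  expect_equal(sqrt(sum((landmark_position(so$landmarks, "vertex") -
                           landmark_position(so$landmarks, "floor"))^2)),
               1.81, tolerance = 1e-9)
  # up axis restored to +z, floor at the origin
  expect_equal(landmark_position(so$landmarks, "floor"), c(0, 0, 0),
               tolerance = 1e-9)
  expect_equal(landmark_position(so$landmarks, "vertex"), c(0, 0, 1.81),
               tolerance = 1e-9)
  # vertical structure restored; the in-plane heading about +z is arbitrary
  expect_equal(so$cloud$points[, 3], .scan$cloud$points[, 3],
               tolerance = 1e-9)
  expect_equal(rowSums(so$cloud$points[, 1:2]^2),
               rowSums(.scan$cloud$points[, 1:2]^2), tolerance = 1e-9)
})

test_that("scale_and_orient is idempotent and preserves distance ratios", {
  so1 <- scale_and_orient(.scan$cloud, .scan$landmarks,
                          c("floor", "vertex"), 1.81)
  expect_equal(so1$scale, 1, tolerance = 1e-12)
  expect_equal(so1$cloud$points, .scan$cloud$points, tolerance = 1e-12)

  # an arbitrary similarity input: pairwise distance ratios survive
  set.seed(3)
  idx <- sample.int(nrow(.scan$cloud$points), 20)
  so2 <- scale_and_orient(.scan$cloud, .scan$landmarks,
                          c("floor", "vertex"), 0.77)
  d_in <- dist(.scan$cloud$points[idx, ])
  d_out <- dist(so2$cloud$points[idx, ])
  expect_equal(as.numeric(d_out / d_in), rep(0.77 / 1.81, length(d_in)),
               tolerance = 1e-9)

  lms <- landmark_set(a = c(0, 0, 0), b = c(0, 0, 0), c = c(0, 0, 1))
  expect_error(scale_and_orient(.scan$cloud, lms, c("a", "b"), 1),
               class = "bodyhull_degenerate_reference")
})

test_that("cut_by_planes splits a line of points at a transverse plane", {
  pts <- cbind(0.02 * (1:10), 0.01, 0.1 * (1:10))
  # give each half nearby satellites so both halves span 3 dimensions
  jitter <- rbind(c(0.01, 0, 0), c(0, 0.02, 0), c(0, 0, 0.015))
  pts <- rbind(pts, sweep(jitter, 2, c(0.1, 0.01, 0.2), "+"),
               sweep(jitter, 2, c(0.1, 0.01, 0.9), "+"))
  lms <- landmark_set(bottom = c(0, 0, 0), top = c(0, 0, 2),
                      cutpoint = c(0, 0, 0.55))
  seg <- body_segmentation(list(
    segment_spec("upper", "central", 1000,
                 list(plane("cutpoint", c("bottom", "top"), "+")),
                 proximal = "top", distal = "cutpoint"),
    segment_spec("lower", "central", 1000,
                 list(plane("cutpoint", c("bottom", "top"), "-")),
                 proximal = "cutpoint", distal = "bottom")))
  parts <- cut_by_planes(point_cloud(pts, "world"), seg, lms)
  expect_equal(nrow(parts$upper$points) + nrow(parts$lower$points), nrow(pts))
  expect_true(all(parts$upper$points[, 3] >= 0.55))
  expect_true(all(parts$lower$points[, 3] < 0.55))
})

test_that("a point exactly on a cut plane goes to the proximal segment", {
  base <- rbind(c(0.1, 0, 0.1), c(-0.1, 0.1, 0.2), c(0, -0.1, 0.3),
                c(0.05, 0.05, 0.45))
  on_plane <- c(0.02, 0.03, 0.5)
  upper_pts <- sweep(base, 2, c(0, 0, 0.41), "+")
  pts <- rbind(base, upper_pts, on_plane)
  lms <- landmark_set(bottom = c(0, 0, 0), top = c(0, 0, 1),
                      joint = c(0, 0, 0.5))
  seg <- body_segmentation(list(
    segment_spec("proximal_seg", "central", 1000,
                 list(plane("joint", c("bottom", "top"), "+")),
                 proximal = "top", distal = "joint"),
    segment_spec("distal_seg", "central", 1000,
                 list(plane("joint", c("bottom", "top"), "-")),
                 proximal = "joint", distal = "bottom")))
  parts <- cut_by_planes(point_cloud(pts, "world"), seg, lms)
  expect_true(any(apply(parts$proximal_seg$points, 1,
                        function(r) all(r == on_plane))))
  expect_equal(nrow(parts$distal_seg$points), 4L)
})

test_that("cut_by_planes partitions the humanoid and hulls match primitive volumes", {
  parts <- cut_by_planes(.scan$cloud, .hum$segmentation, .scan$landmarks)
  expect_setequal(names(parts), names(.hum$primitives))
  expect_equal(sum(vapply(parts, function(p) nrow(p$points), 0L)),
               nrow(.scan$cloud$points))
  # non-cap-sharing segments: hull volume ~ analytic primitive volume
  for (nm in c("head", "hand_left", "upper_arm_right", "foot_left")) {
    vol <- validate_mesh(convex_hull(parts[[nm]]))$signed_volume
    expect_lt(rel_err(vol, .hum$true_properties[[nm]]$volume), 0.05)
  }
})

test_that("unassigned points error by default and can be dropped", {
  lms <- landmark_set(bottom = c(0, 0, 0), top = c(0, 0, 1),
                      joint = c(0, 0, 0.5))
  seg <- body_segmentation(list(
    segment_spec("upper_only", "central", 1000,
                 list(plane("joint", c("bottom", "top"), "+")),
                 proximal = "top", distal = "joint")))
  set.seed(5)
  pts <- matrix(runif(60, -1, 1), ncol = 3)
  expect_error(cut_by_planes(point_cloud(pts, "world"), seg, lms),
               "match no segment")
  kept <- cut_by_planes(point_cloud(pts, "world"), seg, lms,
                        on_unassigned = "drop")
  expect_true(all(kept$upper_only$points[, 3] >= 0.5))
})

test_that("a segment starved of points raises an insufficient-points error naming it", {
  lms <- landmark_set(bottom = c(0, 0, 0), top = c(0, 0, 1),
                      joint = c(0, 0, 0.99))
  seg <- body_segmentation(list(
    segment_spec("starved", "central", 1000,
                 list(plane("joint", c("bottom", "top"), "+")),
                 proximal = "top", distal = "joint"),
    segment_spec("rest", "central", 1000,
                 list(plane("joint", c("bottom", "top"), "-")),
                 proximal = "joint", distal = "bottom")))
  set.seed(6)
  pts <- matrix(runif(90, 0, 0.5), ncol = 3)
  err <- tryCatch(cut_by_planes(point_cloud(pts, "world"), seg, lms),
                  error = function(e) e)
  expect_s3_class(err, "bodyhull_insufficient_points")
  expect_match(conditionMessage(err), "starved")
})

test_that("mirroring about the sagittal plane swaps sides and negates lateral shifts", {
  mirrored <- point_cloud(.scan$cloud$points %*% diag(c(1, -1, 1)), "world")
  mlms <- .scan$landmarks
  mlms$y <- -mlms$y
  # mirrored landmarks: left-named rows now sit at right positions; swap names
  swap <- function(n) {
    n2 <- sub("_left$", "_TMP", n); n2 <- sub("_right$", "_left", n2)
    sub("_TMP$", "_right", n2)
  }
  mlms$name <- swap(mlms$name)
  p0 <- cut_by_planes(.scan$cloud, .hum$segmentation, .scan$landmarks)
  p1 <- cut_by_planes(mirrored, .hum$segmentation, mlms)
  expect_equal(nrow(p1$thigh_right$points), nrow(p0$thigh_left$points))
  expect_equal(nrow(p1$hand_left$points), nrow(p0$hand_right$points))
  # lateral CoM shift flips sign between sides (here via the fitted pipeline)
  fit <- body_bsp(.scan$cloud, .scan$landmarks, .hum$segmentation,
                  subject_record("m", 73.4), subdivide = character(),
                  foot_factor = 1)
  fl <- fit$segments[fit$segments$name == "foot_left", ]
  fr <- fit$segments[fit$segments$name == "foot_right", ]
  # foot transverse axes are (y, z): lateral shift is com_t1
  expect_equal(fl$com_t1_pct, -fr$com_t1_pct, tolerance = 0.5)
})

test_that("segment frames are rigid and put the distal landmark on the longitudinal axis", {
  lms <- landmark_set(hip = c(0.1, 0.2, 1.0), knee = c(0.15, 0.18, 0.6),
                      heel = c(0, 0.2, 0.03), toe = c(0.18, 0.22, 0.05))
  spec_z <- segment_spec("thigh_left", "left", 1000, proximal = "hip",
                         distal = "knee")
  xf <- segment_frame(spec_z, lms)
  L <- segment_length(spec_z, lms)
  expect_equal(apply_transform(landmark_position(lms, "hip"), xf), c(0, 0, 0),
               tolerance = 1e-12)
  expect_equal(apply_transform(landmark_position(lms, "knee"), xf),
               c(0, 0, L), tolerance = 1e-12)
  # rigidity: distances preserved
  set.seed(7)
  pts <- matrix(rnorm(30), ncol = 3)
  expect_equal(as.numeric(dist(apply_transform(pts, xf))),
               as.numeric(dist(pts)), tolerance = 1e-12)
  # composition with the inverse is the identity
  back <- compose_transforms(invert_transform(xf), xf)
  expect_equal(back$R, diag(3), tolerance = 1e-12)
  expect_equal(back$t, c(0, 0, 0), tolerance = 1e-12)

  spec_x <- segment_spec("foot_left", "left", 1000, proximal = "heel",
                         distal = "toe", axis = "x")
  xf2 <- segment_frame(spec_x, lms)
  toe_s <- apply_transform(landmark_position(lms, "toe"), xf2)
  expect_equal(toe_s, c(segment_length(spec_x, lms), 0, 0), tolerance = 1e-12)

  lms2 <- landmark_set(a = c(1, 1, 1), b = c(1, 1, 1))
  expect_error(segment_frame(segment_spec("s", "central", 1000,
                                          proximal = "a", distal = "b"), lms2),
               class = "bodyhull_degenerate_axis")
})

test_that("relative CoM reproduces closed forms for cylinder and cone", {
  lms <- landmark_set(p = c(0, 0, 0), d = c(0, 0, 0.4))
  spec <- segment_spec("seg", "central", 1000, proximal = "p", distal = "d")
  cyl <- primitive_spec("cylinder", list(r = 0.05, length = 0.4))
  pc <- analytic_properties(cyl)
  pc$frame <- "seg"
  rc <- relative_com(pc, spec, lms)
  expect_equal(rc[["com_long_pct"]], 50, tolerance = 1e-9)
  expect_equal(rc[["com_t1_pct"]], 0, tolerance = 1e-9)

  cone <- primitive_spec("truncated_cone", list(r1 = 0.08, r2 = 0, length = 0.4))
  pk <- analytic_properties(cone)
  pk$frame <- "seg"
  expect_equal(relative_com(pk, spec, lms)[["com_long_pct"]], 25,
               tolerance = 1e-9)

  # composite: cylinder with a side lump, transverse shift from closed forms
  lump <- primitive_spec("sphere", list(r = 0.04),
                         rigid_transform(diag(3), c(0.09, 0, 0.2)))
  pl <- analytic_properties(lump)
  pc2 <- analytic_properties(cyl)
  comp <- combine_properties(list(pc2, pl))
  comp$frame <- "seg"
  rcc <- relative_com(comp, spec, lms)
  m1 <- pc2$mass; m2 <- pl$mass
  expect_equal(rcc[["com_t1_pct"]], 100 * (m2 * 0.09 / (m1 + m2)) / 0.4,
               tolerance = 1e-9)
})
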