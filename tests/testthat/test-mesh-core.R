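test_that("convex hull of the unit cube is the exact 12-face polytope", {
  h <- convex_hull(point_cloud(cube_corners(), "world"), audit = TRUE)
  expect_equal(nrow(h$faces), 12L)
  expect_equal(nrow(h$vertices), 8L)
  v <- validate_mesh(h)
  expect_true(v$watertight)
  expect_true(v$oriented)
  expect_equal(v$signed_volume, 1, tolerance = 1e-12)
})

test_that("interior points do not change the hull", {
  with_int <- convex_hull(point_cloud(rbind(cube_corners(), c(0.5, 0.5, 0.5),
                                            c(0.25, 0.25, 0.75)), "world"),
                          audit = TRUE)
  expect_equal(nrow(with_int$vertices), 8L)
  expect_equal(sort(attr(with_int, "hull_index")), 1:8)
})

test_that("degenerate clouds raise classed errors instead of zero volumes", {
  expect_error(convex_hull(point_cloud(matrix(rnorm(9), 3, 3), "world")),
               class = "bodyhull_degenerate_geometry")
  coplanar <- cbind(matrix(runif(40), ncol = 2), 0.3)
  expect_error(convex_hull(point_cloud(coplanar, "world")),
               class = "bodyhull_degenerate_geometry")
  collinear <- cbind(seq_len(10), 2 * seq_len(10), -seq_len(10))
  expect_error(convex_hull(point_cloud(collinear, "world")),
               class = "bodyhull_degenerate_geometry")
})

test_that("hull of points inside the unit ball underestimates and approaches it", {
  set.seed(11)
  sample_ball <- function(n) {
    u <- matrix(rnorm(3 * n), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    u * runif(n)^(1 / 3)
  }
  v_small <- validate_mesh(convex_hull(point_cloud(sample_ball(500), "world"),
                                       audit = TRUE))$signed_volume
  v_big <- validate_mesh(convex_hull(point_cloud(sample_ball(5000), "world"),
                                     audit = TRUE))$signed_volume
  ball <- 4 * pi / 3
  expect_lt(v_small, ball)
  expect_lt(v_big, ball)
  expect_gt(v_big, v_small)
})

test_that("hull volume is monotone under point-set inclusion", {
  set.seed(21)
  pts <- matrix(rnorm(3 * 120), ncol = 3)
  for (k in c(10, 40, 80)) {
    va <- validate_mesh(convex_hull(point_cloud(pts[seq_len(k), ], "world")))
    vb <- validate_mesh(convex_hull(point_cloud(pts, "world")))
    expect_lte(va$signed_volume, vb$signed_volume + 1e-12)
  }
})

test_that("mass properties of the unit cube match the closed form m L^2 / 6", {
  p <- mass_properties(make_cube_mesh(), 1000)
  expect_equal(p$volume, 1, tolerance = 1e-12)
  expect_equal(p$mass, 1000, tolerance = 1e-12)
  expect_equal(p$com, c(0.5, 0.5, 0.5), tolerance = 1e-12)
  expect_equal(p$inertia_com, diag(rep(1000 / 6, 3)), tolerance = 1e-9)
})

test_that("mass properties of the unit right tetrahedron match the simplex centroid", {
  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  p <- mass_properties(convex_hull(point_cloud(tet, "world")), 1000)
  expect_equal(p$volume, 1 / 6, tolerance = 1e-12)
  expect_equal(p$com, rep(0.25, 3), tolerance = 1e-12)
})

test_that("polyhedral integration agrees with the Monte-Carlo reference on a random hull", {
  h <- random_hull(50, seed = 5)
  ex <- mass_properties(h, 1000)
  set.seed(99)
  mc <- mc_mass_properties(h, 1000, n = 3e5)
  expect_lt(rel_err(mc$volume, ex$volume), 0.01)
  rad <- max(sqrt(rowSums(sweep(h$vertices, 2, ex$com)^2)))
  expect_lt(sqrt(sum((mc$com - ex$com)^2)) / rad, 0.01)
  expect_lt(max(abs(mc$inertia_com - ex$inertia_com)) / max(abs(ex$inertia_com)),
            0.02)
})

test_that("mass properties are invariant to the coordinate origin", {
  h <- random_hull(40, seed = 8)
  p0 <- mass_properties(h, 1000)
  off <- c(123.4, -56.7, 89.1)
  h2 <- triangle_mesh(sweep(h$vertices, 2, off, "+"), h$faces, h$frame)
  p1 <- mass_properties(h2, 1000)
  expect_equal(p1$volume, p0$volume, tolerance = 1e-9)
  expect_equal(p1$com, p0$com + off, tolerance = 1e-9)
  expect_equal(p1$inertia_com, p0$inertia_com, tolerance = 1e-9)
})

test_that("mass properties commute with rigid rotation of the mesh", {
  h <- random_hull(40, seed = 13)
  R <- random_rotation(2)
  t_ <- c(0.3, -1.1, 2.2)
  xf <- rigid_transform(R, t_)
  hr <- triangle_mesh(apply_transform(h$vertices, xf), h$faces, h$frame)
  direct <- mass_properties(hr, 1000)
  mapped <- transform_properties(mass_properties(h, 1000), xf)
  expect_equal(direct$com, mapped$com, tolerance = 1e-9)
  expect_equal(direct$inertia_com, mapped$inertia_com, tolerance = 1e-9)
  expect_equal(direct$volume, mapped$volume, tolerance = 1e-12)
})

test_that("transform_properties handles identity, translation and axis permutation", {
  p <- inertial_properties(1, 1, c(0, 0, 0), diag(c(1, 2, 3)))
  expect_identical(transform_properties(p, rigid_transform())$inertia_com,
                   p$inertia_com)
  shifted <- transform_properties(p, rigid_transform(diag(3), c(0, 0, 5)))
  expect_equal(shifted$com, c(0, 0, 5))
  expect_equal(shifted$inertia_com, p$inertia_com)
  rot <- transform_properties(p, rigid_transform(rotation_about("z", pi / 2),
                                                 c(0, 0, 0)))
  expect_equal(rot$inertia_com, diag(c(2, 1, 3)), tolerance = 1e-12)
  expect_error(transform_properties(p, list(R = diag(3), t = c(0, 0, 0))),
               class = "bodyhull_invalid_transform")
  expect_error(rigid_transform(matrix(c(1, 0, 0, 0, 2, 0, 0, 0, 1), 3, 3),
                               c(0, 0, 0)))
})

test_that("combining two unit cubes reproduces the parallel-axis closed form", {
  single <- mass_properties(make_cube_mesh(), 1000)
  expect_equal(combine_properties(list(single)), single)
  m2 <- triangle_mesh(sweep(make_cube_mesh()$vertices, 2, c(2, 0, 0), "+"),
                      make_cube_mesh()$faces, "world")
  both <- combine_properties(list(single, mass_properties(m2, 1000)))
  expect_equal(both$mass, 2000, tolerance = 1e-12)
  expect_equal(both$com, c(1.5, 0.5, 0.5), tolerance = 1e-12)
  expect_equal(both$inertia_com[1, 1], 2 * 1000 / 6, tolerance = 1e-9)
  expect_equal(both$inertia_com[2, 2], 2 * (1000 / 6 + 1000), tolerance = 1e-9)
  expect_equal(both$inertia_com[3, 3], 2 * (1000 / 6 + 1000), tolerance = 1e-9)
})

test_that("combine_properties rejects empty input and mixed frames", {
  expect_error(combine_properties(list()), class = "bodyhull_empty_input")
  a <- inertial_properties(1, 1, c(0, 0, 0), diag(3) * 0.1, frame = "world")
  b <- inertial_properties(1, 1, c(1, 0, 0), diag(3) * 0.1, frame = "thigh_left")
  expect_error(combine_properties(list(a, b)),
               class = "bodyhull_frame_mismatch")
})

test_that("splitting a convex solid and recombining matches the whole", {
  h <- random_hull(60, seed = 31)
  whole <- mass_properties(h, 1000)
  parts <- split_convex_mesh(h, point = whole$com, normal = c(0.3, -1, 0.5))
  got <- combine_properties(list(mass_properties(parts$below, 1000),
                                 mass_properties(parts$above, 1000)))
  expect_equal(got$mass, whole$mass, tolerance = 1e-9)
  expect_equal(got$com, whole$com, tolerance = 1e-9)
  expect_equal(got$inertia_com, whole$inertia_com, tolerance = 1e-7)
})

test_that("validate_mesh flags holes and inconsistent winding", {
  good <- validate_mesh(make_cube_mesh())
  expect_true(good$watertight)
  expect_true(good$oriented)
  expect_equal(good$signed_volume, 1, tolerance = 1e-12)

  holed <- make_cube_mesh()
  holed$faces <- holed$faces[-1, ]
  vh <- validate_mesh(holed)
  expect_false(vh$watertight)
  expect_equal(vh$n_boundary_edges, 3L)

  flipped <- make_cube_mesh()
  flipped$faces[2, ] <- rev(flipped$faces[2, ])
  vf <- validate_mesh(flipped)
  expect_false(vf$oriented)
  expect_error(mass_properties(flipped, 1000),
               class = "bodyhull_mesh_validation")

  inverted <- make_cube_mesh()
  inverted$faces <- inverted$faces[, c(1, 3, 2)]
  expect_error(mass_properties(inverted, 1000),
               class = "bodyhull_mesh_orientation")
})

test_that("inertia tensors from random hulls are realisable", {
  for (seed in 1:8) {
    p <- mass_properties(random_hull(25, seed = seed), 1000)
    I <- p$inertia_com
    expect_equal(I, t(I), tolerance = 1e-12)
    ev <- principal_moments(I)
    expect_gte(ev[1], -1e-12 * max(ev))
    expect_lte(ev[3], ev[1] + ev[2] + 1e-9 * max(ev))
  }
})
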