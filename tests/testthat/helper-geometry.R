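# Fixtures built in code: no data files.

# hand-built unit cube mesh (12 outward-wound faces), independent of convex_hull
make_cube_mesh <- function(frame = "world") {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
             c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  f <- rbind(c(1, 3, 2), c(1, 4, 3),   # bottom (-z)
             c(5, 6, 7), c(5, 7, 8),   # top (+z)
             c(1, 2, 6), c(1, 6, 5),   # front (-y)
             c(2, 3, 7), c(2, 7, 6),   # right (+x)
             c(3, 4, 8), c(3, 8, 7),   # back (+y)
             c(4, 1, 5), c(4, 5, 8))   # left (-x)
  triangle_mesh(v, f, frame)
}

cube_corners <- function() as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))

# seeded random convex polytope (hull of gaussian points)
random_hull <- function(n = 30, seed = 1, scale = 1, centre = c(0, 0, 0)) {
  set.seed(seed)
  pts <- matrix(stats::rnorm(3 * n, sd = scale), ncol = 3)
  convex_hull(point_cloud(sweep(pts, 2, centre, "+"), "world"))
}

random_rotation <- function(seed = 1) {
  set.seed(seed)
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

rel_err <- function(got, want) {
  abs(got - want) / pmax(abs(want), .Machine$double.eps)
}

# principal moments, sorted (frame-invariant)
principal_moments <- function(I) sort(eigen(I, symmetric = TRUE,
                                            only.values = TRUE)$values)
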