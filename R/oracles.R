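#' Monte-Carlo reference integrator for convex meshes
#'
#' Estimates volume, centre of mass and inertia of a convex solid by uniform
#' rejection sampling in the bounding box, with containment tested against the
#' face planes.  This integrator shares no code path with the exact polyhedral
#' integration in [mass_properties()] and serves as its independent
#' cross-check in the validation suite.
#'
#' @param mesh a convex, outward-wound [triangle_mesh()].
#' @param density density in kg/m^3.
#' @param n number of Monte-Carlo samples.
#' @param chunk samples per block (memory control).
#' @return A list with `volume`, `mass`, `com`, `inertia_com`, `n_inside` and
#'   the standard error of the volume estimate `volume_se`.
#' @export
mc_mass_properties <- function(mesh, density = 1000, n = 1e6, chunk = 2e5) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  pl <- attr(mesh, "planes")
  if (is.null(pl)) pl <- .face_planes(mesh)
  pl <- .supporting_planes(mesh, pl)
  lo <- apply(mesh$vertices, 2, min)
  hi <- apply(mesh$vertices, 2, max)
  vbox <- prod(hi - lo)
  nrm <- pl[, 1:3, drop = FALSE]
  off <- pl[, 4]
  n <- as.integer(n)
  # keep the samples x planes distance block within ~160 MB
  chunk <- max(1e3, min(chunk, floor(2e7 / nrow(pl))))
  n_in <- 0
  s1 <- c(0, 0, 0)
  Sxx <- matrix(0, 3, 3)
  done <- 0L
  while (done < n) {
    m <- min(chunk, n - done)
    pts <- cbind(stats::runif(m, lo[1], hi[1]),
                 stats::runif(m, lo[2], hi[2]),
                 stats::runif(m, lo[3], hi[3]))
    d <- pts %*% t(nrm)
    inside <- rowSums(sweep(d, 2, off, "<=")) == ncol(d)
    ip <- pts[inside, , drop = FALSE]
    n_in <- n_in + nrow(ip)
    if (nrow(ip) > 0) {
      s1 <- s1 + colSums(ip)
      Sxx <- Sxx + crossprod(ip)
    }
    done <- done + m
  }
  if (n_in == 0) stop("no Monte-Carlo samples fell inside the mesh")
  frac <- n_in / n
  vol <- frac * vbox
  com <- s1 / n_in
  # second moments about com, per unit volume
  S <- Sxx / n_in - tcrossprod(com)
  mass <- density * vol
  I <- mass * (sum(diag(S)) * diag(3) - S)
  list(volume = vol, mass = mass, com = com, inertia_com = I,
       n_inside = n_in,
       volume_se = vbox * sqrt(frac * (1 - frac) / n))
}

# outward unit normals + offsets; sliver faces (numerically zero area) carry
# no supporting hyperplane and unreliable normals, so they are excluded
.face_planes <- function(mesh) {
  A <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  B <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  C <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  nrm <- .rowcross(B - A, C - A)
  len <- sqrt(rowSums(nrm^2))
  e1 <- sqrt(rowSums((B - A)^2))
  e2 <- sqrt(rowSums((C - A)^2))
  keep <- len > 1e-9 * e1 * e2
  nrm <- nrm[keep, , drop = FALSE] / len[keep]
  cbind(nrm, rowSums(nrm * A[keep, , drop = FALSE]))
}

# keep only planes all mesh vertices lie below (within roundoff): micro-folds
# near coplanar input clusters yield facet planes that cut the solid and
# would break half-space containment tests
.supporting_planes <- function(mesh, pl, chunk = 512L) {
  diag_ <- sqrt(sum((apply(mesh$vertices, 2, max) -
                       apply(mesh$vertices, 2, min))^2))
  tol <- max(1e-12, 1e-6 * diag_)
  keep <- logical(nrow(pl))
  for (s in seq(1, nrow(pl), by = chunk)) {
    idx <- s:min(s + chunk - 1L, nrow(pl))
    d <- mesh$vertices %*% t(pl[idx, 1:3, drop = FALSE])
    d <- sweep(d, 2, pl[idx, 4], "-")
    keep[idx] <- apply(d, 2, max) <= tol
  }
  pl[keep, , drop = FALSE]
}

#' Grid reference properties of a bent cylinder
#'
#' Numeric reference for the concave bent-cylinder test solid (a circular-arc
#' sweep of a disc, the package's stand-in for the curved shank/forearm): the
#' closed-form inside test is evaluated on a regular voxel grid and volume,
#' CoM and inertia accumulated from the occupied voxels.  Used as ground truth
#' where no closed form exists (the inertia tensor); volume and CoM also have
#' closed forms (see [analytic_properties()]) against which this oracle is
#' checked.
#'
#' Geometry, in the primitive's local frame: the disc of radius `r` starts at
#' the origin with tangent +z and is swept along a circular arc of radius
#' `R = L / phi` towards +x, through bend angle `phi`, so the centreline
#' length is `L` and the volume equals the straight cylinder's (Pappus).
#'
#' @param r tube radius (m).
#' @param length centreline arc length L (m).
#' @param bend_angle bend angle phi in radians, in (0, pi/2].
#' @param density density kg/m^3.
#' @param resolution voxel edge length (m); default 1 mm.
#' @return A list with `volume`, `mass`, `com`, `inertia_com` (about the CoM,
#'   local axes).
#' @export
bent_cylinder_grid_properties <- function(r, length, bend_angle,
                                          density = 1000, resolution = 0.001) {
  stopifnot(r > 0, length > 0, bend_angle > 0, bend_angle <= pi / 2 + 1e-12)
  R <- length / bend_angle
  # bounding box of the swept tube
  xmax <- R * (1 - cos(bend_angle)) + r
  zmax <- R * sin(bend_angle) + r
  xs <- seq(-r + resolution / 2, xmax, by = resolution)
  ys <- seq(-r + resolution / 2, r, by = resolution)
  zs <- seq(-r + resolution / 2, zmax, by = resolution)
  vvox <- resolution^3
  n_in <- 0
  s1 <- c(0, 0, 0)
  Sxx <- matrix(0, 3, 3)
  for (z in zs) {   # chunk by z-slab to bound memory
    g <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)), z)
    inside <- .bent_cylinder_inside(g, r, R, bend_angle)
    ip <- g[inside, , drop = FALSE]
    if (nrow(ip) > 0) {
      n_in <- n_in + nrow(ip)
      s1 <- s1 + colSums(ip)
      Sxx <- Sxx + crossprod(ip)
    }
  }
  vol <- n_in * vvox
  com <- s1 / n_in
  S <- Sxx / n_in - tcrossprod(com)
  mass <- density * vol
  list(volume = vol, mass = mass, com = com,
       inertia_com = mass * (sum(diag(S)) * diag(3) - S))
}

# inside test for the arc-swept tube: arc centre at (R, 0, 0), sweep from
# angle 0 (origin, tangent +z) to phi
.bent_cylinder_inside <- function(pts, r, R, phi) {
  dx <- R - pts[, 1]
  t_ <- atan2(pts[, 3], dx)
  rho <- sqrt(dx^2 + pts[, 3]^2)
  tube <- sqrt((rho - R)^2 + pts[, 2]^2) <= r
  tube & t_ >= 0 & t_ <= phi
}
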