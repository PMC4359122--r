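#' Primitive solid specification
#'
#' Parametric solids used by the synthetic-body generator: the classic
#' geometric-model repertoire (spheres, cylinders with circular or elliptical
#' cross-section, truncated cones, ellipsoids) plus a concave `bent_cylinder`
#' (a circular-arc sweep of a disc) emulating the curvature of segments such
#' as the shank or forearm that drives convex-hull volume overestimation.
#'
#' Local frames: spheres/ellipsoids are centred at the origin with semi-axes
#' along x, y, z; cylinders and truncated cones have the proximal (base) cap
#' centre at the origin and the axis along +z; the bent cylinder starts at the
#' origin with tangent +z and bends towards +x along an arc of radius
#' `length / bend_angle`.  `pose` maps local into world coordinates.
#'
#' @param kind one of `"sphere"`, `"cylinder"`, `"truncated_cone"`,
#'   `"ellipsoid"`, `"bent_cylinder"`.
#' @param dims named list of dimensions in metres: sphere `r`; cylinder `r`
#'   (or `a`, `b` cross-section semi-axes) and `length`; truncated cone `r1`,
#'   `r2` (distal radius, may be 0) and `length`; ellipsoid `a`, `b`, `c`;
#'   bent cylinder `r`, `length` (centreline arc length) and `bend_angle`
#'   (radians, in (0, pi/2]).
#' @param pose a [rigid_transform()] placing the primitive in the world.
#' @param density density in kg/m^3.
#' @return Object of class `primitive_spec`.
#' @export
primitive_spec <- function(kind, dims, pose = rigid_transform(),
                           density = 1000) {
  kind <- match.arg(kind, c("sphere", "cylinder", "truncated_cone",
                            "ellipsoid", "bent_cylinder"))
  stopifnot(inherits(pose, "rigid_transform"), density > 0)
  dims <- lapply(dims, as.numeric)
  need <- switch(kind,
    sphere = "r",
    cylinder = c(if (is.null(dims$r)) c("a", "b") else "r", "length"),
    truncated_cone = c("r1", "r2", "length"),
    ellipsoid = c("a", "b", "c"),
    bent_cylinder = c("r", "length", "bend_angle"))
  missing_ <- setdiff(need, names(dims))
  if (length(missing_))
    stop(sprintf("%s needs dimensions: %s", kind, paste(missing_, collapse = ", ")))
  if (kind == "truncated_cone") {
    if (!(dims$r1 > 0 && dims$r2 >= 0 && dims$length > 0))
      stop("truncated cone needs r1 > 0, r2 >= 0, length > 0")
  } else if (any(unlist(dims[need]) <= 0)) {
    stop(sprintf("%s dimensions must be positive", kind))
  }
  if (kind == "bent_cylinder" &&
      (dims$bend_angle <= 0 || dims$bend_angle > pi / 2 + 1e-12))
    stop("bend_angle must lie in (0, pi/2] radians")
  structure(list(kind = kind, dims = dims, pose = pose, density = density),
            class = "primitive_spec")
}

#' Closed-form inertial properties of a primitive
#'
#' Volume, centre of mass and inertia tensor of a [primitive_spec()], in the
#' world frame defined by its pose.  Spheres, cylinders, truncated cones and
#' ellipsoids use exact closed forms.  The bent cylinder's volume (Pappus:
#' equal to the straight cylinder of the same radius and centreline length)
#' and CoM are closed-form; its inertia tensor comes from the voxel reference
#' integrator [bent_cylinder_grid_properties()] and the result carries
#' attribute `approximate = TRUE`.
#'
#' @param p a [primitive_spec()].
#' @param density override the primitive's density.
#' @param grid_resolution voxel size for the bent-cylinder inertia (m).
#' @return An [inertial_properties()] object (world frame).
#' @export
analytic_properties <- function(p, density = p$density,
                                grid_resolution = 0.001) {
  stopifnot(inherits(p, "primitive_spec"))
  d <- p$dims
  approx_ <- FALSE
  loc <- switch(p$kind,
    sphere = {
      V <- 4 / 3 * pi * d$r^3
      m <- density * V
      list(V = V, com = c(0, 0, 0), I = diag(rep(2 / 5 * m * d$r^2, 3)))
    },
    ellipsoid = {
      V <- 4 / 3 * pi * d$a * d$b * d$c
      m <- density * V
      list(V = V, com = c(0, 0, 0),
           I = m / 5 * diag(c(d$b^2 + d$c^2, d$a^2 + d$c^2, d$a^2 + d$b^2)))
    },
    cylinder = {
      a <- if (is.null(d$a)) d$r else d$a
      b <- if (is.null(d$b)) d$r else d$b
      L <- d$length
      V <- pi * a * b * L
      m <- density * V
      list(V = V, com = c(0, 0, L / 2),
           I = m * diag(c(b^2 / 4 + L^2 / 12, a^2 / 4 + L^2 / 12,
                          (a^2 + b^2) / 4)))
    },
    truncated_cone = .frustum_properties(d$r1, d$r2, d$length, density),
    bent_cylinder = {
      approx_ <- TRUE
      R <- d$length / d$bend_angle
      V <- pi * d$r^2 * d$length
      rc <- R + d$r^2 / (4 * R)           # radial centroid of the swept disc
      k <- 2 * sin(d$bend_angle / 2) / d$bend_angle
      u_mid <- c(-cos(d$bend_angle / 2), 0, sin(d$bend_angle / 2))
      com <- c(R, 0, 0) + rc * k * u_mid
      g <- bent_cylinder_grid_properties(d$r, d$length, d$bend_angle,
                                         density, grid_resolution)
      list(V = V, com = com, I = g$inertia_com)
    })
  mass <- density * loc$V
  out <- inertial_properties(
    volume = loc$V, mass = mass,
    com = apply_transform(loc$com, p$pose),
    inertia_com = p$pose$R %*% loc$I %*% t(p$pose$R),
    frame = "world")
  attr(out, "approximate") <- approx_
  out
}

# exact frustum (linear radius profile) via polynomial disc-stack integrals
.frustum_properties <- function(r1, r2, L, density) {
  a <- r1
  b <- (r2 - r1) / L
  S2 <- a^2 * L + a * b * L^2 + b^2 * L^3 / 3              # int rho^2 dz
  T2 <- a^2 * L^2 / 2 + 2 * a * b * L^3 / 3 + b^2 * L^4 / 4 # int rho^2 z dz
  U2 <- a^2 * L^3 / 3 + a * b * L^4 / 2 + b^2 * L^5 / 5     # int rho^2 z^2 dz
  S4 <- a^4 * L + 2 * a^3 * b * L^2 + 2 * a^2 * b^2 * L^3 + # int rho^4 dz
    a * b^3 * L^4 + b^4 * L^5 / 5
  V <- pi * S2
  zbar <- T2 / S2
  m <- density * V
  Iz <- density * pi * S4 / 2
  Ixy <- density * pi * (S4 / 4 + U2 - zbar^2 * S2)
  list(V = V, com = c(0, 0, zbar), I = diag(c(Ixy, Ixy, Iz)))
}

# seed scoping: run expr under a temporary RNG state
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Sample a surface point cloud from a primitive or synthetic body
#'
#' Draws points on the generating surface (area-weighted across lateral
#' surfaces and end caps), optionally perturbed by isotropic Gaussian noise
#' and with a contiguous surface patch removed to emulate reconstruction
#' holes.  With `noise_sigma = 0` every returned point lies exactly on the
#' surface.  Sampling is deterministic for a given `seed`.
#'
#' @param x a [primitive_spec()] or `synthetic_body`.
#' @param n_points points per primitive before hole removal (>= 4).
#' @param noise_sigma isotropic Gaussian noise s.d. in metres.
#' @param hole_fraction fraction in `[0, 1)` of points removed as one
#'   contiguous patch around a random surface location.
#' @param seed integer seed; `NULL` uses (and advances) the current RNG.
#' @param ... passed on between methods.
#' @return For a primitive: a [point_cloud()] (world frame).  For a body: a
#'   list with `cloud` (all segments pooled, world frame) and `landmarks`.
#' @export
sample_surface <- function(x, n_points = 2000, noise_sigma = 0,
                           hole_fraction = 0, seed = NULL, ...) {
  UseMethod("sample_surface")
}

#' @rdname sample_surface
#' @export
sample_surface.primitive_spec <- function(x, n_points = 2000, noise_sigma = 0,
                                          hole_fraction = 0, seed = NULL, ...) {
  if (n_points < 4) stop("n_points must be at least 4")
  if (hole_fraction >= 1 || hole_fraction < 0)
    stop("hole_fraction must lie in [0, 1)")
  .with_seed(seed, {
    pts <- .sample_primitive_local(x, n_points)
    if (hole_fraction > 0) {
      centre <- pts[sample.int(nrow(pts), 1), ]
      k <- round(hole_fraction * n_points)
      if (k > 0) {
        d2 <- rowSums(sweep(pts, 2, centre)^2)
        pts <- pts[rank(d2, ties.method = "first") > k, , drop = FALSE]
      }
    }
    if (noise_sigma > 0)
      pts <- pts + matrix(stats::rnorm(length(pts), 0, noise_sigma), ncol = 3)
    point_cloud(apply_transform(pts, x$pose), frame = "world")
  })
}

.sample_primitive_local <- function(p, n) {
  d <- p$dims
  switch(p$kind,
    sphere = {
      u <- matrix(stats::rnorm(3 * n), ncol = 3)
      u <- u / sqrt(rowSums(u^2))
      d$r * u
    },
    ellipsoid = {
      u <- matrix(stats::rnorm(3 * n), ncol = 3)
      u <- u / sqrt(rowSums(u^2))
      cbind(d$a * u[, 1], d$b * u[, 2], d$c * u[, 3])
    },
    cylinder = {
      a <- if (is.null(d$a)) d$r else d$a
      b <- if (is.null(d$b)) d$r else d$b
      L <- d$length
      per <- pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))  # Ramanujan
      areas <- c(lateral = per * L, cap0 = pi * a * b, cap1 = pi * a * b)
      comp <- sample.int(3, n, replace = TRUE, prob = areas)
      th <- stats::runif(n, 0, 2 * pi)
      rr <- sqrt(stats::runif(n))
      z <- stats::runif(n, 0, L)
      out <- cbind(a * cos(th), b * sin(th), z)
      cap <- comp > 1
      out[cap, 1] <- a * rr[cap] * cos(th[cap])
      out[cap, 2] <- b * rr[cap] * sin(th[cap])
      out[cap, 3] <- ifelse(comp[cap] == 2, 0, L)
      out
    },
    truncated_cone = {
      L <- d$length
      rmax <- max(d$r1, d$r2)
      slant <- sqrt(L^2 + (d$r2 - d$r1)^2)
      areas <- c(lateral = pi * (d$r1 + d$r2) * slant,
                 cap0 = pi * d$r1^2, cap1 = pi * d$r2^2)
      comp <- sample.int(3, n, replace = TRUE, prob = areas)
      out <- matrix(0, n, 3)
      lat <- which(comp == 1)
      if (length(lat)) {
        # lateral area density along z is proportional to the local radius
        z <- numeric(length(lat))
        todo <- seq_along(z)
        while (length(todo)) {
          zc <- stats::runif(length(todo), 0, L)
          keep <- stats::runif(length(todo)) <=
            (d$r1 + (d$r2 - d$r1) * zc / L) / rmax
          z[todo[keep]] <- zc[keep]
          todo <- todo[!keep]
        }
        th <- stats::runif(length(lat), 0, 2 * pi)
        rho <- d$r1 + (d$r2 - d$r1) * z / L
        out[lat, ] <- cbind(rho * cos(th), rho * sin(th), z)
      }
      for (ci in 2:3) {
        idx <- which(comp == ci)
        if (!length(idx)) next
        rcap <- if (ci == 2) d$r1 else d$r2
        th <- stats::runif(length(idx), 0, 2 * pi)
        rr <- rcap * sqrt(stats::runif(length(idx)))
        out[idx, ] <- cbind(rr * cos(th), rr * sin(th),
                            if (ci == 2) 0 else L)
      }
      out
    },
    bent_cylinder = {
      r <- d$r; phi <- d$bend_angle
      R <- d$length / phi
      areas <- c(lateral = 2 * pi * r * d$length, cap0 = pi * r^2,
                 cap1 = pi * r^2)
      comp <- sample.int(3, n, replace = TRUE, prob = areas)
      out <- matrix(0, n, 3)
      lat <- which(comp == 1)
      if (length(lat)) {
        # area element on the swept tube is proportional to (R + r cos alpha)
        t_ <- numeric(length(lat)); al <- numeric(length(lat))
        todo <- seq_along(lat)
        while (length(todo)) {
          tc <- stats::runif(length(todo), 0, phi)
          ac <- stats::runif(length(todo), 0, 2 * pi)
          keep <- stats::runif(length(todo)) <= (R + r * cos(ac)) / (R + r)
          t_[todo[keep]] <- tc[keep]; al[todo[keep]] <- ac[keep]
          todo <- todo[!keep]
        }
        u <- cbind(-cos(t_), 0, sin(t_))
        out[lat, ] <- cbind(R, 0, 0)[rep(1, length(lat)), ] +
          (R + r * cos(al)) * u + r * sin(al) * cbind(0, 1, 0)[rep(1, length(lat)), ]
      }
      for (ci in 2:3) {
        idx <- which(comp == ci)
        if (!length(idx)) next
        tt <- if (ci == 2) 0 else phi
        u <- c(-cos(tt), 0, sin(tt))
        centre <- c(R, 0, 0) + R * u
        th <- stats::runif(length(idx), 0, 2 * pi)
        rr <- r * sqrt(stats::runif(length(idx)))
        out[idx, ] <- matrix(centre, length(idx), 3, byrow = TRUE) +
          outer(rr * cos(th), u) + outer(rr * sin(th), c(0, 1, 0))
      }
      out
    })
}

#' @rdname sample_surface
#' @export
sample_surface.synthetic_body <- function(x, n_points = 2000, noise_sigma = 0,
                                          hole_fraction = 0, seed = NULL, ...) {
  .with_seed(seed, {
    clouds <- lapply(x$primitives, function(p)
      sample_surface(p, n_points = n_points, noise_sigma = noise_sigma,
                     hole_fraction = hole_fraction, seed = NULL)$points)
    list(cloud = point_cloud(do.call(rbind, clouds), frame = "world"),
         landmarks = x$landmarks)
  })
}
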