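#' Inertial properties of a rigid body
#'
#' Container for the mass properties of one body or segment: volume, mass,
#' centre of mass, and the full 3x3 inertia tensor about the centre of mass
#' expressed in the axes of the stated frame.  The tensor follows the standard
#' convention `I = integral rho (|r|^2 Id - r r') dV`, so the products of
#' inertia are stored signed as the off-diagonals (`Ixy = -integral rho x y dV`);
#' report writers additionally emit their unsigned magnitudes.
#'
#' @param volume volume in m^3 (> 0).
#' @param mass mass in kg (> 0).
#' @param com centre of mass, length-3, metres.
#' @param inertia_com 3x3 symmetric inertia tensor about the CoM, kg m^2.
#' @param frame frame label.
#' @param tol relative tolerance for the realisability checks (symmetry,
#'   positive semidefiniteness, principal-moment triangle inequality).
#' @return Object of class `inertial_properties`.
#' @export
inertial_properties <- function(volume, mass, com, inertia_com, frame = "world",
                                tol = 1e-6) {
  com <- as.numeric(com)
  inertia_com <- unname(as.matrix(inertia_com))
  if (!isTRUE(volume > 0)) stop("volume must be positive")
  if (!isTRUE(mass > 0)) stop("mass must be positive")
  if (length(com) != 3L || !all(dim(inertia_com) == c(3L, 3L)))
    stop("com must be length 3 and inertia_com 3x3")
  s <- max(abs(inertia_com), .Machine$double.xmin)
  if (max(abs(inertia_com - t(inertia_com))) > tol * s)
    stop("inertia tensor is not symmetric")
  inertia_com <- (inertia_com + t(inertia_com)) / 2
  ev <- eigen(inertia_com, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * s)
    stop("inertia tensor has negative principal moments")
  if (max(ev) > sum(ev) - max(ev) + tol * s)
    stop("principal moments violate the triangle inequality (not realisable)")
  structure(list(volume = volume, mass = mass, com = com,
                 inertia_com = inertia_com, frame = as.character(frame)[1]),
            class = "inertial_properties")
}

#' @export
print.inertial_properties <- function(x, ...) {
  cat(sprintf("Inertial properties (frame '%s')\n", x$frame))
  cat(sprintf("  volume: %.6g m^3   mass: %.6g kg\n", x$volume, x$mass))
  cat(sprintf("  CoM: (%.6g, %.6g, %.6g) m\n", x$com[1], x$com[2], x$com[3]))
  cat("  inertia about CoM (kg m^2):\n")
  print(signif(x$inertia_com, 6))
  invisible(x)
}

#' Exact mass properties of a watertight mesh
#'
#' Integrates volume, first moments and second moments of a closed triangle
#' surface exactly, by decomposing the solid into signed tetrahedra against an
#' apex point.  For numerical conditioning the mesh is pre-translated to its
#' vertex centroid before integration and the results are translated back, so
#' the output is invariant to the coordinate origin.  The inertia tensor is
#' returned about the centre of mass via the parallel-axis theorem.
#'
#' @param mesh a watertight, outward-wound [triangle_mesh()].
#' @param density uniform density in kg/m^3.
#' @return An [inertial_properties()] object in the mesh frame.
#' @examples
#' cube <- convex_hull(point_cloud(as.matrix(expand.grid(0:1, 0:1, 0:1)), "world"))
#' mass_properties(cube, 1000)  # 1000 kg, CoM (0.5, 0.5, 0.5), I = m L^2 / 6
#' @export
mass_properties <- function(mesh, density) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (!isTRUE(density > 0)) stop("density must be positive")
  .assert_integrable(mesh)
  c0 <- colMeans(mesh$vertices)
  V <- sweep(mesh$vertices, 2, c0)
  A <- V[mesh$faces[, 1], , drop = FALSE]
  B <- V[mesh$faces[, 2], , drop = FALSE]
  C <- V[mesh$faces[, 3], , drop = FALSE]
  detJ <- rowSums(A * .rowcross(B, C))      # 6 * signed tet volume
  vol <- sum(detJ) / 6
  m1 <- colSums(detJ * (A + B + C)) / 24    # first moments about c0
  com_l <- m1 / vol
  # second moments: S = sum detJ/120 * (s s' + a a' + b b' + c c'), s = a+b+c
  S <- matrix(0, 3, 3)
  Ssum <- A + B + C
  for (i in 1:3) for (j in i:3) {
    S[i, j] <- S[j, i] <- sum(detJ * (Ssum[, i] * Ssum[, j] +
                                      A[, i] * A[, j] +
                                      B[, i] * B[, j] +
                                      C[, i] * C[, j])) / 120
  }
  I_origin <- density * (sum(diag(S)) * diag(3) - S)
  mass <- density * vol
  d <- com_l
  I_com <- I_origin - mass * (sum(d * d) * diag(3) - tcrossprod(d))
  inertial_properties(volume = vol, mass = mass, com = com_l + c0,
                      inertia_com = I_com, frame = mesh$frame)
}

#' Express inertial properties in another frame
#'
#' Applies a rigid transform to an [inertial_properties()] object: the centre
#' of mass is mapped as a point and the inertia tensor is rotated
#' (`R I R'`); being taken about the CoM, the tensor is invariant under pure
#' translation, and mass and volume are unchanged.
#'
#' @param props an [inertial_properties()] object.
#' @param xf a [rigid_transform()].
#' @param frame frame label of the result.
#' @return An [inertial_properties()] object.
#' @export
transform_properties <- function(props, xf, frame = props$frame) {
  stopifnot(inherits(props, "inertial_properties"))
  if (!inherits(xf, "rigid_transform"))
    stop(errorCondition("xf must be a rigid_transform",
                        class = c("bodyhull_invalid_transform", "error")))
  out <- props
  out$com <- apply_transform(props$com, xf)
  out$inertia_com <- xf$R %*% props$inertia_com %*% t(xf$R)
  out$frame <- frame
  out
}

#' Recombine inertial properties of sub-parts
#'
#' Composes the mass properties of parts sharing one frame into those of the
#' union: masses and volumes add, the CoM is the mass-weighted mean, and each
#' part's inertia tensor is shifted to the combined CoM by the parallel-axis
#' theorem (including the off-diagonal product terms) before summing.  This is
#' how subdivided segment hulls are recomposed into whole-segment values.
#'
#' @param parts non-empty list of [inertial_properties()] in one frame.
#' @return An [inertial_properties()] object.
#' @export
combine_properties <- function(parts) {
  if (inherits(parts, "inertial_properties")) parts <- list(parts)
  if (length(parts) == 0)
    stop(errorCondition("cannot combine an empty list of parts",
                        class = c("bodyhull_empty_input", "error")))
  stopifnot(all(vapply(parts, inherits, TRUE, "inertial_properties")))
  frames <- vapply(parts, `[[`, "", "frame")
  if (length(unique(frames)) != 1L)
    stop(errorCondition(
      sprintf("parts are in different frames: %s",
              paste(unique(frames), collapse = ", ")),
      class = c("bodyhull_frame_mismatch", "error")))
  m <- vapply(parts, `[[`, 0, "mass")
  vol <- sum(vapply(parts, `[[`, 0, "volume"))
  mass <- sum(m)
  coms <- t(vapply(parts, `[[`, c(0, 0, 0), "com"))
  com <- colSums(coms * m) / mass
  I <- matrix(0, 3, 3)
  for (k in seq_along(parts)) {
    d <- parts[[k]]$com - com
    I <- I + parts[[k]]$inertia_com +
      m[k] * (sum(d * d) * diag(3) - tcrossprod(d))
  }
  inertial_properties(volume = vol, mass = mass, com = com, inertia_com = I,
                      frame = frames[1])
}
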