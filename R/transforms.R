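#' Rigid transform
#'
#' A proper rigid transform (rotation + translation) mapping coordinates from
#' one frame to another: `x' = R x + t`.  Used to move point clouds, meshes and
#' inertial properties between the raw scanner frame, the world frame and
#' per-segment anatomical frames.
#'
#' @param rotation 3x3 rotation matrix (orthonormal, determinant +1).
#' @param translation length-3 numeric translation vector (metres).
#' @param tol orthonormality tolerance.
#' @return An object of class `rigid_transform` with elements `R` and `t`.
#' @examples
#' xf <- rigid_transform(rotation_about("z", pi / 2), c(0, 0, 1))
#' apply_transform(c(1, 0, 0), xf)
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            tol = 1e-8) {
  rotation <- unname(as.matrix(rotation))
  translation <- unname(as.numeric(translation))
  if (!all(dim(rotation) == c(3L, 3L)) || length(translation) != 3L)
    stop("rigid_transform needs a 3x3 rotation and a length-3 translation")
  if (!all(is.finite(rotation)) || !all(is.finite(translation)))
    stop("rigid_transform entries must be finite")
  err <- max(abs(crossprod(rotation) - diag(3)))
  if (err > tol)
    stop(sprintf("rotation is not orthonormal (max |R'R - I| = %.3g)", err),
         call. = FALSE)
  if (abs(det(rotation) - 1) > tol)
    stop("rotation must be proper (det = +1); reflections are not rigid transforms",
         call. = FALSE)
  structure(list(R = rotation, t = translation), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("Rigid transform\n  rotation:\n")
  print(round(x$R, 6))
  cat("  translation:", paste(signif(x$t, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Elementary rotation matrix
#'
#' @param axis one of `"x"`, `"y"`, `"z"`.
#' @param angle rotation angle in radians (right-handed).
#' @return 3x3 rotation matrix.
#' @export
rotation_about <- function(axis = c("x", "y", "z"), angle) {
  axis <- match.arg(axis)
  c_ <- cos(angle); s_ <- sin(angle)
  switch(axis,
    x = matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3),
    y = matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3),
    z = matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3))
}

#' Minimal rotation taking one direction onto another
#'
#' Rodrigues rotation about `from x to`; used to bring the body's vertical
#' axis onto +z when orienting raw scans.
#'
#' @param from,to length-3 direction vectors (need not be unit length).
#' @return 3x3 rotation matrix `R` with `R from ∝ to`.
#' @export
rotation_between <- function(from, to) {
  f <- from / sqrt(sum(from^2))
  t_ <- to / sqrt(sum(to^2))
  v <- c(f[2] * t_[3] - f[3] * t_[2],
         f[3] * t_[1] - f[1] * t_[3],
         f[1] * t_[2] - f[2] * t_[1])
  c_ <- sum(f * t_)
  s2 <- sum(v^2)
  if (s2 < 1e-30) {
    if (c_ > 0) return(diag(3))
    # opposite directions: rotate pi about any axis orthogonal to f
    a <- if (abs(f[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    a <- a - sum(a * f) * f
    a <- a / sqrt(sum(a^2))
    return(2 * tcrossprod(a) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx * ((1 - c_) / s2)
}

#' Apply, compose and invert rigid transforms
#'
#' `apply_transform()` maps points (a vector or an n x 3 matrix),
#' `compose_transforms(a, b)` returns the transform equivalent to applying `b`
#' first and `a` second, and `invert_transform()` returns the inverse map.
#'
#' @param points numeric length-3 vector or n x 3 matrix.
#' @param xf,a,b `rigid_transform` objects.
#' @return Transformed coordinates, or a `rigid_transform`.
#' @export
apply_transform <- function(points, xf) {
  stopifnot(inherits(xf, "rigid_transform"))
  if (is.null(dim(points))) {
    drop(xf$R %*% points + xf$t)
  } else {
    sweep(points %*% t(xf$R), 2, xf$t, "+")
  }
}

#' @rdname apply_transform
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$R %*% b$R, drop(a$R %*% b$t) + a$t)
}

#' @rdname apply_transform
#' @export
invert_transform <- function(xf) {
  rigid_transform(t(xf$R), drop(-t(xf$R) %*% xf$t))
}
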