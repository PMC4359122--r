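#' Point cloud
#'
#' An unordered set of 3D surface samples in metres.  The `frame` label tracks
#' where the coordinates live: `"raw"` (unscaled scanner output), `"world"`
#' (scaled, +z vertical, anatomical standing pose) or a segment-anatomical
#' frame named after the segment.
#'
#' @param points n x 3 numeric matrix (or something coercible to one).
#' @param frame frame label, default `"raw"`.
#' @return Object of class `point_cloud`: list with `points` (n x 3 matrix)
#'   and `frame`.
#' @export
point_cloud <- function(points, frame = "raw") {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  points <- unname(as.matrix(points))
  storage.mode(points) <- "double"
  if (ncol(points) != 3L)
    stop("a point cloud needs 3 columns (x, y, z)")
  if (nrow(points) > 0 && !all(is.finite(points)))
    stop("point cloud contains non-finite coordinates")
  structure(list(points = points, frame = as.character(frame)[1]),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("Point cloud: %d points, frame '%s'\n", nrow(x$points), x$frame))
  if (nrow(x$points) > 0) {
    rng <- apply(x$points, 2, range)
    cat(sprintf("  extent  x [%.4g, %.4g]  y [%.4g, %.4g]  z [%.4g, %.4g]\n",
                rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  }
  invisible(x)
}

as_point_cloud <- function(x, frame = "raw") {
  if (inherits(x, "point_cloud")) x else point_cloud(x, frame)
}

#' Transform a point cloud into another frame
#'
#' @param cloud a `point_cloud`.
#' @param xf a [rigid_transform()].
#' @param frame frame label of the result.
#' @return A `point_cloud` in the new frame.
#' @export
transform_cloud <- function(cloud, xf, frame = cloud$frame) {
  cloud <- as_point_cloud(cloud)
  point_cloud(apply_transform(cloud$points, xf), frame)
}
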