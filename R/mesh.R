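#' Triangle mesh
#'
#' A triangle surface mesh.  All downstream mass-property integration assumes
#' the mesh is watertight (every edge shared by exactly two faces), that face
#' winding is consistent, and that normals point outward so the signed volume
#' is positive; [validate_mesh()] checks exactly these conditions.
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates (metres).
#' @param faces m x 3 integer matrix of 1-based vertex indices, wound so that
#'   normals point outward.
#' @param frame frame label carried over from the source point cloud.
#' @return Object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, frame = "world") {
  vertices <- unname(as.matrix(vertices))
  storage.mode(vertices) <- "double"
  faces <- unname(as.matrix(faces))
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L || ncol(faces) != 3L)
    stop("triangle_mesh needs n x 3 vertices and m x 3 faces")
  if (nrow(faces) > 0 &&
      (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces,
                 frame = as.character(frame)[1]),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  v <- validate_mesh(x)
  cat(sprintf("Triangle mesh: %d vertices, %d faces, frame '%s'\n",
              nrow(x$vertices), nrow(x$faces), x$frame))
  cat(sprintf("  watertight: %s  oriented: %s  signed volume: %.6g m^3\n",
              v$watertight, v$oriented, v$signed_volume))
  invisible(x)
}

# row-wise cross product of n x 3 matrices
.rowcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# signed volume of the mesh about its vertex centroid (conditioning)
.signed_volume <- function(mesh) {
  if (nrow(mesh$faces) == 0) return(0)
  c0 <- colMeans(mesh$vertices)
  V <- sweep(mesh$vertices, 2, c0)
  A <- V[mesh$faces[, 1], , drop = FALSE]
  B <- V[mesh$faces[, 2], , drop = FALSE]
  C <- V[mesh$faces[, 3], , drop = FALSE]
  sum(rowSums(A * .rowcross(B, C))) / 6
}

#' Convex hull of a point cloud
#'
#' Computes the minimum convex polyhedron enclosing the points, returned as a
#' watertight, outward-wound triangle mesh.  The hull is the geometric outline
#' used for all segment volume and inertia estimates; for concave segments it
#' systematically overestimates the enclosed volume, which is why curved
#' segments are subdivided before hulling (see [subdivide_along_axis()]).
#'
#' Degenerate inputs (fewer than four points, or all points collinear or
#' coplanar) raise an error of class `bodyhull_degenerate_geometry`: a silent
#' zero-volume hull would poison the pro-rata mass scaling downstream.
#'
#' @param cloud a [point_cloud()] (or bare n x 3 matrix) with at least 4
#'   non-coplanar points.
#' @param tol distance tolerance for the hull construction; default scales
#'   with the cloud extent.
#' @param audit if `TRUE`, verify after construction that every input point
#'   lies inside the hull (O(n * faces); used by validation tests).
#' @return A [triangle_mesh()] in the cloud's frame.  Attribute `hull_index`
#'   gives, for each hull vertex, its row in the input cloud.
#' @examples
#' cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
#' h <- convex_hull(point_cloud(cube, "world"))
#' nrow(h$faces)  # 12 triangles
#' @export
convex_hull <- function(cloud, tol = -1, audit = FALSE) {
  cloud <- as_point_cloud(cloud)
  if (nrow(cloud$points) < 4L)
    stop(errorCondition("convex hull needs at least 4 points",
                        class = c("bodyhull_degenerate_geometry", "error")))
  res <- tryCatch(
    .quickhull3d(cloud$points, tol, audit),
    error = function(e) {
      if (grepl("degenerate|at least 4", conditionMessage(e)))
        stop(errorCondition(conditionMessage(e),
                            class = c("bodyhull_degenerate_geometry", "error")))
      stop(e)
    })
  mesh <- triangle_mesh(res$vertices, res$faces, frame = cloud$frame)
  attr(mesh, "hull_index") <- res$orig_index
  attr(mesh, "planes") <- res$planes
  attr(mesh, "tolerance") <- res$tolerance
  mesh
}

#' Validate a triangle mesh
#'
#' Reports (never raises) whether a mesh is safe for volume integration: it
#' must be two-manifold and hole free (every directed edge matched by exactly
#' one reverse edge), consistently wound, and enclose a positive signed
#' volume.
#'
#' @param mesh a [triangle_mesh()].
#' @return A list of class `mesh_validation`: `watertight`, `oriented`,
#'   `signed_volume`, `n_boundary_edges`, `n_vertices`, `n_faces`.
#' @export
validate_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  f <- mesh$faces
  if (nrow(f) == 0) {
    out <- list(watertight = FALSE, oriented = FALSE, signed_volume = 0,
                n_boundary_edges = 0L, n_vertices = nrow(mesh$vertices),
                n_faces = 0L)
    class(out) <- "mesh_validation"
    return(out)
  }
  from <- c(f[, 1], f[, 2], f[, 3])
  to   <- c(f[, 2], f[, 3], f[, 1])
  nv <- nrow(mesh$vertices)
  key <- (from - 1) * nv + to          # directed edge id
  rkey <- (to - 1) * nv + from         # its reverse
  dup <- anyDuplicated(key) > 0L       # a directed edge used twice => bad winding
  unmatched <- sum(!(key %in% rkey))   # boundary edges (hole or flipped patch)
  degen <- any(from == to)
  vol <- .signed_volume(mesh)
  out <- list(
    watertight = !dup && unmatched == 0L && !degen,
    oriented = !dup && !degen,
    signed_volume = vol,
    n_boundary_edges = as.integer(unmatched),
    n_vertices = nv,
    n_faces = nrow(f))
  class(out) <- "mesh_validation"
  out
}

#' @export
print.mesh_validation <- function(x, ...) {
  cat(sprintf(paste0("Mesh validation: %d vertices, %d faces\n",
                     "  watertight: %s (%d boundary edges)\n",
                     "  consistent winding: %s\n  signed volume: %.6g m^3\n"),
              x$n_vertices, x$n_faces, x$watertight, x$n_boundary_edges,
              x$oriented, x$signed_volume))
  invisible(x)
}

.assert_integrable <- function(mesh) {
  v <- validate_mesh(mesh)
  if (!v$oriented)
    stop(errorCondition("mesh has inconsistent face winding",
                        class = c("bodyhull_mesh_validation", "error")))
  if (!v$watertight)
    stop(errorCondition(
      sprintf("mesh is not watertight (%d boundary edges)", v$n_boundary_edges),
      class = c("bodyhull_mesh_validation", "error")))
  if (v$signed_volume <= 0)
    stop(errorCondition("mesh signed volume is not positive (normals point inward?)",
                        class = c("bodyhull_mesh_orientation", "error")))
  v
}

#' Split a convex mesh by a plane
#'
#' Cuts a convex polyhedron into the two sub-polyhedra on either side of a
#' plane.  Each part is the convex hull of the original vertices on that side
#' plus the exact edge-plane intersection points, so part volumes and moments
#' recombine to the whole to numerical precision (used to verify the
#' parallel-axis composition of subdivided segments).
#'
#' @param mesh a convex [triangle_mesh()].
#' @param point a point on the cutting plane.
#' @param normal plane normal (need not be unit length).
#' @return List with meshes `below` and `above` (either may be `NULL` when the
#'   plane misses the solid).
#' @export
split_convex_mesh <- function(mesh, point, normal) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  n <- normal / sqrt(sum(normal^2))
  d <- drop(mesh$vertices %*% n) - sum(point * n)
  scale <- max(abs(d), 1)
  tol <- 1e-12 * scale
  f <- mesh$faces
  e_from <- c(f[, 1], f[, 2], f[, 3])
  e_to   <- c(f[, 2], f[, 3], f[, 1])
  crossing <- (d[e_from] > tol & d[e_to] < -tol) |
              (d[e_from] < -tol & d[e_to] > tol)
  cuts <- NULL
  if (any(crossing)) {
    a <- mesh$vertices[e_from[crossing], , drop = FALSE]
    b <- mesh$vertices[e_to[crossing], , drop = FALSE]
    t_ <- d[e_from[crossing]] / (d[e_from[crossing]] - d[e_to[crossing]])
    cuts <- a + (b - a) * t_
  }
  part <- function(side_pts) {
    pts <- rbind(side_pts, cuts)
    if (nrow(pts) < 4) return(NULL)
    tryCatch(convex_hull(point_cloud(pts, mesh$frame)),
             bodyhull_degenerate_geometry = function(e) NULL)
  }
  list(below = part(mesh$vertices[d <= tol, , drop = FALSE]),
       above = part(mesh$vertices[d >= -tol, , drop = FALSE]))
}
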