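#' Landmark sets
#'
#' Landmarks are named anatomical reference points in metres, stored as a
#' data frame with columns `name`, `x`, `y`, `z`.  They define the cutting
#' planes of the body segmentation and the per-segment anatomical axes.
#'
#' @param ... named length-3 numeric vectors, e.g.
#'   `landmark_set(vertex = c(0, 0, 1.8), floor = c(0, 0, 0))`.
#' @return A `data.frame` of class `landmark_set`.
#' @export
landmark_set <- function(...) {
  lms <- list(...)
  if (length(lms) == 1 && is.list(lms[[1]]) && is.null(dim(lms[[1]])))
    lms <- lms[[1]]
  if (is.null(names(lms)) || any(names(lms) == ""))
    stop("all landmarks must be named")
  if (anyDuplicated(names(lms)))
    stop("landmark names must be unique")
  m <- do.call(rbind, lapply(lms, as.numeric))
  if (ncol(m) != 3 || !all(is.finite(m)))
    stop("each landmark must be a finite length-3 coordinate")
  out <- data.frame(name = names(lms), x = m[, 1], y = m[, 2], z = m[, 3],
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("landmark_set", "data.frame")
  out
}

#' @rdname landmark_set
#' @param landmarks a `landmark_set`.
#' @param name landmark name.
#' @export
landmark_position <- function(landmarks, name) {
  i <- match(name, landmarks$name)
  if (is.na(i))
    stop(sprintf("landmark '%s' not found", name), call. = FALSE)
  c(landmarks$x[i], landmarks$y[i], landmarks$z[i])
}

#' @rdname landmark_set
#' @param xf a [rigid_transform()] (or similarity map from
#'   [scale_and_orient()]).
#' @export
transform_landmarks <- function(landmarks, xf) {
  p <- apply_transform(as.matrix(landmarks[, c("x", "y", "z")]), xf)
  landmarks$x <- p[, 1]; landmarks$y <- p[, 2]; landmarks$z <- p[, 3]
  landmarks
}

#' Segment specification
#'
#' One anatomical segment: its density, the half-space constraints that carve
#' its points out of the whole-body cloud, the proximal and distal landmarks
#' defining the anatomical longitudinal axis, and which axis is longitudinal
#' (`z` by convention, `x` for the foot).
#'
#' Each cutting plane is given as `plane(origin, normal, side)`: `origin`
#' names the landmark the plane passes through; `normal` is either a pair of
#' landmark names (direction from the first to the second) or a literal
#' length-3 vector; `side = "+"` keeps points with non-negative signed
#' distance (boundary included), `side = "-"` keeps strictly negative ones.
#' Boundary ownership is therefore encoded in the configuration; shipped
#' configurations give points lying exactly on a transverse joint cut to the
#' proximal (more cranial/axial) segment.
#'
#' @param name segment name (unique within a segmentation).
#' @param side `"left"`, `"right"` or `"central"`.
#' @param density segment density in kg/m^3.
#' @param planes list of half-space constraints from [plane()].
#' @param proximal,distal landmark names of the segment endpoints.
#' @param axis longitudinal axis, `"z"` (default) or `"x"` (foot).
#' @param group segment family used to match subdivision/correction options
#'   (defaults to the name with any `_left`/`_right` suffix removed).
#' @return Object of class `segment_spec`.
#' @export
segment_spec <- function(name, side = c("central", "left", "right"),
                         density = 1000, planes = list(),
                         proximal, distal, axis = c("z", "x"),
                         group = NULL) {
  side <- match.arg(side)
  axis <- match.arg(axis)
  stopifnot(density > 0, is.character(name), nzchar(name))
  if (proximal == distal)
    stop("proximal and distal landmarks must differ")
  if (is.null(group)) group <- sub("_(left|right)$", "", name)
  structure(list(name = name, side = side, density = density,
                 planes = planes, proximal = proximal, distal = distal,
                 axis = axis, group = group),
            class = "segment_spec")
}

#' @rdname segment_spec
#' @param origin landmark name the plane passes through.
#' @param normal landmark-name pair or length-3 numeric direction.
#' @export
plane <- function(origin, normal, side = c("+", "-")) {
  side <- match.arg(side)
  if (is.character(normal) && length(normal) != 2)
    stop("a landmark-pair normal needs exactly two names")
  if (is.numeric(normal) && length(normal) != 3)
    stop("a literal normal needs three components")
  list(origin = origin, normal = normal, side = side)
}

#' Body segmentation
#'
#' The anatomical decomposition of the body: an ordered list of
#' [segment_spec()]s (points are assigned to the first segment whose
#' half-space constraints they satisfy) plus, optionally, the landmark set the
#' planes refer to.
#'
#' @param segments list of [segment_spec()].
#' @param landmarks optional [landmark_set()].
#' @return Object of class `body_segmentation`.
#' @export
body_segmentation <- function(segments, landmarks = NULL) {
  stopifnot(all(vapply(segments, inherits, TRUE, "segment_spec")))
  nms <- vapply(segments, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("segment names must be unique")
  names(segments) <- nms
  out <- structure(list(segments = segments, landmarks = landmarks),
                   class = "body_segmentation")
  if (!is.null(landmarks)) validate_segmentation(out, landmarks)
  out
}

#' @rdname body_segmentation
#' @export
validate_segmentation <- function(seg, landmarks) {
  refs <- unique(unlist(lapply(seg$segments, function(s) {
    c(s$proximal, s$distal,
      unlist(lapply(s$planes, function(pl)
        c(pl$origin, if (is.character(pl$normal)) pl$normal))))
  })))
  missing_ <- setdiff(refs, landmarks$name)
  if (length(missing_))
    stop(sprintf("segmentation references unknown landmarks: %s",
                 paste(missing_, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

#' @export
print.body_segmentation <- function(x, ...) {
  cat(sprintf("Body segmentation: %d segments\n", length(x$segments)))
  for (s in x$segments)
    cat(sprintf("  %-18s %-7s density %4g kg/m^3  axis %s  %s -> %s\n",
                s$name, s$side, s$density, s$axis, s$proximal, s$distal))
  invisible(x)
}

# signed distance of points to a configured plane
.plane_distance <- function(points, pl, landmarks) {
  o <- landmark_position(landmarks, pl$origin)
  n <- if (is.character(pl$normal)) {
    landmark_position(landmarks, pl$normal[2]) -
      landmark_position(landmarks, pl$normal[1])
  } else as.numeric(pl$normal)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-12)
    stop(errorCondition("degenerate plane normal (coincident landmark pair)",
                        class = c("bodyhull_degenerate_reference", "error")))
  n <- n / nn
  drop(points %*% n) - sum(o * n)
}

#' Scale and orient a raw point cloud into the world frame
#'
#' Applies one similarity transform (uniform scale, rotation, translation) so
#' that a reference landmark pair is at its known metric distance, the body's
#' vertical axis points along +z, and the base of the up-axis pair sits at the
#' origin.  All pairwise distance ratios are preserved.
#'
#' @param cloud a [point_cloud()] in the raw frame.
#' @param landmarks [landmark_set()] in the same raw frame.
#' @param reference character pair of landmark names whose true separation is
#'   known (e.g. `c("floor", "vertex")` for subject height).
#' @param distance known separation of the reference pair in metres (for a
#'   floor-vertex pair, the subject height).
#' @param up character pair of landmark names pointing from low to high along
#'   the body's vertical (default: the reference pair).
#' @return List with `cloud` (world frame), `landmarks` (transformed),
#'   `scale`, and `transform` (the rigid part, applied after scaling about
#'   the up-base landmark).
#' @export
scale_and_orient <- function(cloud, landmarks, reference, distance,
                             up = reference) {
  cloud <- as_point_cloud(cloud)
  stopifnot(length(reference) == 2, length(up) == 2, distance > 0)
  p1 <- landmark_position(landmarks, reference[1])
  p2 <- landmark_position(landmarks, reference[2])
  d_raw <- sqrt(sum((p2 - p1)^2))
  if (d_raw < 1e-12)
    stop(errorCondition("reference landmarks coincide",
                        class = c("bodyhull_degenerate_reference", "error")))
  s <- distance / d_raw
  u1 <- landmark_position(landmarks, up[1])
  u2 <- landmark_position(landmarks, up[2])
  if (sqrt(sum((u2 - u1)^2)) < 1e-12)
    stop(errorCondition("up-axis landmarks coincide",
                        class = c("bodyhull_degenerate_reference", "error")))
  R <- rotation_between(u2 - u1, c(0, 0, 1))
  map <- function(p) {
    if (is.null(dim(p))) s * drop(R %*% (p - u1))
    else s * sweep(p, 2, u1) %*% t(R)
  }
  lms <- landmarks
  pm <- map(as.matrix(landmarks[, c("x", "y", "z")]))
  lms$x <- pm[, 1]; lms$y <- pm[, 2]; lms$z <- pm[, 3]
  list(cloud = point_cloud(map(cloud$points), frame = "world"),
       landmarks = lms, scale = s,
       transform = rigid_transform(R, drop(-s * R %*% u1)))
}

#' Cut a world-frame cloud into anatomical segments
#'
#' Assigns every point to the first segment (in configuration order) whose
#' half-space constraints it satisfies.  For a configuration whose segments
#' partition space this yields disjoint per-segment clouds whose union is the
#' input.
#'
#' @param cloud a [point_cloud()] in the world frame.
#' @param seg a [body_segmentation()].
#' @param landmarks [landmark_set()] in the world frame (default: the one
#'   stored in `seg`).
#' @param on_unassigned `"error"` (default) or `"drop"` for points matching
#'   no segment.
#' @param min_points minimum points per segment (each segment must also span
#'   3 dimensions); fewer raises an error naming the segment.
#' @return Named list of per-segment [point_cloud()]s.
#' @export
cut_by_planes <- function(cloud, seg, landmarks = seg$landmarks,
                          on_unassigned = c("error", "drop"),
                          min_points = 4L) {
  cloud <- as_point_cloud(cloud)
  on_unassigned <- match.arg(on_unassigned)
  if (is.null(landmarks)) stop("cut_by_planes needs landmarks")
  validate_segmentation(seg, landmarks)
  pts <- cloud$points
  n <- nrow(pts)
  assigned <- integer(n)
  for (k in seq_along(seg$segments)) {
    s <- seg$segments[[k]]
    cand <- which(assigned == 0L)
    if (!length(cand)) break
    ok <- rep(TRUE, length(cand))
    for (pl in s$planes) {
      d <- .plane_distance(pts[cand, , drop = FALSE], pl, landmarks)
      ok <- ok & if (pl$side == "+") d >= 0 else d < 0
    }
    assigned[cand[ok]] <- k
  }
  if (any(assigned == 0L)) {
    if (on_unassigned == "error")
      stop(sprintf("%d points match no segment (use on_unassigned = 'drop' to discard)",
                   sum(assigned == 0L)), call. = FALSE)
  }
  out <- lapply(seq_along(seg$segments), function(k) {
    p <- pts[assigned == k, , drop = FALSE]
    s <- seg$segments[[k]]
    if (nrow(p) < min_points || .rank3(p) < 3L)
      stop(errorCondition(
        sprintf("segment '%s' received %d points (need >= %d spanning 3 dimensions)",
                s$name, nrow(p), min_points),
        class = c("bodyhull_insufficient_points", "error")))
    point_cloud(p, frame = cloud$frame)
  })
  names(out) <- names(seg$segments)
  out
}

# affine rank of a point set (3 = spans a volume)
.rank3 <- function(p) {
  if (nrow(p) < 2) return(0L)
  q <- sweep(p, 2, colMeans(p))
  sv <- svd(q, nu = 0, nv = 0)$d
  sum(sv > max(sv[1], 1e-300) * 1e-9)
}

#' Segment-anatomical frame
#'
#' Builds the rigid transform from the world frame into a segment's
#' anatomical frame: origin at the proximal landmark, longitudinal axis (+z,
#' or +x for the foot) pointing from the proximal to the distal landmark.
#' The remaining axes complete a right-handed frame, chosen as close as
#' possible to the world axes (anatomical standing pose) so transverse x/y
#' retain their anterior/lateral meaning.
#'
#' @param spec a [segment_spec()].
#' @param landmarks [landmark_set()] in the world frame.
#' @return A [rigid_transform()] mapping world to segment coordinates.
#' @export
segment_frame <- function(spec, landmarks) {
  p <- landmark_position(landmarks, spec$proximal)
  d <- landmark_position(landmarks, spec$distal)
  axis <- d - p
  L <- sqrt(sum(axis^2))
  if (L < 1e-12)
    stop(errorCondition("proximal and distal landmarks coincide",
                        class = c("bodyhull_degenerate_axis", "error")))
  e_long <- axis / L
  if (spec$axis == "z") {
    # longitudinal -> z; keep x (anterior) near the world x axis
    ref <- c(1, 0, 0)
    if (abs(sum(ref * e_long)) > 0.99) ref <- c(0, 1, 0)
    e_x <- ref - sum(ref * e_long) * e_long
    e_x <- e_x / sqrt(sum(e_x^2))
    e_y <- c(e_long[2] * e_x[3] - e_long[3] * e_x[2],
             e_long[3] * e_x[1] - e_long[1] * e_x[3],
             e_long[1] * e_x[2] - e_long[2] * e_x[1])
    A <- cbind(e_x, e_y, e_long)
  } else {
    # longitudinal -> x (foot); keep z near the world vertical
    ref <- c(0, 0, 1)
    if (abs(sum(ref * e_long)) > 0.99) ref <- c(0, 1, 0)
    e_z <- ref - sum(ref * e_long) * e_long
    e_z <- e_z / sqrt(sum(e_z^2))
    e_y <- c(e_z[2] * e_long[3] - e_z[3] * e_long[2],
             e_z[3] * e_long[1] - e_z[1] * e_long[3],
             e_z[1] * e_long[2] - e_z[2] * e_long[1])
    A <- cbind(e_long, e_y, e_z)
  }
  rigid_transform(t(A), drop(-t(A) %*% p))
}

#' Segment length between the endpoint landmarks
#'
#' @param spec a [segment_spec()].
#' @param landmarks [landmark_set()].
#' @return Length in metres.
#' @export
segment_length <- function(spec, landmarks) {
  p <- landmark_position(landmarks, spec$proximal)
  d <- landmark_position(landmarks, spec$distal)
  sqrt(sum((d - p)^2))
}

#' Relative centre of mass of a segment
#'
#' Expresses a segment's CoM the way anthropometric tables report it: the
#' longitudinal position as a percentage of segment length measured from the
#' proximal landmark, and the transverse shift from the anatomical
#' longitudinal axis (as a percentage of segment length) in the two remaining
#' axes.  For z-longitudinal segments the transverse axes are (x, y); for the
#' foot (x-longitudinal) they are (y, z).  Left- and right-side segments have
#' opposite-signed lateral (y) shifts by mirror symmetry.
#'
#' @param props [inertial_properties()] in the segment-anatomical frame.
#' @param spec the segment's [segment_spec()].
#' @param landmarks [landmark_set()] (any rigid frame; only the
#'   proximal-distal distance is used).
#' @return Named numeric: `com_long_pct`, `com_t1_pct`, `com_t2_pct` (t1/t2 =
#'   x/y for z-axis segments, y/z for the foot).
#' @export
relative_com <- function(props, spec, landmarks) {
  stopifnot(inherits(props, "inertial_properties"))
  L <- segment_length(spec, landmarks)
  if (L <= 0)
    stop(errorCondition("segment length is zero",
                        class = c("bodyhull_degenerate_axis", "error")))
  idx <- if (spec$axis == "z") c(3L, 1L, 2L) else c(1L, 2L, 3L)
  v <- 100 * props$com[idx] / L
  names(v) <- c("com_long_pct", "com_t1_pct", "com_t2_pct")
  v
}
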