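#' Subject record
#'
#' @param id subject label.
#' @param mass measured body mass in kg.
#' @param height stature in metres.
#' @param sex optional label.
#' @return Object of class `subject_record`.
#' @export
subject_record <- function(id = "subject", mass, height = NA_real_,
                           sex = NA_character_) {
  if (!isTRUE(mass > 0)) stop("subject mass must be positive")
  if (!is.na(height) && height <= 0) stop("subject height must be positive")
  structure(list(id = as.character(id)[1], mass = mass, height = height,
                 sex = as.character(sex)[1]),
            class = "subject_record")
}

#' Pro-rata mass-closure scaling factor
#'
#' The hull-derived total body mass never matches the measured subject mass
#' exactly, so all segment densities are rescaled pro rata by
#' `s = subject_mass / sum(hull_masses)`.  The factor multiplies every
#' segment's mass and, being a density factor, the full inertia tensor
#' (moments and products); volumes are reported unscaled.  A useful
#' consequence: if every segment's hull volume were inflated by the same
#' factor, the scaled segment masses would still be exact.
#'
#' @param subject_mass measured body mass, kg.
#' @param hull_masses vector of per-segment hull masses (density x hull
#'   volume, after any segment-specific corrections), kg.
#' @return The scalar factor `s`.
#' @examples
#' scaling_factor(73.4, c(40, 25, 15))  # 0.9175
#' @export
scaling_factor <- function(subject_mass, hull_masses) {
  if (!isTRUE(subject_mass > 0)) stop("subject mass must be positive")
  if (length(hull_masses) == 0 || any(hull_masses <= 0))
    stop("all hull masses must be positive")
  subject_mass / sum(hull_masses)
}

#' Subdivide a segment cloud along its longitudinal axis
#'
#' Cuts a segment-frame point cloud by planes perpendicular to the
#' longitudinal axis at given fractions of the segment length, measured from
#' the proximal landmark (the segment-frame origin).  Subdividing before
#' hulling reduces the convex hull's volume overestimation of curved
#' segments; the parts are hulled separately and recombined with
#' [combine_properties()].  Points exactly on a cutting plane go to the
#' proximal (lower) part.
#'
#' @param segment_cloud [point_cloud()] in the segment-anatomical frame.
#' @param fractions cut positions as fractions of segment length (default one
#'   mid-length cut); ignored when `n_parts` is given.
#' @param n_parts alternatively, number of equal-length parts (>= 2).
#' @param axis longitudinal axis, `"z"` or `"x"`.
#' @param seg_length segment length the fractions refer to; default spans the
#'   cloud's extent along the axis.
#' @param from axis coordinate of the proximal end; default the cloud minimum.
#' @param min_points minimum points per part.
#' @return List of [point_cloud()]s, proximal part first.
#' @export
subdivide_along_axis <- function(segment_cloud, fractions = 0.5,
                                 n_parts = NULL, axis = c("z", "x"),
                                 seg_length = NULL, from = NULL,
                                 min_points = 4L) {
  segment_cloud <- as_point_cloud(segment_cloud)
  axis <- match.arg(axis)
  if (!is.null(n_parts)) {
    if (n_parts < 2) stop("n_parts must be >= 2")
    fractions <- seq_len(n_parts - 1) / n_parts
  }
  fractions <- sort(unique(as.numeric(fractions)))
  if (any(fractions <= 0 | fractions >= 1))
    stop("cut fractions must lie strictly between 0 and 1")
  ai <- if (axis == "z") 3L else 1L
  co <- segment_cloud$points[, ai]
  if (is.null(from)) from <- min(co)
  if (is.null(seg_length)) seg_length <- max(co) - from
  if (seg_length <= 0) stop("segment length must be positive")
  cuts <- from + fractions * seg_length
  part_of <- findInterval(co, cuts, left.open = TRUE) + 1L
  out <- lapply(seq_len(length(cuts) + 1L), function(k) {
    p <- segment_cloud$points[part_of == k, , drop = FALSE]
    if (nrow(p) < min_points || .rank3(p) < 3L)
      stop(errorCondition(
        sprintf("subdivision part %d has %d points (need >= %d spanning 3 dimensions)",
                k, nrow(p), min_points),
        class = c("bodyhull_insufficient_points", "error")))
    point_cloud(p, frame = segment_cloud$frame)
  })
  out
}

#' Body segment parameters from a segmented surface scan
#'
#' The package's end-to-end estimator.  Given a world-frame point cloud with
#' landmarks (or pre-cut per-segment clouds), a segmentation configuration
#' and the subject's measured mass, it: (1) cuts the cloud into segments;
#' (2) re-expresses each segment in its anatomical frame; (3) builds the
#' convex hull of each segment -- for segments in `subdivide`, of each
#' longitudinal part, recombined by the parallel-axis composition; (4) forms
#' hull masses as density x hull volume (940 kg/m^3 trunk, 1000 kg/m^3
#' elsewhere by default); (5) multiplies the foot segments' volume, mass and
#' inertia by `foot_factor` (default 0.51, compensating shoe-induced volume
#' overestimation) before mass closure; (6) computes the pro-rata factor
#' `s = mass / sum(hull masses)` and applies it to every segment's mass and
#' full inertia tensor; and (7) derives relative quantities (mass as % of
#' body mass, CoM as % of segment length).  Reported volumes are unscaled
#' hull volumes (foot-corrected for the feet).
#'
#' @param cloud [point_cloud()] in the world frame (scaled and oriented), or
#'   `NULL` when `segment_clouds` is given.
#' @param landmarks [landmark_set()] in the world frame.
#' @param segmentation a [body_segmentation()];
#'   default [default_segmentation()].
#' @param subject a [subject_record()].
#' @param segment_clouds optional named list of per-segment world-frame
#'   clouds, bypassing [cut_by_planes()]; names must match the segmentation.
#' @param subdivide segment groups hulled in longitudinal parts; the default
#'   mirrors the segments with the strongest curvature.  Use `character()`
#'   for whole-segment hulls everywhere.
#' @param cut_fractions fractions of segment length at which subdivided
#'   segments are cut (default one mid-length cut).
#' @param foot_factor multiplicative correction applied to foot volume, mass
#'   and inertia before mass closure; set to 1 for barefoot scans.
#' @return Object of class `body_bsp`: `subject`, `segments` (one row per
#'   segment: name, side, segment_length_m, volume_m3, mass_kg, mass_pct,
#'   com_long_pct, com_t1_pct, com_t2_pct, the six inertia-tensor entries
#'   Ixx..Iyz in kg m^2 about the CoM in segment axes, `subdivided`,
#'   `corrections`), `scaling_factor`, `unscaled_hull_mass_total`, and
#'   per-segment `details` (hull meshes, frames, unscaled properties).
#' @examples
#' body <- generate_default_humanoid(1.70, 65)
#' scan <- sample_surface(body, n_points = 2500, seed = 7)
#' fit <- body_bsp(scan$cloud, scan$landmarks, body$segmentation,
#'                 subject_record("demo", 65, 1.70), foot_factor = 1)
#' fit
#' @export
body_bsp <- function(cloud = NULL, landmarks = NULL,
                     segmentation = default_segmentation(),
                     subject,
                     segment_clouds = NULL,
                     subdivide = c("foot", "shank", "forearm", "hand"),
                     cut_fractions = 0.5,
                     foot_factor = 0.51) {
  stopifnot(inherits(subject, "subject_record"),
            inherits(segmentation, "body_segmentation"))
  if (is.null(landmarks)) landmarks <- segmentation$landmarks
  if (is.null(landmarks)) stop("body_bsp needs landmarks")
  if (is.null(segment_clouds)) {
    if (is.null(cloud)) stop("provide either a whole-body cloud or segment_clouds")
    segment_clouds <- cut_by_planes(cloud, segmentation, landmarks)
  } else {
    missing_ <- setdiff(names(segmentation$segments), names(segment_clouds))
    if (length(missing_))
      stop(sprintf("segment clouds missing for: %s",
                   paste(missing_, collapse = ", ")))
  }

  details <- list()
  for (s in segmentation$segments) {
    seg_cloud <- segment_clouds[[s$name]]
    xf <- segment_frame(s, landmarks)
    cl_s <- transform_cloud(seg_cloud, xf, frame = s$name)
    L <- segment_length(s, landmarks)
    subdivided <- s$group %in% subdivide
    props <- tryCatch({
      if (subdivided) {
        parts <- subdivide_along_axis(cl_s, fractions = cut_fractions,
                                      axis = s$axis, seg_length = L, from = 0)
        combine_properties(lapply(parts, function(p)
          mass_properties(convex_hull(p), s$density)))
      } else {
        mass_properties(convex_hull(cl_s), s$density)
      }
    }, error = function(e) {
      stop(sprintf("segment '%s': %s", s$name, conditionMessage(e)),
           call. = FALSE)
    })
    corrections <- character()
    if (s$group == "foot" && foot_factor != 1) {
      props$volume <- props$volume * foot_factor
      props$mass <- props$mass * foot_factor
      props$inertia_com <- props$inertia_com * foot_factor
      corrections <- sprintf("foot_factor_%g", foot_factor)
    }
    details[[s$name]] <- list(spec = s, frame = xf, length = L,
                              hull_properties = props,
                              subdivided = subdivided,
                              corrections = corrections)
  }

  hull_masses <- vapply(details, function(d) d$hull_properties$mass, 0)
  s_factor <- scaling_factor(subject$mass, hull_masses)

  rows <- lapply(details, function(d) {
    p <- d$hull_properties
    mass <- p$mass * s_factor
    I <- p$inertia_com * s_factor
    rc <- relative_com(p, d$spec, landmarks)
    data.frame(
      name = d$spec$name, side = d$spec$side, group = d$spec$group,
      segment_length_m = d$length, volume_m3 = p$volume, mass_kg = mass,
      mass_pct = 100 * mass / subject$mass,
      com_long_pct = rc[["com_long_pct"]],
      com_t1_pct = rc[["com_t1_pct"]], com_t2_pct = rc[["com_t2_pct"]],
      Ixx = I[1, 1], Iyy = I[2, 2], Izz = I[3, 3],
      Ixy = I[1, 2], Ixz = I[1, 3], Iyz = I[2, 3],
      subdivided = d$subdivided,
      corrections = paste(d$corrections, collapse = ";"),
      stringsAsFactors = FALSE)
  })
  segments <- do.call(rbind, c(rows, list(make.row.names = FALSE)))

  structure(list(subject = subject, segments = segments,
                 scaling_factor = s_factor,
                 unscaled_hull_mass_total = sum(hull_masses),
                 details = details,
                 options = list(subdivide = subdivide,
                                cut_fractions = cut_fractions,
                                foot_factor = foot_factor)),
            class = "body_bsp")
}

#' @export
print.body_bsp <- function(x, digits = 4, ...) {
  cat(sprintf("Body segment parameters: subject '%s' (%.4g kg%s)\n",
              x$subject$id, x$subject$mass,
              if (is.na(x$subject$height)) ""
              else sprintf(", %.2f m", x$subject$height)))
  cat(sprintf("  hull mass before closure: %.4g kg; pro-rata factor s = %.4f\n",
              x$unscaled_hull_mass_total, x$scaling_factor))
  df <- x$segments[, c("name", "mass_kg", "mass_pct", "volume_m3",
                       "com_long_pct")]
  df[-1] <- lapply(df[-1], signif, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.body_bsp <- function(object, ...) {
  structure(list(bsp = object), class = "summary.body_bsp")
}

#' @export
print.summary.body_bsp <- function(x, ...) {
  b <- x$bsp
  print(b)
  cat("\nInertia about the segment CoM, segment-anatomical axes (kg m^2):\n")
  df <- b$segments[, c("name", "Ixx", "Iyy", "Izz", "Ixy", "Ixz", "Iyz")]
  df[-1] <- lapply(df[-1], signif, 4)
  print(df, row.names = FALSE)
  cat(sprintf("\nTotal reported mass: %.10g kg (subject %.10g kg)\n",
              sum(b$segments$mass_kg), b$subject$mass))
  cat(sprintf("Subdivided segments: %s; foot factor %g\n",
              if (any(b$segments$subdivided))
                paste(b$segments$name[b$segments$subdivided], collapse = ", ")
              else "none",
              b$options$foot_factor))
  invisible(x)
}

#' @export
as.data.frame.body_bsp <- function(x, ...) x$segments

#' @export
plot.body_bsp <- function(x, ...) {
  df <- x$segments[order(-x$segments$mass_pct), ]
  op <- graphics::par(mar = c(5, 8, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(rev(df$mass_pct), names.arg = rev(df$name), horiz = TRUE,
                    las = 1, xlab = "segment mass (% of body mass)", ...)
  invisible(x)
}

#' Hull volume overestimation relative to a reference shape
#'
#' Relative volume difference of hull variants with respect to a reference
#' solid, as a percentage: `100 * (V_hull - V_ref) / V_ref`.  This is the
#' statistic used to compare whole-segment convex hulls (CH) against hulls of
#' subdivided segments (CHD) and quantify how much subdivision reduces the
#' systematic overestimation of concave segments.
#'
#' @param reference an [inertial_properties()] (or a bare volume in m^3).
#' @param hull_variants named list of [inertial_properties()] (or volumes).
#' @return Named numeric vector of overestimation percentages.
#' @export
overestimation_report <- function(reference, hull_variants) {
  vol <- function(x) if (inherits(x, "inertial_properties")) x$volume
    else as.numeric(x)
  vref <- vol(reference)
  if (!isTRUE(vref > 0)) stop("reference volume must be positive")
  if (!is.list(hull_variants)) hull_variants <- as.list(hull_variants)
  out <- vapply(hull_variants, function(v) 100 * (vol(v) - vref) / vref, 0)
  if (is.null(names(out)) && length(out))
    names(out) <- paste0("variant", seq_along(out))
  out
}
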