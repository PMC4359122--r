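#' Parametric humanoid test body with closed-form ground truth
#'
#' Builds a 16-segment humanoid from primitive solids in the anatomical
#' standing pose (+z vertical, x anterior, y to the subject's left) with arms
#' abducted horizontally so every joint can be cut by a plane: a spherical
#' head; the trunk as three stacked elliptical-cylinder segments (upper, mid,
#' lower) sharing one cross-section so the whole trunk stays convex; and per
#' side a cylindrical upper arm, truncated-cone forearm, ellipsoidal hand,
#' truncated-cone thigh and shank, and an elliptical-cylinder foot whose
#' longitudinal axis is x.  All dimensions scale with `height`; densities
#' default to 940 kg/m^3 for the trunk segments and 1000 kg/m^3 elsewhere and
#' are then rescaled by one common factor so the true segment masses sum
#' exactly to `total_mass`.
#'
#' Adjacent primitives are separated by small gaps (0.004 x height at limb
#' joints) so that no sampled surface point lies exactly on a cutting plane;
#' landmarks sit at every joint plane.  `bent_segments` swaps the named
#' groups (`"shank"`, `"forearm"`) for volume-matched concave bent cylinders,
#' the package's model of the segment curvature that makes convex hulls
#' overestimate.
#'
#' @param height stature in metres.
#' @param total_mass body mass in kg; the generator's true segment masses sum
#'   to this exactly.
#' @param bent_segments character subset of `c("shank", "forearm")`.
#' @param grid_resolution voxel size (m) for bent-segment inertia truth.
#' @return Object of class `synthetic_body`: `primitives` (one per segment,
#'   named), `landmarks`, `segmentation` (16 segments referencing those
#'   landmarks), `true_properties` (per-segment [inertial_properties()] in
#'   the world frame), `true_total_mass`, `height`.
#' @examples
#' body <- generate_default_humanoid(1.80, 90.3)
#' sum(vapply(body$true_properties, function(p) p$mass, 0))  # 90.3
#' @export
generate_default_humanoid <- function(height, total_mass,
                                      bent_segments = character(),
                                      grid_resolution = 0.001) {
  stopifnot(height > 0, total_mass > 0)
  bad <- setdiff(bent_segments, c("shank", "forearm"))
  if (length(bad))
    stop("bent variants exist only for: shank, forearm")
  H <- height
  down <- rotation_about("x", pi)           # local +z -> world -z
  foot_rot <- rotation_about("y", pi / 2)   # local +z -> world +x

  prim <- list()
  # central column
  prim$head <- primitive_spec("sphere", list(r = 0.063 * H),
    rigid_transform(diag(3), c(0, 0, 0.937 * H)))
  trunk_z <- c(0.522, 0.522 + 0.346 / 3, 0.522 + 2 * 0.346 / 3, 0.868) * H
  for (i in 1:3) {
    nm <- c("lower_trunk", "mid_trunk", "upper_trunk")[i]
    prim[[nm]] <- primitive_spec("cylinder",
      list(a = 0.08 * H, b = 0.13 * H, length = trunk_z[i + 1] - trunk_z[i]),
      rigid_transform(diag(3), c(0, 0, trunk_z[i])), density = 940)
  }
  # limbs, left (+y) then mirrored
  arm_z <- 0.82 * H
  for (sd in c("left", "right")) {
    sgn <- if (sd == "left") 1 else -1
    yaxis <- rigid_transform(
      rotation_about("x", -sgn * pi / 2),   # local +z -> world sgn*y
      c(0, 0, 0))
    prim[[paste0("upper_arm_", sd)]] <- primitive_spec("cylinder",
      list(r = 0.035 * H, length = 0.190 * H),
      rigid_transform(yaxis$R, c(0, sgn * 0.134 * H, arm_z)))
    if ("forearm" %in% bent_segments) {
      # bend in the horizontal plane: local +x (bend direction) -> world +x
      prim[[paste0("forearm_", sd)]] <- primitive_spec("bent_cylinder",
        list(r = 0.027 * H, length = 0.140 * H, bend_angle = 0.35),
        rigid_transform(yaxis$R, c(0, sgn * 0.328 * H, arm_z)))
    } else {
      prim[[paste0("forearm_", sd)]] <- primitive_spec("truncated_cone",
        list(r1 = 0.030 * H, r2 = 0.024 * H, length = 0.150 * H),
        rigid_transform(yaxis$R, c(0, sgn * 0.328 * H, arm_z)))
    }
    prim[[paste0("hand_", sd)]] <- primitive_spec("ellipsoid",
      list(a = 0.028 * H, b = 0.055 * H, c = 0.020 * H),
      rigid_transform(diag(3), c(0, sgn * 0.537 * H, arm_z)))
    prim[[paste0("thigh_", sd)]] <- primitive_spec("truncated_cone",
      list(r1 = 0.055 * H, r2 = 0.042 * H, length = 0.237 * H),
      rigid_transform(down, c(0, sgn * 0.065 * H, 0.518 * H)))
    if ("shank" %in% bent_segments) {
      prim[[paste0("shank_", sd)]] <- primitive_spec("bent_cylinder",
        list(r = 0.035 * H, length = 0.190 * H, bend_angle = 0.35),
        rigid_transform(down, c(0, sgn * 0.065 * H, 0.277 * H)))
    } else {
      prim[[paste0("shank_", sd)]] <- primitive_spec("truncated_cone",
        list(r1 = 0.042 * H, r2 = 0.028 * H, length = 0.210 * H),
        rigid_transform(down, c(0, sgn * 0.065 * H, 0.277 * H)))
    }
    prim[[paste0("foot_", sd)]] <- primitive_spec("cylinder",
      list(a = 0.0315 * H, b = 0.032 * H, length = 0.150 * H),
      rigid_transform(foot_rot, c(-0.045 * H, sgn * 0.065 * H, 0.0315 * H)))
  }

  lm <- list(
    vertex = c(0, 0, 1.000), floor = c(0, 0, 0),
    neck = c(0, 0, 0.870), xiphoid = c(0, 0, 0.522 + 2 * 0.346 / 3),
    omphalion = c(0, 0, 0.522 + 0.346 / 3), mid_hip = c(0, 0, 0.520))
  for (sd in c("left", "right")) {
    sgn <- if (sd == "left") 1 else -1
    lm[[paste0("shoulder_", sd)]]  <- c(0, sgn * 0.132, 0.82)
    lm[[paste0("elbow_", sd)]]     <- c(0, sgn * 0.326, 0.82)
    lm[[paste0("wrist_", sd)]]     <- c(0, sgn * 0.480, 0.82)
    lm[[paste0("dactylion_", sd)]] <- c(0, sgn * 0.592, 0.82)
    lm[[paste0("hip_", sd)]]       <- c(0, sgn * 0.065, 0.520)
    lm[[paste0("knee_", sd)]]      <- c(0, sgn * 0.065, 0.279)
    lm[[paste0("ankle_", sd)]]     <- c(0, sgn * 0.065, 0.065)
    lm[[paste0("heel_", sd)]]      <- c(-0.045, sgn * 0.065, 0.0315)
    lm[[paste0("toe_", sd)]]       <- c(0.105, sgn * 0.065, 0.0315)
  }
  landmarks <- landmark_set(lapply(lm, function(v) v * H))

  seg <- humanoid_segmentation(landmarks, split_trunk = TRUE)
  # density closure: one common factor brings true total mass to target
  props0 <- lapply(names(prim), function(nm)
    analytic_properties(prim[[nm]], grid_resolution = grid_resolution))
  names(props0) <- names(prim)
  k <- total_mass / sum(vapply(props0, `[[`, 0, "mass"))
  prim <- lapply(prim, function(p) { p$density <- p$density * k; p })
  props <- lapply(names(props0), function(nm) {
    p0 <- props0[[nm]]
    inertial_properties(volume = p0$volume, mass = p0$mass * k, com = p0$com,
                        inertia_com = p0$inertia_com * k, frame = "world")
  })
  names(props) <- names(props0)
  # keep configuration order
  ord <- names(seg$segments)
  structure(list(primitives = prim[ord], landmarks = landmarks,
                 segmentation = seg, true_properties = props[ord],
                 true_total_mass = total_mass, height = height),
            class = "synthetic_body")
}

#' @export
print.synthetic_body <- function(x, ...) {
  cat(sprintf("Synthetic humanoid: %d segments, height %.2f m, true mass %.4g kg\n",
              length(x$primitives), x$height, x$true_total_mass))
  invisible(x)
}

#' Landmark-driven segmentation configurations
#'
#' `humanoid_segmentation()` builds the cutting configuration matching
#' [generate_default_humanoid()]'s landmark names; with `split_trunk = TRUE`
#' the trunk is three segments (16 total), otherwise one (14 total, the
#' decomposition reported for real scans).  `default_segmentation()` is the
#' 14-segment variant and is the package default for scanned subjects; it
#' requires the same landmark names (vertex, neck, mid_hip, shoulders,
#' elbows, wrists, dactylions, hips, knees, ankles, heels, toes).
#'
#' Transverse joint cuts assign boundary points to the proximal segment;
#' trunk densities default to 940 kg/m^3 (lungs included in the enclosed
#' volume), all other segments to 1000 kg/m^3.
#'
#' @param landmarks optional [landmark_set()] stored with the configuration.
#' @param split_trunk split the trunk into upper/mid/lower segments.
#' @param trunk_density,other_density default segment densities, kg/m^3.
#' @return A [body_segmentation()].
#' @export
humanoid_segmentation <- function(landmarks = NULL, split_trunk = FALSE,
                                  trunk_density = 940, other_density = 1000) {
  up <- c("mid_hip", "neck")           # +z
  left <- c("shoulder_right", "shoulder_left")  # +y
  fwd <- c("heel_left", "toe_left")    # +x
  segs <- list()
  for (sd in c("left", "right")) {
    pos_side <- if (sd == "left") "+" else "-"
    neg_side <- if (sd == "left") "-" else "+"
    sh <- paste0("shoulder_", sd); el <- paste0("elbow_", sd)
    wr <- paste0("wrist_", sd); da <- paste0("dactylion_", sd)
    segs[[paste0("hand_", sd)]] <- segment_spec(
      paste0("hand_", sd), sd, other_density,
      list(plane(wr, left, pos_side)),
      proximal = wr, distal = da)
    segs[[paste0("forearm_", sd)]] <- segment_spec(
      paste0("forearm_", sd), sd, other_density,
      list(plane(el, left, pos_side), plane(wr, left, neg_side)),
      proximal = el, distal = wr)
    segs[[paste0("upper_arm_", sd)]] <- segment_spec(
      paste0("upper_arm_", sd), sd, other_density,
      list(plane(sh, left, pos_side), plane(el, left, neg_side)),
      proximal = sh, distal = el)
  }
  segs$head <- segment_spec("head", "central", other_density,
    list(plane("neck", up, "+")), proximal = "neck", distal = "vertex")
  trunk_band <- list(plane("shoulder_left", left, "-"),
                     plane("shoulder_right", left, "+"))
  if (split_trunk) {
    segs$upper_trunk <- segment_spec("upper_trunk", "central", trunk_density,
      c(list(plane("neck", up, "-"), plane("xiphoid", up, "+")), trunk_band),
      proximal = "neck", distal = "xiphoid")
    segs$mid_trunk <- segment_spec("mid_trunk", "central", trunk_density,
      c(list(plane("xiphoid", up, "-"), plane("omphalion", up, "+")), trunk_band),
      proximal = "xiphoid", distal = "omphalion")
    segs$lower_trunk <- segment_spec("lower_trunk", "central", trunk_density,
      c(list(plane("omphalion", up, "-"), plane("mid_hip", up, "+")), trunk_band),
      proximal = "omphalion", distal = "mid_hip")
  } else {
    segs$trunk <- segment_spec("trunk", "central", trunk_density,
      c(list(plane("neck", up, "-"), plane("mid_hip", up, "+")), trunk_band),
      proximal = "neck", distal = "mid_hip")
  }
  for (sd in c("left", "right")) {
    pos_side <- if (sd == "left") "+" else "-"
    kn <- paste0("knee_", sd); an <- paste0("ankle_", sd)
    segs[[paste0("thigh_", sd)]] <- segment_spec(
      paste0("thigh_", sd), sd, other_density,
      list(plane("mid_hip", up, "-"), plane(kn, up, "+"),
           plane("mid_hip", left, pos_side)),
      proximal = paste0("hip_", sd), distal = kn)
    segs[[paste0("shank_", sd)]] <- segment_spec(
      paste0("shank_", sd), sd, other_density,
      list(plane(kn, up, "-"), plane(an, up, "+"),
           plane("mid_hip", left, pos_side)),
      proximal = kn, distal = an)
    segs[[paste0("foot_", sd)]] <- segment_spec(
      paste0("foot_", sd), sd, other_density,
      list(plane(an, up, "-"), plane("mid_hip", left, pos_side)),
      proximal = paste0("heel_", sd), distal = paste0("toe_", sd),
      axis = "x")
  }
  body_segmentation(segs, landmarks)
}

#' @rdname humanoid_segmentation
#' @export
default_segmentation <- function(landmarks = NULL, trunk_density = 940,
                                 other_density = 1000) {
  humanoid_segmentation(landmarks, split_trunk = FALSE,
                        trunk_density = trunk_density,
                        other_density = other_density)
}

#' Ground-truth properties aggregated to a segmentation's segments
#'
#' Maps a synthetic body's per-segment truth onto another segmentation (e.g.
#' the 14-segment [default_segmentation()], whose single trunk is the
#' composition of the generator's three trunk thirds), recombining parts with
#' [combine_properties()].
#'
#' @param body a `synthetic_body`.
#' @param seg target [body_segmentation()].
#' @return Named list of [inertial_properties()], one per target segment.
#' @export
true_segment_properties <- function(body, seg) {
  out <- lapply(seg$segments, function(s) {
    if (s$name == "trunk") {
      combine_properties(body$true_properties[
        c("upper_trunk", "mid_trunk", "lower_trunk")])
    } else {
      p <- body$true_properties[[s$name]]
      if (is.null(p))
        stop(sprintf("no ground truth for segment '%s'", s$name))
      p
    }
  })
  names(out) <- names(seg$segments)
  out
}
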