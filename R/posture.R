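# Sagittal-plane frame: x anterior, y up, lengths in metres, angles in
# degrees with flexion (anterior rotation) positive.  A segment inclined by
# theta has long axis (sin theta, cos theta) and anterior unit
# (cos theta, -sin theta); the flexion-positive rotation is the clockwise one
# in this frame.

deg2rad <- function(d) d * pi / 180

# clockwise (flexion-positive) rotation of 2-vector(s); p may be a 2-column matrix
rot_flex <- function(p, deg) {
  a <- deg2rad(deg)
  R <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2)
  if (is.matrix(p)) p %*% t(R) else as.vector(R %*% p)
}

axis_unit <- function(deg) c(sin(deg2rad(deg)), cos(deg2rad(deg)))
anterior_unit <- function(deg) c(cos(deg2rad(deg)), -sin(deg2rad(deg)))

#' Fixed world-frame lumbar vertebral orientations of a Roussouly type
#'
#' The five vertebral inclinations (L1..L5, degrees, flexion positive) that
#' define the lumbar shape of each type.  They are held fixed for a type
#' regardless of sacral slope, pelvic incidence and SVA.
#'
#' @inheritParams spinopelvic_params
#' @return Named numeric vector `c(L1=, L2=, L3=, L4=, L5=)`.
#' @export
lumbar_orientations <- function(rt, constants = default_constants()) {
  rt_entry(rt, constants)$vertebral_rotation
}

#' Anterior rotation of the sacrum-pelvis segment realising a sacral slope
#'
#' The sacrum-pelvis segment carries a built-in default endplate inclination;
#' the target slope is realised by rotating the whole segment (joints and
#' muscle attachment points included) anteriorly by the difference.
#'
#' @param ss_target Target sacral slope, degrees.
#' @param ss_default Default endplate inclination of the unrotated segment,
#'   degrees (30 by default).
#' @param strict If `TRUE`, require `ss_target` within the union of the
#'   design ranges (25 to 55 degrees).
#' @return Degrees of anterior rotation to apply (negative = posterior).
#' @export
sacrum_rotation <- function(ss_target, ss_default = 30, strict = TRUE) {
  if (strict && (ss_target < 25 || ss_target > 55)) {
    stop("sacral slope ", ss_target, " outside the design union [25, 55]; ",
         "use strict = FALSE for exploratory values")
  }
  ss_target - ss_default
}

#' Horizontal hip-joint shift realising a pelvic incidence
#'
#' Pelvic incidence is the angle between the caudally-directed normal of the
#' sacral endplate at its midpoint and the line from that midpoint to the hip
#' joint centre.  The hip sits a fixed vertical drop below the endplate
#' midpoint; only its horizontal coordinate is moved.  With the signed angle
#' of each direction from the downward vertical (anterior positive), the
#' normal lies at -SS and the hip line at atan(x / drop), so
#' `x = drop * tan(PI - SS) = drop * tan(PT)`.
#'
#' @param pi_target Target pelvic incidence, degrees.
#' @param ss Sacral slope of the configuration, degrees.
#' @param hip_drop Vertical drop from endplate midpoint to hip centre, metres.
#' @return Horizontal hip offset from below the endplate midpoint, metres,
#'   anterior positive.
#' @export
hip_offset_for_pi <- function(pi_target, ss, hip_drop = 0.09) {
  if (hip_drop <= 0) stop("hip vertical drop must be strictly positive")
  pt <- pi_target - ss
  if (abs(pt) >= 90) {
    stop("pelvic incidence ", pi_target,
         " is geometrically unreachable with a horizontal hip shift (|PI - SS| must be < 90)")
  }
  hip_drop * tan(deg2rad(pt))
}

#' Angle between the anterior axes of L5 and S1
#'
#' The L5 anterior axis is parallel to its upper endplate (inclination fixed
#' by the lumbar type); the S1 anterior axis is parallel to the sacral
#' endplate (inclination SS).  The absolute angle between them explains why
#' the anterior shear component differs between the L4L5 and L5S1 levels.
#'
#' @inheritParams spinopelvic_params
#' @param strict Passed to range validation of `ss`.
#' @return Degrees, non-negative.
#' @export
anterior_axis_angle_difference <- function(rt, ss, constants = default_constants(),
                                           strict = TRUE) {
  entry <- rt_entry(rt, constants)
  if (strict && (ss < entry$ss[1] || ss > entry$ss[2])) {
    stop(sprintf("sacral slope %g outside %s design range [%g, %g]",
                 ss, rt, entry$ss[1], entry$ss[2]))
  }
  abs(ss - unname(entry$vertebral_rotation["L5"]))
}

#' Wedge (extension) angle between L5 and S1
#'
#' Signed relative orientation of L5 over the sacral endplate under the
#' flexion-positive convention: `L5 orientation - SS`.  Negative values are
#' extension; standing lordotic alignments give values between -43 and -13
#' degrees over the design grid.
#'
#' @inheritParams anterior_axis_angle_difference
#' @return Degrees (negative = extension).
#' @export
l5s1_wedge_angle <- function(rt, ss, constants = default_constants(),
                             strict = TRUE) {
  entry <- rt_entry(rt, constants)
  if (strict && (ss < entry$ss[1] || ss > entry$ss[2])) {
    stop(sprintf("sacral slope %g outside %s design range [%g, %g]",
                 ss, rt, entry$ss[1], entry$ss[2]))
  }
  unname(entry$vertebral_rotation["L5"]) - ss
}

#' Lumbar lordosis between T12 and S1
#'
#' Lordosis is measured between the T12 endplate (carried by the thoracic
#' segment) and the sacral endplate, positive in lordosis:
#' `LL = SS - T12 inclination` under the flexion-positive convention.
#'
#' @param t12_inclination World inclination of the T12 endplate, degrees.
#' @param ss Sacral slope, degrees.
#' @return Degrees, lordosis positive.
#' @export
compute_ll <- function(t12_inclination, ss) ss - t12_inclination

# -------------------------------------------------------------------------
# Posture assembly

# Chain of joint positions for given vertebral orientations; L5S1 at origin.
lumbar_joint_positions <- function(orient, lengths) {
  lv <- c("L5", "L4", "L3", "L2", "L1")
  pos <- matrix(0, 6, 2, dimnames = list(c("L5S1", "L4L5", "L3L4", "L2L3",
                                           "L1L2", "T12L1"), c("x", "y")))
  p <- c(0, 0)
  for (i in seq_along(lv)) {
    p <- p + lengths[lv[i]] * axis_unit(orient[lv[i]])
    pos[i + 1, ] <- p
  }
  pos
}

#' Measure the sagittal vertical axis of a posture
#'
#' Forward measurement: horizontal offset (centimetres, anterior positive)
#' from the C7 marker plumb-line to the posterior-superior corner of the
#' sacral endplate.
#'
#' @param posture A `posture_config`.
#' @return SVA in centimetres.
#' @export
measure_sva <- function(posture) {
  100 * (posture$landmarks["C7", "x"] -
           posture$landmarks["sacral_corner", "x"])
}

#' Measure the sacral slope of a posture
#'
#' Forward measurement from the stored endplate landmarks (posterior corner
#' to midpoint), independent of the parameters the posture was built from.
#'
#' @param posture A `posture_config`.
#' @return Degrees.
#' @export
measure_ss <- function(posture) {
  d <- posture$landmarks["endplate_mid", ] - posture$landmarks["sacral_corner", ]
  unname(atan2(-d["y"], d["x"]) * 180 / pi)
}

#' Measure the pelvic incidence of a posture
#'
#' Forward measurement: signed angle between the caudal normal of the sacral
#' endplate at its midpoint (from the stored endplate landmarks) and the
#' midpoint-to-hip line, degrees.
#'
#' @param posture A `posture_config`.
#' @return Degrees.
#' @export
measure_pi <- function(posture) {
  mid <- posture$landmarks["endplate_mid", ]
  hip <- posture$landmarks["hip", ]
  v <- hip - mid
  # angles from the downward vertical, anterior positive
  ang_hip <- atan2(v["x"], -v["y"]) * 180 / pi
  ang_normal <- -measure_ss(posture)
  unname(ang_hip - ang_normal)
}

#' Thoracic rotation achieving a target SVA
#'
#' Solves for the rotation of the thoracic segment about T12L1 such that the
#' C7 plumb-line offset to the posterior-superior sacral corner equals the
#' target, by bracketed 1-D root finding (the C7 horizontal position is
#' continuous and strictly monotone in the rotation over the bracket).
#'
#' @param target_sva Target SVA, centimetres.
#' @param t12l1 World position of the T12L1 joint (x, y), metres.
#' @param corner_x World x of the posterior-superior sacral corner, metres.
#' @param thorax_length T12L1-to-C7 distance, metres.
#' @param limit_deg Bracket half-width, degrees.
#' @return Rotation in degrees, flexion positive.
#' @export
thoracic_rotation_for_sva <- function(target_sva, t12l1, corner_x,
                                      thorax_length, limit_deg = 45) {
  resid <- function(phi) {
    c7x <- t12l1[1] + thorax_length * sin(deg2rad(phi))
    100 * (c7x - corner_x) - target_sva
  }
  lo <- resid(-limit_deg); hi <- resid(limit_deg)
  if (lo > 0 || hi < 0) {
    stop(sprintf(
      "target SVA %.2f cm unreachable within +/-%g deg thoracic rotation; achievable interval [%.2f, %.2f] cm",
      target_sva, limit_deg, target_sva + lo, target_sva + hi))
  }
  stats::uniroot(resid, c(-limit_deg, limit_deg), tol = 1e-10)$root
}

#' Build the standing posture for a spinopelvic parameter point
#'
#' Applies, in order: sacral rotation about the L5S1 joint to the target
#' sacral slope; horizontal hip shift to the target pelvic incidence; fixed
#' lumbar vertebral orientations of the type, each vertebra rotated about its
#' inferior joint (the chain above is carried along); thoracic rotation about
#' T12L1 solved to realise the target SVA, with the head counter-rotated to
#' keep its default (upright) orientation and the arms hanging vertically
#' from the shoulders.
#'
#' @param params A `spinopelvic_params` object (or a one-row data.frame slice
#'   from [enumerate_sweep()]).
#' @param constants Model constants.
#' @return An object of class `posture_config`: segment orientations
#'   (degrees), joint positions, landmark positions, segment COM positions,
#'   lumbar lordosis and applied thoracic rotation.
#' @export
build_posture <- function(params, constants = default_constants()) {
  if (is.data.frame(params)) {
    params <- spinopelvic_params(params$rt, params$ss, params$pi,
                                 params$sva_condition, constants)
  }
  geo <- constants$geometry
  des <- constants$design

  ## sacrum-pelvis: rotate about L5S1 (origin) from the default inclination
  sac_rot <- sacrum_rotation(params$ss, des$ss_default, strict = FALSE)
  ep_ant <- anterior_unit(params$ss)      # endplate anterior direction
  mid <- c(0, 0)                          # endplate midpoint == L5S1 joint
  corner <- mid - (geo$endplate_width / 2) * ep_ant  # posterior-superior corner

  ## hip: fixed vertical drop below the midpoint, horizontal shift for PI
  hip <- c(hip_offset_for_pi(params$pi, params$ss, geo$hip_drop), -geo$hip_drop)

  ## lumbar chain: fixed world orientations per type
  orient <- lumbar_orientations(params$rt, constants)
  joints <- lumbar_joint_positions(orient, geo$lumbar_length)

  ## thorax: rotation about T12L1 solves the SVA target
  phi <- thoracic_rotation_for_sva(params$sva, joints["T12L1", ], corner[1],
                                   geo$thorax_length, geo$thoracic_rot_limit)
  t12l1 <- joints["T12L1", ]
  c7 <- t12l1 + geo$thorax_length * axis_unit(phi)

  ## segment COMs ------------------------------------------------------
  lv <- c("L5", "L4", "L3", "L2", "L1")
  jseq <- c("L5S1", "L4L5", "L3L4", "L2L3", "L1L2", "T12L1")
  com <- matrix(NA_real_, 8, 2,
                dimnames = list(c(lv, "thorax", "head_neck", "arms"), c("x", "y")))
  for (i in seq_along(lv)) {
    midpt <- (joints[jseq[i], ] + joints[jseq[i + 1], ]) / 2
    com[lv[i], ] <- midpt +
      geo$lumbar_com_anterior[lv[i]] * anterior_unit(orient[lv[i]])
  }
  com["thorax", ] <- t12l1 + geo$thorax_com_height * axis_unit(phi) +
    geo$thorax_com_anterior * anterior_unit(phi)
  shoulder <- t12l1 + geo$shoulder_height * axis_unit(phi) +
    geo$shoulder_anterior * anterior_unit(phi)
  ## head counter-rotated to default orientation: COM rises vertically off C7
  com["head_neck", ] <- c7 + geo$head_com_height * axis_unit(0) +
    geo$head_com_anterior * anterior_unit(0)
  ## arms hang plumb from the shoulders (vertical load at the shoulder x)
  com["arms", ] <- c(shoulder[1], shoulder[2] - 0.25)

  t12_incl <- phi + geo$t12_offset_deg
  landmarks <- rbind(endplate_mid = mid, sacral_corner = corner,
                     hip = hip, C7 = c7, shoulder = shoulder)
  colnames(landmarks) <- c("x", "y")

  structure(list(
    params = params,
    segment_orientations = c(sacrum_pelvis = params$ss,
                             orient["L5"], orient["L4"], orient["L3"],
                             orient["L2"], orient["L1"],
                             thorax = phi, head = 0),
    sacrum_rotation = sac_rot,
    thoracic_rotation_deg = phi,
    joints = joints,
    landmarks = landmarks,
    com_positions = com,
    t12_inclination = t12_incl,
    ll_deg = compute_ll(t12_incl, params$ss)
  ), class = "posture_config")
}

#' @export
print.posture_config <- function(x, ...) {
  cat(sprintf("<posture_config> %s  SS %g°  PI %g°  SVA %s (%g cm)  LL %.1f°  thorax %.2f°\n",
              x$params$rt, x$params$ss, x$params$pi, x$params$sva_condition,
              x$params$sva, x$ll_deg, x$thoracic_rotation_deg))
  invisible(x)
}

#' Export a posture as JSON
#'
#' Writes orientations, joint, landmark and COM positions for plotting or
#' debugging.
#'
#' @param posture A `posture_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_posture_json <- function(posture, path) {
  asrows <- function(m) {
    d <- as.data.frame(m)
    d$name <- rownames(m)
    d[, c("name", "x", "y")]
  }
  obj <- list(
    params = unclass(posture$params),
    segment_orientations_deg = as.list(posture$segment_orientations),
    thoracic_rotation_deg = posture$thoracic_rotation_deg,
    ll_deg = posture$ll_deg,
    joints = asrows(posture$joints),
    landmarks = asrows(posture$landmarks),
    com_positions = asrows(posture$com_positions)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
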