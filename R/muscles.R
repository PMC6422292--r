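# Lumped sagittal trunk actuators.
#
# Each fascicle is a straight tensile element between a caudal attachment
# (origin) and a cranial attachment (insertion), bilateral pairs summed into
# one sagittal actuator.  Moment arms follow the extension-positive
# convention: tension producing an extension (posterior) moment about a
# joint has a positive arm there.

#' Build the lumped muscle set for a posture
#'
#' Default set (bilateral pairs summed into single sagittal actuators):
#' * multifidus group: five sacral fascicles fanning out to each lumbar
#'   level plus six deep single-joint fascicles (rotatores-like, with a
#'   stronger semispinalis-like one at the thoracolumbar junction) — small
#'   posterior offsets;
#' * erector spinae / longissimus: one sacrum-to-thorax actuator crossing
#'   every lumbar joint, with moment arms growing cranially;
#' * rectus abdominis: one pubis-to-lower-thorax flexor with a large
#'   anterior offset (the straight line stands for the abdominal-wall path);
#' * psoas major: five per-vertebra flexor fascicles running to the pelvis
#'   with small anterior offsets.
#'
#' Attachment points rotate rigidly with their owning segments, so sacral
#' and pelvic attachments move with sacral slope.  Grouped muscle forces are
#' reported as sums over each group's fascicles.
#'
#' The set must leave every lumbar joint with at least one extensor and one
#' flexor crossing it, otherwise some gravity moments are unbalanceable and
#' an error is raised.
#'
#' @param posture A `posture_config`.
#' @param constants Model constants.
#' @return Object of class `muscle_set`: data.frame of fascicles with world
#'   attachment points, strengths and spanned joints.
#' @export
build_muscle_set <- function(posture, constants = default_constants()) {
  mus <- constants$muscles
  geo <- constants$geometry
  orient <- posture$segment_orientations
  joints <- posture$joints
  sac_rot <- posture$sacrum_rotation
  phi <- posture$thoracic_rotation_deg
  t12l1 <- joints["T12L1", ]

  sacrum_pt <- function(local) rot_flex(local, sac_rot)          # about L5S1 origin
  thorax_pt <- function(local) t12l1 + rot_flex(local, phi)
  # point on vertebra lv at perpendicular offset `off` (anterior +) and
  # height fraction `frac` of the segment length
  vert_pt <- function(lv, off, frac) {
    jinf <- switch(lv, L5 = "L5S1", L4 = "L4L5", L3 = "L3L4",
                   L2 = "L2L3", L1 = "L1L2")
    joints[jinf, ] + frac * geo$lumbar_length[lv] * axis_unit(orient[lv]) +
      off * anterior_unit(orient[lv])
  }

  fas <- list()
  add <- function(name, group, origin, insertion, strength, spanned) {
    fas[[length(fas) + 1]] <<- list(
      name = name, group = group,
      ox = origin[1], oy = origin[2], ix = insertion[1], iy = insertion[2],
      strength = strength, spanned = paste(spanned, collapse = ","))
  }

  ## multifidus: sacral fascicles fanning out to each lumbar spinous level
  ## (spanning every joint between the sacrum and the insertion vertebra),
  ## plus small deep single-joint fascicles (rotatores-like) that guarantee
  ## per-joint extension controllability; all reported in the multifidus
  ## group.
  mf <- mus$multifidus
  off <- -mf$posterior_offset
  lv <- c("L5", "L4", "L3", "L2", "L1")
  jn <- c("L5S1", "L4L5", "L3L4", "L2L3", "L1L2")
  for (k in seq_along(lv)) {
    add(paste0("MF_", lv[k]), "multifidus", sacrum_pt(mf$sacral_origin),
        vert_pt(lv[k], off, 0.5), mf$strength, jn[seq_len(k)])
  }
  pairs <- list(c("L5", "L4", "L4L5"), c("L4", "L3", "L3L4"),
                c("L3", "L2", "L2L3"), c("L2", "L1", "L1L2"))
  add("MFd_L5S1", "multifidus", sacrum_pt(mf$sacral_origin),
      vert_pt("L5", off, 0.4), mf$deep_strength, "L5S1")
  for (p in pairs) {
    add(paste0("MFd_", p[3]), "multifidus",
        vert_pt(p[1], off, 0.4), vert_pt(p[2], off, 0.6), mf$deep_strength, p[3])
  }
  add("MFd_T12L1", "multifidus", vert_pt("L1", off - 0.010, 0.4),
      thorax_pt(c(off - 0.010, 0.03)), mf$t12_strength, "T12L1")

  ## erector spinae / longissimus: sacrum to thorax, crosses all joints
  es <- mus$erector_spinae
  add("ES", "erector_spinae", sacrum_pt(es$sacral_origin),
      thorax_pt(es$thorax_insertion), es$strength, joint_labels())

  ## rectus abdominis: pubis to lower thorax, crosses all joints
  ra <- mus$rectus_abdominis
  add("RA", "rectus_abdominis", sacrum_pt(ra$pelvis_origin),
      thorax_pt(ra$thorax_insertion), ra$strength, joint_labels())

  ## psoas major: per-vertebra flexor fascicles running to the pelvis with
  ## small anterior offsets (spanning every joint between the vertebra and
  ## the sacrum; does not cross T12L1)
  ps <- mus$psoas
  for (k in seq_along(lv)) {
    add(paste0("PS_", lv[k]), "psoas", sacrum_pt(ps$pelvis_insertion),
        vert_pt(lv[k], ps$anterior_offset, 0.5), ps$strength, jn[seq_len(k)])
  }

  df <- do.call(rbind, lapply(fas, function(f) as.data.frame(f, stringsAsFactors = FALSE)))
  set <- structure(list(fascicles = df,
                        abdominal_pressure = mus$abdominal_pressure),
                   class = "muscle_set")
  check_coverage(set, posture)
  set
}

check_coverage <- function(set, posture) {
  for (j in joint_labels()) {
    arms <- fascicle_arms(set, j, posture)
    arms <- arms[arms != 0]
    if (!any(arms > 0) || !any(arms < 0)) {
      stop("muscle set leaves joint ", j,
           " without both an extensor and a flexor crossing it")
    }
  }
  invisible(set)
}

#' Line of action of a fascicle
#'
#' @param fascicle One row of the fascicle table of a `muscle_set`.
#' @param posture Unused placeholder (attachments are already resolved to
#'   world coordinates when the set is built); kept for interface symmetry.
#' @return List with `origin`, `insertion` (world points) and `unit`
#'   (origin-to-insertion unit vector).
#' @export
line_of_action <- function(fascicle, posture = NULL) {
  o <- c(fascicle$ox, fascicle$oy)
  i <- c(fascicle$ix, fascicle$iy)
  d <- i - o
  len <- sqrt(sum(d^2))
  if (len < 1e-12) {
    stop("degenerate fascicle geometry: coincident attachment points for ",
         fascicle$name)
  }
  list(origin = o, insertion = i, unit = d / len)
}

#' Signed moment arm of a fascicle about a joint
#'
#' Signed perpendicular distance from the joint centre to the straight line
#' of action; positive when unit tension produces an extension (posterior)
#' moment.  Joints not spanned by the fascicle return 0 (no contribution).
#'
#' @param fascicle One row of the fascicle table.
#' @param joint Joint label.
#' @param posture A `posture_config` (for joint positions).
#' @return Metres, signed.
#' @export
moment_arm <- function(fascicle, joint, posture) {
  if (!joint %in% strsplit(fascicle$spanned, ",")[[1]]) return(0)
  loa <- line_of_action(fascicle)
  p <- posture$joints[joint, ]
  # pull direction on the superincumbent free body: cranial -> caudal
  u <- -loa$unit
  d <- loa$insertion - p
  # extension-positive planar moment: -(d x F)_z with flexion positive
  unname(d[1] * u[2] - d[2] * u[1])
}

fascicle_arms <- function(set, joint, posture) {
  vapply(seq_len(nrow(set$fascicles)), function(i) {
    moment_arm(set$fascicles[i, ], joint, posture)
  }, numeric(1))
}

#' Export resolved muscle geometry as JSON
#'
#' Writes the world-frame attachment points, strengths and spanned joints of
#' every fascicle in a posture, for plotting or debugging.
#'
#' @param muscles A `muscle_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_muscle_geometry_json <- function(muscles, path) {
  jsonlite::write_json(muscles$fascicles, path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
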