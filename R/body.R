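# Weighted rigid-segment chain and free-body gravity queries.
#
# Gravity moments use the flexion-positive convention: a superincumbent COM
# anterior of a joint produces a positive (flexion) moment about it.

# cranial rank of each balanced joint, caudal = 1
joint_rank <- function() {
  stats::setNames(seq(6, 1), joint_labels())
}

# joints a segment lies strictly above (by name)
segment_min_rank <- function() {
  c(L5 = 1, L4 = 2, L3 = 3, L2 = 4, L1 = 5,
    thorax = 6, head_neck = 6, arms = 6)
}

#' Assemble the weighted rigid-segment chain of a posture
#'
#' Attaches the configured mass fractions of the total body mass to the
#' segment COM positions of the posture.  The sacrum-pelvis and legs are the
#' grounded side; the suprapelvic chain carries the five lumbar slices, the
#' thorax, the head+neck (counter-rotated) and the arms entering as vertical
#' loads hanging from the shoulders.
#'
#' @param posture A `posture_config`.
#' @param constants Model constants.
#' @return Object of class `body_chain` with the per-segment table, joint
#'   positions, total suprapelvic mass and gravity constant.
#' @export
build_chain <- function(posture, constants = default_constants()) {
  fr <- constants$masses$fractions
  if (abs(sum(fr) - 1) > 1e-9) {
    stop("segment mass fractions must sum to 1 (got ",
         format(sum(fr), digits = 12), ")")
  }
  total <- constants$masses$total
  segs <- rownames(posture$com_positions)  # L5..L1, thorax, head_neck, arms
  mass <- numeric(length(segs))
  names(mass) <- segs
  for (s in segs) mass[s] <- total * unname(fr[s])
  ground_mass <- total * sum(fr[c("pelvis", "legs")])
  segments <- data.frame(
    name = segs,
    mass = unname(mass),
    com_x = posture$com_positions[, "x"],
    com_y = posture$com_positions[, "y"],
    min_rank = unname(segment_min_rank()[segs]),
    stringsAsFactors = FALSE
  )
  rownames(segments) <- NULL
  structure(list(
    segments = segments,
    joints = posture$joints,
    ground_mass = ground_mass,
    total_mass = ground_mass + sum(segments$mass),
    total_suprapelvic_mass = sum(segments$mass),
    gravity = constants$gravity
  ), class = "body_chain")
}

#' Gravity load of the body above a lumbar joint
#'
#' Free-body query: vector sum of the weights of all segments strictly above
#' the given joint, and their net moment about the joint centre
#' (flexion positive).
#'
#' @param chain A `body_chain`.
#' @param level Joint label, one of [joint_labels()].
#' @return List with `force` (N, world x/y), `moment` (N m, flexion
#'   positive) and `mass_above` (kg).
#' @export
superincumbent_load <- function(chain, level) {
  rk <- joint_rank()
  if (length(level) != 1 || !level %in% names(rk)) {
    stop("unknown joint level '", level, "'; valid: ",
         paste(joint_labels(), collapse = ", "))
  }
  above <- chain$segments[chain$segments$min_rank >= rk[level], ]
  g <- chain$gravity
  jx <- chain$joints[level, "x"]
  m_total <- sum(above$mass)
  # vertical gravity: flexion moment = sum m g (x_com - x_joint)
  moment <- g * sum(above$mass * (above$com_x - jx))
  list(force = c(x = 0, y = -g * m_total), moment = unname(moment),
       mass_above = m_total)
}
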