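#' Default model constants
#'
#' Returns the full set of editable constants driving the simulation: the
#' per-Roussouly-type design ranges (sacral slope, pelvic incidence, sagittal
#' vertical axis) and fixed vertebral orientations; the skeletal dimensions of
#' the default 1.76 m / 75 kg body; the segment mass fractions and per-level
#' anterior centre-of-mass offsets of the lumbar vertebrae; and the lumped
#' muscle actuator geometry and strengths.
#'
#' All lengths are in metres, masses in kilograms, angles in degrees with
#' flexion (anterior rotation) positive, SVA in centimetres with anterior
#' positive.  The values can be edited freely, or loaded from a YAML file via
#' [read_constants()]; the geometric worked examples of the design grid (wedge
#' angles, axis differences, sweep cardinality) do not depend on them.
#'
#' @return A nested list with elements `design`, `geometry`, `masses`,
#'   `muscles`, `solver`, `gravity`, `body_height`.
#' @export
default_constants <- function() {
  list(
    ## Design grid: per-type parameter ranges and fixed world-frame vertebral
    ## inclinations (L1..L5, flexion positive).
    design = list(
      ss_default = 30,
      rt = list(
        RT1 = list(ss = c(25, 35), pi = c(30, 50),
                   sva = c(back = -3.0, med = 3.0, front = 9.0),
                   vertebral_rotation = c(L1 = -17, L2 = -22, L3 = -27,
                                          L4 = -19, L5 = -8)),
        RT2 = list(ss = c(25, 35), pi = c(30, 50),
                   sva = c(back = -4.9, med = 1.1, front = 7.1),
                   vertebral_rotation = c(L1 = -12, L2 = -13, L3 = -8,
                                          L4 = -1, L5 = 9)),
        RT3 = list(ss = c(35, 45), pi = c(40, 60),
                   sva = c(back = -4.5, med = 1.5, front = 7.5),
                   vertebral_rotation = c(L1 = -20, L2 = -22, L3 = -12,
                                          L4 = -2, L5 = 22)),
        RT4 = list(ss = c(45, 55), pi = c(50, 70),
                   sva = c(back = -6.3, med = -0.3, front = 6.3),
                   vertebral_rotation = c(L1 = -20, L2 = -14, L3 = -2,
                                          L4 = 9, L5 = 30))
      )
    ),

    ## Skeletal dimensions for a 1.76 m standing adult.  Lumbar lengths are
    ## joint-to-joint distances (vertebral body plus disc); the sacral
    ## endplate width sets the posterior-superior corner used by the SVA
    ## plumb-line; the hip sits below the endplate midpoint and is shifted
    ## horizontally to realise pelvic incidence.
    geometry = list(
      endplate_width    = 0.050,
      hip_drop          = 0.090,
      lumbar_length     = c(L1 = 0.035, L2 = 0.035, L3 = 0.035,
                            L4 = 0.035, L5 = 0.035),
      # anterior offset of each lumbar vertebral COM from the segment midpoint
      lumbar_com_anterior = c(L1 = 0.030, L2 = 0.035, L3 = 0.040,
                              L4 = 0.040, L5 = 0.040),
      thorax_length       = 0.420,   # T12L1 joint to C7 marker
      thorax_com_height   = 0.231,   # along thorax axis from T12L1
      thorax_com_anterior = 0.040,   # ribcage/viscera lie anterior of the spine
      shoulder_height     = 0.378,   # arm load application point on the axis
      shoulder_anterior   = 0.050,   # glenohumeral centre anterior of the spine
      head_com_height     = 0.120,   # above C7, along the (counter-rotated) head
      head_com_anterior   = 0.020,
      t12_offset_deg      = -8,      # T12 endplate inclination minus thorax rotation
      thoracic_rot_limit  = 45       # bracket for the SVA solve, degrees
    ),

    ## Segment mass fractions of total body mass (must sum to 1).  The chain
    ## above L5S1 carries lumbar slices, thorax, head+neck and both arms; the
    ## pelvis and legs are the grounded side.
    masses = list(
      total = 75,
      fractions = c(head_neck = 0.081, arms = 0.100, thorax = 0.216,
                    L1 = 0.0276, L2 = 0.0276, L3 = 0.0276,
                    L4 = 0.0276, L5 = 0.0276,
                    pelvis = 0.142, legs = 0.323)
    ),

    ## Lumped sagittal actuators.  Attachment points are local coordinates in
    ## the owning segment frame: sacrum-pelvis points are relative to the L5S1
    ## joint at the default sacral orientation, thorax points relative to the
    ## T12L1 joint with the thorax upright, vertebral points relative to the
    ## inferior joint of the vertebra.  x anterior, y up.
    muscles = list(
      multifidus = list(
        strength = 500,             # per sacral fascicle, bilateral sum
        deep_strength = 600,        # per single-joint deep fascicle
        t12_strength = 700,         # thoracolumbar deep extensor (semispinalis)
        posterior_offset = 0.035,
        sacral_origin = c(-0.040, -0.030)
      ),
      erector_spinae = list(
        strength = 2200,
        sacral_origin = c(-0.040, -0.050),
        thorax_insertion = c(-0.095, 0.100)
      ),
      rectus_abdominis = list(
        strength = 1000,
        pelvis_origin = c(0.115, -0.075),   # pubic region via the abdominal wall
        thorax_insertion = c(0.070, 0.055)  # costal cartilage / sternum
      ),
      psoas = list(
        strength = 180,             # per fascicle, bilateral sum
        anterior_offset = 0.015,
        pelvis_insertion = c(0.025, -0.100)
      ),
      abdominal_pressure = list(enabled = FALSE, extension_moment = 0)
    ),

    solver = list(criterion_power = 3, tol = 1e-9, max_iter = 200),
    gravity = 9.81,
    body_height = 1.76
  )
}

#' Read constants from a YAML file
#'
#' Reads a flat YAML constants file and merges it over [default_constants()]:
#' any key present in the file replaces the default, keys not present keep
#' their default value.
#'
#' @param path Path to a YAML file.
#' @return A constants list as from [default_constants()].
#' @export
read_constants <- function(path) {
  user <- yaml::read_yaml(path)
  merge_constants(default_constants(), user)
}

#' Write constants to a YAML file
#'
#' @param constants A constants list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_constants <- function(constants, path) {
  yaml::write_yaml(prepare_yaml(constants), path)
  invisible(path)
}

# yaml drops names on unnamed vectors; keep named vectors as named lists
prepare_yaml <- function(x) {
  if (is.list(x)) return(lapply(x, prepare_yaml))
  if (!is.null(names(x)) && length(x) > 1) return(as.list(x))
  x
}

merge_constants <- function(base, user) {
  if (!is.list(user)) {
    # scalar or vector leaf replaces default; restore names lost to YAML
    if (!is.list(base) && length(base) > 1 && !is.null(names(base)) &&
        length(user) == length(base) && is.null(names(user))) {
      names(user) <- names(base)
    }
    return(user)
  }
  if (!is.list(base)) {
    u <- unlist(user)
    if (!is.null(names(base)) && length(u) == length(base)) {
      v <- base
      v[names(user)] <- unlist(user)
      return(v)
    }
    return(u)
  }
  for (nm in names(user)) {
    base[[nm]] <- if (nm %in% names(base)) {
      merge_constants(base[[nm]], user[[nm]])
    } else {
      user[[nm]]
    }
  }
  base
}

#' Validate a constants list
#'
#' Checks structural invariants: mass fractions summing to one (within 1e-9),
#' strictly positive lengths, strengths and total mass, and the presence of the
#' four lumbar-type design entries.
#'
#' @param constants A constants list.
#' @return `constants`, invisibly, or an error describing the violation.
#' @export
validate_constants <- function(constants) {
  fr <- constants$masses$fractions
  if (abs(sum(fr) - 1) > 1e-9) {
    stop("segment mass fractions must sum to 1 (got ", format(sum(fr), digits = 12), ")")
  }
  if (any(fr < 0)) stop("segment mass fractions must be non-negative")
  if (constants$masses$total <= 0) stop("total body mass must be positive")
  geo <- constants$geometry
  lens <- c(geo$endplate_width, geo$hip_drop, geo$lumbar_length,
            geo$thorax_length, geo$thorax_com_height, geo$head_com_height)
  if (any(lens <= 0)) stop("skeletal lengths must be strictly positive")
  if (!all(rt_labels() %in% names(constants$design$rt))) {
    stop("design grid must define all four lumbar types: ",
         paste(rt_labels(), collapse = ", "))
  }
  for (m in c("multifidus", "erector_spinae", "rectus_abdominis")) {
    if (constants$muscles[[m]]$strength <= 0) {
      stop("muscle strength must be strictly positive: ", m)
    }
  }
  if (constants$solver$criterion_power <= 1) {
    stop("recruitment criterion power must exceed 1")
  }
  invisible(constants)
}

#' Valid Roussouly lumbar type labels
#' @return Character vector `c("RT1","RT2","RT3","RT4")`.
#' @export
rt_labels <- function() c("RT1", "RT2", "RT3", "RT4")

#' Lumbar joint labels, cranial to caudal
#' @return Character vector of the six balanced joints.
#' @export
joint_labels <- function() c("T12L1", "L1L2", "L2L3", "L3L4", "L4L5", "L5S1")

sva_conditions <- function() c("back", "med", "front")

rt_entry <- function(rt, constants) {
  if (length(rt) != 1 || !rt %in% rt_labels()) {
    stop("unknown Roussouly type '", rt, "'; valid labels: ",
         paste(rt_labels(), collapse = ", "))
  }
  constants$design$rt[[rt]]
}
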