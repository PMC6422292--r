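# Compression/shear decomposition of intersegmental forces.
#
# Axes are orthonormal pairs: `axial` caudally oriented (so a downward
# transmitted load projects to positive compression), `anterior` anteriorly
# oriented and endplate-parallel.

projection_axes <- function(axial, anterior) {
  structure(list(axial = axial, anterior = anterior),
            class = "projection_axes")
}

#' Projection axes at L4L5
#'
#' Axial direction through the two intervertebral joints of L5 (from L4L5
#' down to L5S1, caudally oriented); anterior direction its +90 degree
#' orthogonal, parallel to the upper endplate of L5.
#'
#' @param posture A `posture_config`.
#' @return A `projection_axes` object.
#' @export
l4l5_axes <- function(posture) {
  d <- posture$joints["L5S1", ] - posture$joints["L4L5", ]
  len <- sqrt(sum(d^2))
  if (len < 1e-12) stop("degenerate geometry: coincident L5 joints")
  axial <- unname(d / len)
  # +90 deg (counter-clockwise) orthogonal of the caudal axis is anterior
  projection_axes(axial, c(-axial[2], axial[1]))
}

#' Projection axes at L5S1
#'
#' Anterior direction parallel to the sacral endplate at the configuration's
#' sacral slope; axial direction its caudally oriented normal.
#'
#' @param posture A `posture_config`.
#' @return A `projection_axes` object.
#' @export
l5s1_axes <- function(posture) {
  ant <- anterior_unit(posture$params$ss)
  projection_axes(c(ant[2], -ant[1]), ant)
}

#' Decompose a force into axial compression and anterior shear
#'
#' @param force World force vector (N).
#' @param axes A `projection_axes` pair (must be orthonormal).
#' @return Named numeric `c(compression=, shear=)`, Newtons; compression
#'   positive for a caudally transmitted load.
#' @export
decompose <- function(force, axes) {
  a <- axes$axial; s <- axes$anterior
  if (abs(sum(a^2) - 1) > 1e-9 || abs(sum(s^2) - 1) > 1e-9 ||
      abs(sum(a * s)) > 1e-9) {
    stop("projection axes must be orthonormal")
  }
  force <- unname(force)
  c(compression = sum(force * a), shear = sum(force * s))
}
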