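#' Construct a validated spinopelvic parameter point
#'
#' One point in the (RT, SS, PI, SVA) design space.  Pelvic tilt is derived
#' from the spinopelvic identity PT = PI - SS; the SVA value in centimetres is
#' looked up from the design table for the requested condition.
#'
#' @param rt Roussouly type label, one of `"RT1"`..`"RT4"`.
#' @param ss Sacral slope, degrees.
#' @param pi Pelvic incidence, degrees.
#' @param sva_condition One of `"back"`, `"med"`, `"front"`.
#' @param constants Model constants, see [default_constants()].
#' @param strict If `TRUE` (default) SS and PI must lie inside the closed
#'   per-type design ranges; disable for exploratory use outside them.
#' @return An object of class `spinopelvic_params`.
#' @export
spinopelvic_params <- function(rt, ss, pi, sva_condition = "med",
                               constants = default_constants(),
                               strict = TRUE) {
  entry <- rt_entry(rt, constants)
  if (length(sva_condition) != 1 || !sva_condition %in% sva_conditions()) {
    stop("unknown SVA condition '", sva_condition, "'; valid: ",
         paste(sva_conditions(), collapse = ", "))
  }
  if (!is.finite(ss) || !is.finite(pi)) stop("ss and pi must be finite")
  if (strict) {
    if (ss < entry$ss[1] || ss > entry$ss[2]) {
      stop(sprintf("sacral slope %g outside %s design range [%g, %g]",
                   ss, rt, entry$ss[1], entry$ss[2]))
    }
    if (pi < entry$pi[1] || pi > entry$pi[2]) {
      stop(sprintf("pelvic incidence %g outside %s design range [%g, %g]",
                   pi, rt, entry$pi[1], entry$pi[2]))
    }
  }
  structure(list(rt = rt, ss = ss, pi = pi,
                 sva_condition = sva_condition,
                 sva = unname(entry$sva[sva_condition]),
                 pt = pi - ss),
            class = "spinopelvic_params")
}

#' @export
print.spinopelvic_params <- function(x, ...) {
  cat(sprintf("<spinopelvic_params> %s  SS %g°  PI %g°  PT %g°  SVA %s (%g cm)\n",
              x$rt, x$ss, x$pi, x$pt, x$sva_condition, x$sva))
  invisible(x)
}

#' Enumerate the full design sweep
#'
#' For every lumbar type, sacral slope and pelvic incidence run from their
#' per-type minima to maxima inclusive in 1 degree increments, crossed with the
#' three SVA conditions, in deterministic (RT, SS, PI, SVA) order.  The full
#' grid has 4 x 11 x 21 x 3 = 2772 configurations.
#'
#' @param constants Model constants.
#' @param rt Optional subset of type labels.
#' @param ss_range,pi_range Optional length-2 numeric filters (closed bounds)
#'   intersected with the per-type design ranges.
#' @param sva Optional subset of `c("back","med","front")`.
#' @return A data.frame with columns `rt`, `ss`, `pi`, `sva_condition`,
#'   `sva`, `pt`, one row per configuration.
#' @export
enumerate_sweep <- function(constants = default_constants(), rt = NULL,
                            ss_range = NULL, pi_range = NULL, sva = NULL) {
  rts <- if (is.null(rt)) rt_labels() else rt
  if (!all(rts %in% rt_labels())) {
    stop("unknown Roussouly type in filter; valid labels: ",
         paste(rt_labels(), collapse = ", "))
  }
  svas <- if (is.null(sva)) sva_conditions() else sva
  if (!all(svas %in% sva_conditions())) stop("unknown SVA condition in filter")
  out <- vector("list", length(rts))
  for (k in seq_along(rts)) {
    entry <- rt_entry(rts[k], constants)
    ss_lo <- entry$ss[1]; ss_hi <- entry$ss[2]
    pi_lo <- entry$pi[1]; pi_hi <- entry$pi[2]
    if (!is.null(ss_range)) { ss_lo <- max(ss_lo, ss_range[1]); ss_hi <- min(ss_hi, ss_range[2]) }
    if (!is.null(pi_range)) { pi_lo <- max(pi_lo, pi_range[1]); pi_hi <- min(pi_hi, pi_range[2]) }
    if (ss_lo > ss_hi || pi_lo > pi_hi) next
    grid <- expand.grid(sva_condition = svas,
                        pi = seq(pi_lo, pi_hi, by = 1),
                        ss = seq(ss_lo, ss_hi, by = 1),
                        stringsAsFactors = FALSE)
    out[[k]] <- data.frame(rt = rts[k], ss = grid$ss, pi = grid$pi,
                           sva_condition = grid$sva_condition,
                           sva = unname(entry$sva[grid$sva_condition]),
                           pt = grid$pi - grid$ss,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(rt = character(), ss = numeric(), pi = numeric(),
                      sva_condition = character(), sva = numeric(),
                      pt = numeric())
  }
  rownames(res) <- NULL
  res
}

#' Sample random spinopelvic parameter points
#'
#' Fixture generator: draws the lumbar type by weight, then SS and PI
#' uniformly on the integer-degree grid inside that type's design range
#' (matching the 1 degree increments of the sweep), and the SVA condition
#' uniformly.  Reproducible from `seed`.
#'
#' @param n Number of points.
#' @param seed Integer seed.
#' @param rt_weights Non-negative sampling weights over RT1..RT4.
#' @param constants Model constants.
#' @return A data.frame in the same layout as [enumerate_sweep()].
#' @export
sample_params <- function(n, seed = 1, rt_weights = rep(1, 4),
                          constants = default_constants()) {
  stopifnot(n >= 0)
  if (length(rt_weights) != 4 || any(rt_weights < 0) || sum(rt_weights) == 0) {
    stop("rt_weights must be four non-negative weights, not all zero")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  rts <- sample(rt_labels(), n, replace = TRUE, prob = rt_weights / sum(rt_weights))
  svas <- sample(sva_conditions(), n, replace = TRUE)
  ss <- pi_ <- sva_cm <- numeric(n)
  for (i in seq_len(n)) {
    entry <- rt_entry(rts[i], constants)
    ss[i] <- sample(seq(entry$ss[1], entry$ss[2]), 1)
    pi_[i] <- sample(seq(entry$pi[1], entry$pi[2]), 1)
    sva_cm[i] <- unname(entry$sva[svas[i]])
  }
  data.frame(rt = rts, ss = ss, pi = pi_, sva_condition = svas,
             sva = sva_cm, pt = pi_ - ss, stringsAsFactors = FALSE)
}

#' Randomly perturb the anthropometric constants
#'
#' Multiplies every skeletal length, anterior offset, muscle attachment
#' coordinate, muscle strength and segment mass fraction by an independent
#' factor drawn uniformly from `[1 - jitter, 1 + jitter]`, then renormalises
#' the mass fractions to sum to one.  The design grid (parameter ranges,
#' vertebral rotations) is left untouched: perturbation probes robustness of
#' the findings to the body, not to the study conditions.
#'
#' @param constants Model constants.
#' @param jitter Fractional perturbation, in `[0, 0.2]`.
#' @param seed Integer seed.
#' @return A perturbed constants list passing [validate_constants()].
#' @export
perturb_anthropometry <- function(constants = default_constants(),
                                  jitter = 0.05, seed = 1) {
  if (jitter < 0 || jitter > 0.2) stop("jitter must lie in [0, 0.2]")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  fac <- function(x) x * runif(length(x), 1 - jitter, 1 + jitter)
  geo <- constants$geometry
  for (nm in c("endplate_width", "hip_drop", "lumbar_length",
               "lumbar_com_anterior", "thorax_length", "thorax_com_height",
               "thorax_com_anterior", "shoulder_height", "shoulder_anterior",
               "head_com_height", "head_com_anterior")) {
    geo[[nm]] <- fac(geo[[nm]])
  }
  constants$geometry <- geo
  mus <- constants$muscles
  for (m in c("multifidus", "erector_spinae", "rectus_abdominis")) {
    mus[[m]] <- lapply(mus[[m]], fac)
  }
  constants$muscles <- mus
  fr <- fac(constants$masses$fractions)
  constants$masses$fractions <- fr / sum(fr)
  constants$masses$total <- fac(constants$masses$total)
  validate_constants(constants)
  constants
}
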