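# Static muscle recruitment: minimise the polynomial activation criterion
#   sum_i (f_i / S_i)^p ,  p > 1 (default 3)
# subject to moment equilibrium at every lumbar joint,
#   sum_i r[j,i] f_i = M[j]   (extension-positive arms, flexion-positive
#                              gravity moments)
# and non-negative tension f_i >= 0.  The problem is strictly convex on the
# non-negative orthant, so the minimiser is unique.
#
# The solver is a primal-dual interior-point iteration on the KKT system
#   p f^(p-1)/S^p - t(R) lambda - z = 0,   R f = M,   z_i f_i = mu -> 0,
# followed by an active-set polish: fascicles with vanishing force are
# clamped to exactly zero and the equality-constrained KKT system of the
# remaining ones is re-solved by Newton to machine-level residuals.

#' Assemble the recruitment problem for one posture
#'
#' Builds the flexion-positive gravity moment of the superincumbent free body
#' about each lumbar joint and the signed moment-arm matrix of the muscle
#' set.  The equilibrium constraint at joint j is
#' `sum_i arm[j,i] * f_i = gravity_moment[j]`: muscle extension moments
#' balance gravity flexion moments.  When the optional abdominal pressure
#' stub is enabled, its extension moment is subtracted from each joint's
#' demand.
#'
#' @param chain A `body_chain`.
#' @param muscles A `muscle_set`.
#' @param posture The `posture_config` both were built from.
#' @return Object of class `recruitment_problem`.
#' @export
assemble_problem <- function(chain, muscles, posture) {
  joints <- joint_labels()
  M <- vapply(joints, function(j) superincumbent_load(chain, j)$moment,
              numeric(1))
  ap <- muscles$abdominal_pressure
  if (isTRUE(ap$enabled)) M <- M - ap$extension_moment
  nfas <- nrow(muscles$fascicles)
  R <- matrix(0, length(joints), nfas,
              dimnames = list(joints, muscles$fascicles$name))
  for (j in joints) R[j, ] <- fascicle_arms(muscles, j, posture)
  for (j in joints) {
    if (M[j] > 0 && !any(R[j, ] > 0)) {
      stop("infeasible recruitment: joint ", j,
           " needs an extension moment but no extensor crosses it")
    }
    if (M[j] < 0 && !any(R[j, ] < 0)) {
      stop("infeasible recruitment: joint ", j,
           " needs a flexion moment but no flexor crosses it")
    }
  }
  structure(list(joints = joints, gravity_moments = M, moment_arms = R,
                 strengths = stats::setNames(muscles$fascicles$strength,
                                             muscles$fascicles$name)),
            class = "recruitment_problem")
}

#' Solve a static muscle-recruitment problem
#'
#' Minimises `sum_i (f_i / S_i)^p` subject to exact moment balance at every
#' joint and non-negative fascicle tensions.  Activations above 1 are
#' permitted with a warning (the actuators are then working above their
#' nominal strength).
#'
#' @param problem A `recruitment_problem` (or a list with fields
#'   `moment_arms`, `gravity_moments`, `strengths`).
#' @param p Criterion power (> 1); defaults to 3, the cubic polynomial
#'   criterion.
#' @param tol Convergence tolerance on the worst joint moment residual, N m.
#' @param max_iter Newton iteration cap.
#' @return Object of class `recruitment_solution`: `muscle_forces` (N),
#'   `activations`, `objective_value`, `equilibrium_residual` (N m),
#'   `multipliers`.
#' @export
solve_recruitment <- function(problem, p = 3, tol = 1e-9, max_iter = 200) {
  R <- problem$moment_arms
  M <- problem$gravity_moments
  S <- problem$strengths
  nj <- nrow(R)
  stopifnot(ncol(R) == length(S), nj == length(M), p > 1)

  n <- ncol(R)
  if (max(abs(M)) == 0) {
    # no demand anywhere: zero tension is the exact unique minimiser
    f0 <- stats::setNames(numeric(n), colnames(R))
    return(structure(list(muscle_forces = f0, activations = f0,
                          objective_value = 0, equilibrium_residual = 0,
                          multipliers = stats::setNames(numeric(nj), rownames(R)),
                          iterations = 0L),
                     class = "recruitment_solution"))
  }
  grad <- function(f) p * f^(p - 1) / S^p
  hess <- function(f) p * (p - 1) * f^(p - 2) / S^p

  ## --- primal-dual interior point -----------------------------------
  scl <- max(abs(M), 1)
  f <- 0.05 * S
  z <- pmax(grad(f), 1e-3)
  lambda <- rep(0, nj)
  mu <- sum(f * z) / n
  it <- 0L
  for (it in seq_len(max_iter)) {
    r_p <- drop(R %*% f) - M
    r_d <- grad(f) - drop(crossprod(R, lambda)) - z
    comp <- sum(f * z) / n
    if (max(abs(r_p)) <= 1e-11 * scl && max(abs(r_d)) <= 1e-9 &&
        comp <= 1e-12 * scl) break
    mu <- 0.15 * comp
    # eliminate dz, then df, solve the nj x nj Schur system for dlambda
    W <- hess(f) + z / f
    rdm <- grad(f) - drop(crossprod(R, lambda)) - mu / f
    RW <- R * rep(1 / W, each = nj)
    A <- RW %*% t(R)
    rhs <- -r_p + drop(RW %*% rdm)
    dl <- tryCatch(solve(A, rhs), error = function(e) NULL)
    if (is.null(dl)) dl <- solve(A + diag(1e-10 * max(diag(A), 1), nj), rhs)
    df <- (drop(crossprod(R, dl)) - rdm) / W
    dz <- (mu - z * f - z * df) / f
    # fraction-to-boundary
    amax <- 1
    neg <- df < 0
    if (any(neg)) amax <- min(amax, 0.995 * min(-f[neg] / df[neg]))
    neg <- dz < 0
    if (any(neg)) amax <- min(amax, 0.995 * min(-z[neg] / dz[neg]))
    f <- f + amax * df
    lambda <- lambda + amax * dl
    z <- z + amax * dz
  }

  ## --- active-set polish --------------------------------------------
  active <- f > z                      # complementarity separates the sets
  if (any(active)) {
    fa <- f[active]
    Ra <- R[, active, drop = FALSE]
    Sa <- S[active]
    for (k in 1:50) {
      g <- p * fa^(p - 1) / Sa^p - drop(crossprod(Ra, lambda))
      r <- drop(Ra %*% fa) - M
      if (max(abs(g)) <= 1e-13 && max(abs(r)) <= 1e-12 * scl) break
      H <- p * (p - 1) * fa^(p - 2) / Sa^p
      K <- rbind(cbind(diag(H, length(fa)), -t(Ra)),
                 cbind(Ra, matrix(0, nj, nj)))
      step <- tryCatch(solve(K, -c(g, r)), error = function(e) NULL)
      if (is.null(step)) break
      dfa <- step[seq_along(fa)]
      # keep strictly positive; if a fascicle insists on leaving, stop here
      amax <- 1
      neg <- dfa < 0
      if (any(neg)) amax <- min(1, 0.9 * min(-fa[neg] / dfa[neg]))
      fa <- fa + amax * dfa
      lambda <- lambda + amax * step[-seq_along(fa)]
      if (amax < 1e-3) break
    }
    if (all(fa >= 0)) {
      f2 <- numeric(n)
      f2[active] <- fa
      if (max(abs(drop(R %*% f2) - M)) <= max(abs(drop(R %*% f) - M))) f <- f2
    }
  } else if (max(abs(M)) <= 1e-12 * scl) {
    f <- numeric(n)
  }

  r <- drop(R %*% f) - M
  res <- max(abs(r))
  if (res > 1e-6) {
    stop(sprintf(
      "recruitment solver did not converge: residual %.3g N m after %d iterations (demands: %s)",
      res, it, paste(sprintf("%.3g", M), collapse = ", ")))
  }
  act <- f / S
  if (any(act > 1 + 1e-9)) {
    warning("muscle activation exceeds 1 for: ",
            paste(names(S)[act > 1 + 1e-9], collapse = ", "),
            " (forces above nominal strength)")
  }
  structure(list(muscle_forces = stats::setNames(f, colnames(R)),
                 activations = stats::setNames(act, colnames(R)),
                 objective_value = sum((f / S)^p),
                 equilibrium_residual = res,
                 multipliers = stats::setNames(lambda, rownames(R)),
                 iterations = it),
            class = "recruitment_solution")
}

#' Intersegmental reaction force at a lumbar level
#'
#' Free-body balance of everything above the level: the reaction transmitted
#' to the inferior element equals the superincumbent gravity load plus the
#' pull of every fascicle crossing the level on the superincumbent body, so
#' a standing posture yields a downward (compressive) resultant.
#'
#' @param chain A `body_chain`.
#' @param muscles The `muscle_set`.
#' @param solution The solved `recruitment_solution`.
#' @param level Joint label.
#' @param posture The `posture_config`.
#' @return World force vector `c(x=, y=)`, Newtons.
#' @export
intersegmental_force <- function(chain, muscles, solution, level, posture) {
  rk <- joint_rank()
  if (length(level) != 1 || !level %in% names(rk)) {
    stop("unknown joint level '", level, "'; valid: ",
         paste(joint_labels(), collapse = ", "))
  }
  grav <- superincumbent_load(chain, level)$force
  F <- c(grav["x"], grav["y"])
  fas <- muscles$fascicles
  for (i in seq_len(nrow(fas))) {
    if (!level %in% strsplit(fas$spanned[i], ",")[[1]]) next
    loa <- line_of_action(fas[i, ])
    F <- F + solution$muscle_forces[[fas$name[i]]] * (-loa$unit)
  }
  stats::setNames(F, c("x", "y"))
}

#' Simulate one spinopelvic configuration end to end
#'
#' Full pipeline: posture construction, weighted chain, muscle set,
#' recruitment solve, intersegmental reactions at L4L5 and L5S1 and their
#' compression/shear decomposition.  Deterministic: identical inputs give
#' bit-identical results.
#'
#' @param params A `spinopelvic_params` (or one-row sweep slice).
#' @param constants Model constants.
#' @return Object of class `load_result`: a one-row data.frame with the
#'   configuration, lumbar lordosis, reaction components (`fl4l5c`,
#'   `fl4l5s`, `fl5s1c`, `fl5s1s`, Newtons, compression and anterior shear
#'   positive), grouped muscle forces (`f_mf`, `f_es`, `f_ra`) and the
#'   equilibrium residual.
#' @export
simulate_configuration <- function(params, constants = default_constants()) {
  posture <- build_posture(params, constants)
  chain <- build_chain(posture, constants)
  muscles <- build_muscle_set(posture, constants)
  problem <- assemble_problem(chain, muscles, posture)
  sol <- solve_recruitment(problem, p = constants$solver$criterion_power,
                           tol = constants$solver$tol,
                           max_iter = constants$solver$max_iter)
  f45 <- intersegmental_force(chain, muscles, sol, "L4L5", posture)
  f51 <- intersegmental_force(chain, muscles, sol, "L5S1", posture)
  d45 <- decompose(f45, l4l5_axes(posture))
  d51 <- decompose(f51, l5s1_axes(posture))
  grp <- function(g) sum(sol$muscle_forces[muscles$fascicles$group == g])
  pp <- posture$params
  out <- data.frame(
    rt = pp$rt, ss = pp$ss, pi = pp$pi, sva_condition = pp$sva_condition,
    sva = pp$sva, pt = pp$pt, ll_deg = posture$ll_deg,
    thoracic_rotation_deg = posture$thoracic_rotation_deg,
    fl4l5_x = unname(f45["x"]), fl4l5_y = unname(f45["y"]),
    fl5s1_x = unname(f51["x"]), fl5s1_y = unname(f51["y"]),
    fl4l5c = d45[["compression"]], fl4l5s = d45[["shear"]],
    fl5s1c = d51[["compression"]], fl5s1s = d51[["shear"]],
    f_mf = grp("multifidus"), f_es = grp("erector_spinae"),
    f_ra = grp("rectus_abdominis"),
    residual = sol$equilibrium_residual,
    stringsAsFactors = FALSE
  )
  class(out) <- c("load_result", class(out))
  out
}
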