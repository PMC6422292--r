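# Independent oracles used across the test files.  They deliberately avoid
# the package's own computational paths.

# Brute-force minimisation of sum((f/S)^p) on {f >= 0 : R f = M} for small
# problems (nullspace dimension <= 2): two-stage grid search over the
# nullspace coordinates, refined around the incumbent.
oracle_recruitment <- function(R, M, S, p = 3, n_grid = 201, half_width = NULL) {
  R <- as.matrix(R)
  n <- ncol(R)
  qrR <- qr(t(R))
  rank <- qrR$rank
  f0 <- drop(t(R) %*% solve(R %*% t(R), M))             # least-norm particular solution
  Q <- qr.Q(qrR, complete = TRUE)
  N <- Q[, seq(rank + 1, n), drop = FALSE]              # nullspace basis
  k <- ncol(N)
  stopifnot(k >= 1, k <= 2)
  if (is.null(half_width)) half_width <- 2 * (max(abs(f0)) + max(S) / 2)
  obj <- function(z) {
    f <- f0 + drop(N %*% z)
    if (any(f < 0)) return(Inf)
    sum((f / S)^p)
  }
  centre <- rep(0, k)
  width <- half_width
  best <- list(val = Inf, z = centre)
  for (stage in 1:6) {
    gr <- seq(-width, width, length.out = n_grid)
    if (k == 1) {
      for (z1 in gr) {
        v <- obj(centre + z1)
        if (v < best$val) best <- list(val = v, z = centre + z1)
      }
    } else {
      for (z1 in gr) for (z2 in gr) {
        z <- centre + c(z1, z2)
        v <- obj(z)
        if (v < best$val) best <- list(val = v, z = z)
      }
    }
    centre <- best$z
    width <- width * 2.5 / n_grid * 2   # shrink around the incumbent
  }
  list(objective = best$val, forces = f0 + drop(N %*% best$z))
}

# Hand-measured SVA: horizontal offset (cm) of the C7 marker from the
# posterior-superior sacral corner, recomputed from raw landmark coordinates.
oracle_sva <- function(posture) {
  (posture$landmarks["C7", "x"] - posture$landmarks["sacral_corner", "x"]) * 100
}

# Hand-trigonometry pelvic incidence from raw geometry.
oracle_pi <- function(posture) {
  mid <- posture$landmarks["endplate_mid", ]
  hip <- posture$landmarks["hip", ]
  ep <- posture$landmarks["endplate_mid", ] - posture$landmarks["sacral_corner", ]
  ss <- atan2(-ep["y"], ep["x"])               # endplate inclination, radians
  hip_ang <- atan2(hip["x"] - mid["x"], mid["y"] - hip["y"])
  unname((hip_ang + ss) * 180 / pi)
}

# Sort-based median (independent of stats::median).
oracle_median <- function(v) {
  v <- sort(v)
  n <- length(v)
  if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
}

# A small deterministic sample of design-grid configurations covering all
# types and SVA conditions.
sample_grid <- function(constants = default_constants()) {
  out <- list()
  for (rt in rt_labels()) {
    e <- spinoload:::rt_entry(rt, constants)
    for (sv in c("back", "med", "front")) {
      out[[paste(rt, sv)]] <- data.frame(
        rt = rt, ss = c(e$ss[1], e$ss[2]), pi = c(e$pi[1], e$pi[2]),
        sva_condition = sv, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
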