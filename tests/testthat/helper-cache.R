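# Heavy shared computations, evaluated lazily and at most once per test run.
.spinoload_cache <- new.env(parent = emptyenv())

# Full 2772-configuration sweep under the default model.
full_sweep <- function() {
  if (is.null(.spinoload_cache$sweep)) {
    .spinoload_cache$sweep <- run_sweep(default_constants())
  }
  .spinoload_cache$sweep
}

# Central pelvic incidence of each type's design range.
central_pi <- function() c(RT1 = 40, RT2 = 40, RT3 = 50, RT4 = 60)

# The qualitative findings, checked on any sweep table; returns a character
# vector of violated properties (empty when all hold).
finding_violations <- function(sw) {
  fails <- character()
  bk <- sw[sw$sva_condition == "back", ]
  if (any(sw$f_ra[sw$sva_condition == "front"] > 1e-6)) fails <- c(fails, "ra_front")
  if (any(sw$f_ra[sw$sva_condition == "med" & sw$rt != "RT4"] > 1e-6)) {
    fails <- c(fails, "ra_med_rt123")
  }
  if (any(bk$f_ra <= 0)) fails <- c(fails, "ra_back")
  key <- paste(sw$rt, sw$ss, sw$pi)
  es <- tapply(sw$f_es, list(key, sw$sva_condition), c)
  fc <- tapply(sw$fl4l5c, list(key, sw$sva_condition), c)
  if (any(es[, "front"] <= es[, "med"])) fails <- c(fails, "es_front_med")
  if (any(es[, "med"] <= es[, "back"])) fails <- c(fails, "es_med_back")
  if (any(fc[, "front"] <= fc[, "med"])) fails <- c(fails, "fl4l5c_front_med")
  cpi <- central_pi()
  for (rt in unique(sw$rt)) for (sv in c("back", "med", "front")) {
    d <- sw[sw$rt == rt & sw$sva_condition == sv & sw$pi == cpi[rt], ]
    if (nrow(d) < 2) next
    lo <- d$ss == min(d$ss); hi <- d$ss == max(d$ss)
    if (d$fl4l5s[hi] >= d$fl4l5s[lo]) fails <- c(fails, paste0("fl4l5s_ss_", rt, "_", sv))
    if (d$fl5s1s[hi] <= d$fl5s1s[lo]) fails <- c(fails, paste0("fl5s1s_ss_", rt, "_", sv))
  }
  fails
}

# PI-collapse check: maximum relative spread of every output across the PI
# grid within each (RT, SS, SVA) stratum.
pi_relative_spread <- function(sw) {
  outs <- c("fl4l5c", "fl4l5s", "fl5s1c", "fl5s1s", "f_mf", "f_es", "f_ra",
            "ll_deg", "thoracic_rotation_deg")
  key <- paste(sw$rt, sw$ss, sw$sva_condition)
  worst <- 0
  for (o in outs) {
    spread <- tapply(sw[[o]], key, function(v) diff(range(v)))
    scale <- pmax(abs(tapply(sw[[o]], key, function(v) max(abs(v)))), 1e-9)
    worst <- max(worst, max(spread / scale))
  }
  worst
}
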