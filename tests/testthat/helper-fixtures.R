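# Shared fixtures: a short acquisition protocol and small cohorts keep the
# suite fast while exercising every stage.

short_protocol <- function() {
  acquisition_protocol(
    fast_frame_interval = 3.2, n_fast_frames = 30, n_precontrast_fast = 3,
    slow_frame_interval = 30, n_slow_frames = 14, n_precontrast_slow = 2
  )
}

tiny_config <- function(...) {
  simulation_config(n_patients = 2, n_controls = 2, ...)
}

# Minimal conc_series constructor for unit tests (grid d, frames in minutes).
toy_conc <- function(values, times_min, d = c(2, 2, 1)) {
  arr <- array(rep(values, each = prod(d)), c(d, length(times_min)))
  bbbpatlak:::new_conc_series(arr, times_min, array(TRUE, d), "fast")
}

# Brute-force SSE grid search over (ki, vp) for the Patlak model; the
# independent oracle for the OLS fit.
patlak_grid_oracle <- function(ct, times_min, vif, ki_range, vp_range,
                               ki_step = 1e-5, vp_step = 1e-4) {
  X <- bbbpatlak:::patlak_design(vif, times_min)
  kis <- seq(ki_range[1], ki_range[2], by = ki_step)
  vps <- seq(vp_range[1], vp_range[2], by = vp_step)
  best <- c(NA, NA); best_sse <- Inf
  for (ki in kis) {
    resid0 <- ct - ki * X[, 1]
    sse <- vapply(vps, function(vp) sum((resid0 - vp * X[, 2])^2), numeric(1))
    j <- which.min(sse)
    if (sse[j] < best_sse) { best_sse <- sse[j]; best <- c(ki, vps[j]) }
  }
  list(ki = best[1], vp = best[2], ki_step = ki_step, vp_step = vp_step)
}
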