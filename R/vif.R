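#' Parametric vascular input function: gamma-variate bolus with recirculation
#'
#' Closed-form plasma concentration model used by the synthetic cohort: zero
#' before bolus arrival, then a normalized gamma-variate first pass plus a
#' recirculation/washout component
#' `(1 - exp(-(t - t0)/tau_rise)) * exp(-washout_rate * (t - t0))`.
#' The mixture is rescaled so its global maximum equals `peak_conc`.
#'
#' @param t times, seconds (vector).
#' @param bolus_arrival bolus arrival time t0, seconds.
#' @param peak_conc peak plasma concentration, mM (> 0).
#' @param washout_rate mono-exponential washout rate of the recirculation
#'   component, min^-1 (>= 0; 0 gives a late plateau).
#' @param shape gamma-variate shape parameter alpha.
#' @param time_to_peak time from arrival to the first-pass peak, seconds.
#' @param recirc_frac weight of the recirculation component relative to the
#'   unit-height first pass.
#' @param recirc_tau rise time of the recirculation component, seconds.
#' @return concentrations in mM, same length as `t`.
#' @export
vif_conc <- function(t, bolus_arrival, peak_conc,
                     washout_rate = 0.06,
                     shape = 2.5, time_to_peak = 8,
                     recirc_frac = 0.35, recirc_tau = 30) {
  if (!is.numeric(peak_conc) || length(peak_conc) != 1 || peak_conc <= 0) {
    stop("peak_conc must be a single positive number (mM)")
  }
  if (washout_rate < 0) stop("washout_rate must be >= 0")
  shape_fun <- function(tt) {
    s <- tt - bolus_arrival
    out <- numeric(length(s))
    pos <- s > 0
    x <- s[pos] / time_to_peak
    g <- x^shape * exp(shape * (1 - x))        # unit maximum at x = 1
    tail <- (1 - exp(-s[pos] / recirc_tau)) * exp(-washout_rate * s[pos] / 60)
    out[pos] <- g + recirc_frac * tail
    out
  }
  # normalize the mixture maximum to peak_conc on a dense grid
  grid <- bolus_arrival + seq(0.01, 60 * time_to_peak + 600, by = 0.05)
  m <- max(shape_fun(grid))
  peak_conc * shape_fun(t) / m
}

#' Sample a synthetic vascular input function on the protocol's frame grid
#'
#' @param protocol an [acquisition_protocol()].
#' @param peak_conc peak plasma concentration, mM.
#' @param washout_rate washout rate, min^-1.
#' @param ... further shape parameters passed to [vif_conc()].
#' @return a `vif` object: list with `times` (minutes, strictly increasing)
#'   and `cp` (mM), sampled at the union of fast and slow frame times.
#' @export
simulate_vif <- function(protocol, peak_conc = 5, washout_rate = 0.06, ...) {
  ft <- protocol_frame_times(protocol)
  t_s <- sort(unique(c(ft$fast, ft$slow)))
  cp <- vif_conc(t_s, protocol$bolus_arrival, peak_conc, washout_rate, ...)
  new_vif(t_s / 60, cp)
}

new_vif <- function(times_min, cp) {
  stopifnot(length(times_min) == length(cp), all(diff(times_min) > 0),
            all(is.finite(cp)))
  structure(list(times = times_min, cp = cp), class = "vif")
}

#' @export
print.vif <- function(x, ...) {
  cat(sprintf("vascular input function: %d samples over %.1f min, peak %.2f mM\n",
              length(x$times), diff(range(x$times)), max(x$cp)))
  invisible(x)
}
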