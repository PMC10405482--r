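#' Spoiled gradient-echo steady-state signal
#'
#' `S = m0 * sin(a) * (1 - E1) / (1 - cos(a) * E1)` with `E1 = exp(-TR * R1)`.
#' Used both to synthesize dynamic signal and, inverted, to recover
#' concentration from measured signal.
#'
#' @param r1 longitudinal relaxation rate 1/T1, s^-1 (vector/array).
#' @param tr repetition time, seconds.
#' @param flip_angle flip angle, degrees.
#' @param m0 equilibrium magnetization / scanner gain (arbitrary units).
#' @return signal in arbitrary units, same shape as `r1`.
#' @export
spgr_signal <- function(r1, tr, flip_angle, m0 = 1) {
  a <- flip_angle * pi / 180
  e1 <- exp(-tr * r1)
  m0 * sin(a) * (1 - e1) / (1 - cos(a) * e1)
}

# Invert the SPGR equation for E1 given the signal ratio to a baseline with
# known E10. Returns E1; values outside (0, 1) mark unattainable ratios.
.spgr_invert_e1 <- function(signal_ratio, e10, cos_a) {
  f10 <- (1 - e10) / (1 - cos_a * e10)
  y <- signal_ratio * f10
  (1 - y) / (1 - cos_a * y)
}

#' Dynamic contrast-enhanced series container
#'
#' @param signal 4D array (x, y, z, frame), arbitrary units, finite.
#' @param frame_times frame timestamps, seconds, strictly increasing; length
#'   must equal `dim(signal)[4]`.
#' @param label `"fast"` or `"slow"`.
#' @return a `dce_series` object.
#' @export
dce_series <- function(signal, frame_times, label = c("fast", "slow")) {
  label <- match.arg(label)
  stopifnot(length(dim(signal)) == 4,
            dim(signal)[4] == length(frame_times),
            all(diff(frame_times) > 0),
            all(is.finite(signal)))
  structure(list(signal = signal, frame_times = frame_times, label = label),
            class = "dce_series")
}

new_conc_series <- function(concentration, frame_times_min, valid, label) {
  structure(list(concentration = concentration,
                 frame_times = frame_times_min,
                 valid = valid, label = label),
            class = "conc_series")
}

#' Convert dynamic signal to contrast-agent concentration
#'
#' Per voxel, the pre-contrast baseline `S0` is the mean over frames acquired
#' before bolus arrival. With the voxel's baseline relaxation rate
#' `R1_0 = 1/T1` from the T1 map, each post-contrast frame's R1 is obtained by
#' inverting the SPGR signal equation, and concentration is
#' `C(t) = (R1(t) - R1_0) / r1` with `r1` the contrast relaxivity.
#'
#' Voxels where the inversion has no solution at some frame (signal ratio
#' outside the attainable range), or with non-positive baseline or T1, are
#' flagged invalid: their concentration is `NA` and `valid` is `FALSE`. The
#' flag — never a clamped value — is what downstream masks consume.
#'
#' @param series a [dce_series()].
#' @param t1map 3D array of T1 values, seconds, matching the series grid.
#' @param protocol an [acquisition_protocol()] supplying TR, flip angle,
#'   relaxivity and bolus arrival.
#' @param method `"spgr"` (full inversion, default) or `"linear"`
#'   (first-order relative signal change, `C = (S/S0 - 1) / (r1 * T1)`),
#'   kept for sensitivity checks.
#' @return a `conc_series`: 4D `concentration` (mM), `frame_times` in
#'   minutes, 3D logical `valid`.
#' @export
signal_to_concentration <- function(series, t1map, protocol,
                                    method = c("spgr", "linear")) {
  method <- match.arg(method)
  stopifnot(inherits(series, "dce_series"),
            inherits(protocol, "acquisition_protocol"))
  d <- dim(series$signal)
  stopifnot(identical(dim(t1map), d[1:3]))
  pre <- series$frame_times < protocol$bolus_arrival
  if (!any(pre)) stop("series has no pre-contrast frames before bolus arrival")

  nvox <- prod(d[1:3])
  nt <- d[4]
  sig <- matrix(series$signal, nvox, nt)
  s0 <- rowMeans(sig[, pre, drop = FALSE])
  t1 <- as.vector(t1map)

  ok <- is.finite(s0) & s0 > 0 & is.finite(t1) & t1 > 0
  conc <- matrix(NA_real_, nvox, nt)
  r1x <- protocol$contrast_relaxivity

  if (method == "spgr") {
    tr <- protocol$repetition_time
    cos_a <- cos(protocol$flip_angle * pi / 180)
    e10 <- exp(-tr / t1[ok])
    ratio <- sig[ok, , drop = FALSE] / s0[ok]
    e1 <- .spgr_invert_e1(ratio, e10, cos_a)
    bad <- !is.finite(e1) | e1 <= 0 | e1 >= 1
    e1[bad] <- NA_real_
    r1t <- -log(e1) / tr
    conc[ok, ] <- (r1t - 1 / t1[ok]) / r1x
    ok[ok] <- ok[ok] & rowSums(bad) == 0
  } else {
    ratio <- sig[ok, , drop = FALSE] / s0[ok]
    conc[ok, ] <- (ratio - 1) / (r1x * t1[ok])
  }
  conc[!ok, ] <- NA_real_

  new_conc_series(array(conc, d), series$frame_times / 60,
                  array(ok, d[1:3]), series$label)
}
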