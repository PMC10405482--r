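#' Dual-time-resolution DCE-MRI acquisition protocol
#'
#' Describes the spoiled gradient-echo (SPGR) readout and the frame timing of
#' the two interleaved dynamic sequences: a fast sequence that samples the
#' contrast bolus and a slow sequence that samples the pre-contrast baseline
#' and the long leakage tail. Both sequences acquire frames before contrast
#' injection.
#'
#' The frame layout on a single clock starting at 0 s is: the slow
#' pre-contrast frames first, then the full fast sequence (whose first
#' `n_precontrast_fast` frames precede the bolus), then the remaining slow
#' frames after the fast sequence ends.
#'
#' @param repetition_time SPGR repetition time TR, seconds.
#' @param flip_angle excitation flip angle, degrees.
#' @param fast_frame_interval,slow_frame_interval frame spacing of the fast
#'   and slow dynamic sequences, seconds.
#' @param n_fast_frames,n_slow_frames total frame counts per sequence.
#' @param n_precontrast_fast,n_precontrast_slow frames acquired before the
#'   contrast bolus in each sequence (at least 1 each).
#' @param bolus_arrival contrast arrival time, seconds. Defaults to the end
#'   of the fast pre-contrast block.
#' @param contrast_relaxivity longitudinal relaxivity r1 of the contrast
#'   agent, s^-1 mM^-1. Default 5.0 (gadobutrol at 3 T).
#' @return An object of class `acquisition_protocol`.
#' @export
acquisition_protocol <- function(repetition_time = 0.0056,
                                 flip_angle = 15,
                                 fast_frame_interval = 3.2,
                                 slow_frame_interval = 30,
                                 n_fast_frames = 40,
                                 n_slow_frames = 22,
                                 n_precontrast_fast = 4,
                                 n_precontrast_slow = 2,
                                 bolus_arrival = NULL,
                                 contrast_relaxivity = 5.0) {
  stopifnot(
    repetition_time > 0, flip_angle > 0,
    fast_frame_interval > 0, slow_frame_interval > 0,
    n_fast_frames >= 2, n_slow_frames >= 2,
    n_precontrast_fast >= 1, n_precontrast_slow >= 1,
    n_precontrast_fast < n_fast_frames,
    n_precontrast_slow < n_slow_frames,
    contrast_relaxivity > 0
  )
  fast_start <- n_precontrast_slow * slow_frame_interval
  if (is.null(bolus_arrival)) {
    bolus_arrival <- fast_start + n_precontrast_fast * fast_frame_interval
  }
  stopifnot(bolus_arrival > 0)
  p <- list(
    repetition_time = repetition_time,
    flip_angle = flip_angle,
    fast_frame_interval = fast_frame_interval,
    slow_frame_interval = slow_frame_interval,
    n_fast_frames = n_fast_frames,
    n_slow_frames = n_slow_frames,
    n_precontrast_fast = n_precontrast_fast,
    n_precontrast_slow = n_precontrast_slow,
    bolus_arrival = bolus_arrival,
    contrast_relaxivity = contrast_relaxivity
  )
  class(p) <- "acquisition_protocol"
  p
}

#' Frame timestamps of a protocol
#'
#' @param protocol an [acquisition_protocol()].
#' @return list with numeric vectors `fast` and `slow`, timestamps in seconds,
#'   strictly increasing within each sequence.
#' @export
protocol_frame_times <- function(protocol) {
  stopifnot(inherits(protocol, "acquisition_protocol"))
  p <- protocol
  slow_pre <- (seq_len(p$n_precontrast_slow) - 1) * p$slow_frame_interval
  fast_start <- p$n_precontrast_slow * p$slow_frame_interval
  fast <- fast_start + (seq_len(p$n_fast_frames) - 1) * p$fast_frame_interval
  fast_end <- fast[length(fast)]
  n_tail <- p$n_slow_frames - p$n_precontrast_slow
  slow_tail <- fast_end + seq_len(n_tail) * p$slow_frame_interval
  list(fast = fast, slow = c(slow_pre, slow_tail))
}

#' @export
print.acquisition_protocol <- function(x, ...) {
  ft <- protocol_frame_times(x)
  cat("DCE-MRI acquisition protocol\n")
  cat(sprintf("  SPGR: TR %.2f ms, flip %.1f deg, r1 %.2f /s/mM\n",
              1000 * x$repetition_time, x$flip_angle, x$contrast_relaxivity))
  cat(sprintf("  fast: %d frames @ %.1f s (%d pre-contrast)\n",
              x$n_fast_frames, x$fast_frame_interval, x$n_precontrast_fast))
  cat(sprintf("  slow: %d frames @ %.1f s (%d pre-contrast)\n",
              x$n_slow_frames, x$slow_frame_interval, x$n_precontrast_slow))
  cat(sprintf("  bolus arrival %.1f s, last frame %.1f min\n",
              x$bolus_arrival, max(ft$slow, ft$fast) / 60))
  invisible(x)
}
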