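#' Merge fast and slow concentration series onto one time axis
#'
#' Frames from both sequences are pooled and sorted by time. Where a slow
#' frame falls within half the fast frame interval of a fast frame, the fast
#' frame wins and the slow frame is dropped, so no timestamp is duplicated.
#' Voxels valid in both inputs remain valid.
#'
#' @param fast,slow `conc_series` objects on the same voxel grid (either may
#'   have zero frames).
#' @return a merged `conc_series` with strictly increasing `frame_times`.
#' @export
merge_dual_time <- function(fast, slow) {
  stopifnot(inherits(fast, "conc_series"), inherits(slow, "conc_series"))
  df <- dim(fast$concentration)[1:3]
  ds <- dim(slow$concentration)[1:3]
  if (!identical(df, ds)) stop("fast and slow series are on different voxel grids")
  nf <- length(fast$frame_times)
  ns <- length(slow$frame_times)
  if (ns == 0) return(new_conc_series(fast$concentration, fast$frame_times,
                                      fast$valid & slow$valid, "merged"))
  if (nf == 0) return(new_conc_series(slow$concentration, slow$frame_times,
                                      fast$valid & slow$valid, "merged"))

  fast_int <- stats::median(diff(fast$frame_times))
  near_fast <- vapply(slow$frame_times,
                      function(t) min(abs(t - fast$frame_times)) < fast_int / 2,
                      logical(1))
  keep_slow <- which(!near_fast)

  nvox <- prod(df)
  m <- cbind(matrix(fast$concentration, nvox, nf),
             matrix(slow$concentration, nvox, ns)[, keep_slow, drop = FALSE])
  times <- c(fast$frame_times, slow$frame_times[keep_slow])
  ord <- order(times)
  new_conc_series(array(m[, ord, drop = FALSE], c(df, length(ord))),
                  times[ord], fast$valid & slow$valid, "merged")
}

#' Extract the vascular input function from a blood-pool mask
#'
#' The plasma curve is the spatial mean of the concentration over the mask
#' at each frame. Voxels flagged invalid by the signal inversion are excluded
#' (with a message giving the count). When a hematocrit is supplied, the
#' blood curve is divided by `1 - hematocrit` to convert whole-blood to
#' plasma concentration; by default no correction is applied.
#'
#' @param conc a `conc_series`.
#' @param vif_mask 3D logical array (superior sagittal sinus region).
#' @param hematocrit optional fraction in [0, 1); `NULL` (default) disables
#'   the blood-to-plasma correction.
#' @return a `vif` object (`times` in minutes, `cp` in mM).
#' @export
extract_vif <- function(conc, vif_mask, hematocrit = NULL) {
  stopifnot(inherits(conc, "conc_series"),
            identical(dim(vif_mask), dim(conc$concentration)[1:3]))
  vif_mask <- vif_mask & TRUE
  if (!any(vif_mask)) stop("VIF mask is empty")
  n_invalid <- sum(vif_mask & !conc$valid)
  if (n_invalid > 0) {
    message(sprintf("extract_vif: excluding %d invalid voxel(s) from VIF mask",
                    n_invalid))
  }
  use <- vif_mask & conc$valid
  if (!any(use)) stop("no valid voxels inside the VIF mask")
  nvox <- prod(dim(vif_mask))
  m <- matrix(conc$concentration, nvox, length(conc$frame_times))
  cp <- colMeans(m[as.vector(use), , drop = FALSE])
  if (!is.null(hematocrit)) {
    stopifnot(hematocrit >= 0, hematocrit < 1)
    cp <- cp / (1 - hematocrit)
  }
  new_vif(conc$frame_times, cp)
}
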