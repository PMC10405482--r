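#' Patlak regressors on a tissue time grid
#'
#' Builds the two-column design of the Patlak model,
#' `C_t(t) = K_i * integral(C_p) + v_p * C_p(t)`: the running trapezoidal
#' integral of the plasma curve on the VIF grid and the plasma curve itself,
#' both linearly interpolated to the requested frame times.
#'
#' @param vif a `vif` object (times in minutes, cp in mM).
#' @param times_min tissue frame times, minutes.
#' @return matrix with columns `cum_cp` (mM min) and `cp` (mM).
#' @keywords internal
patlak_design <- function(vif, times_min) {
  cum <- as.vector(pracma::cumtrapz(vif$times, vif$cp))
  x1 <- stats::approx(vif$times, cum, xout = times_min, rule = 2)$y
  x2 <- stats::approx(vif$times, vif$cp, xout = times_min, rule = 2)$y
  cbind(cum_cp = x1, cp = x2)
}

# OLS for the no-intercept two-regressor Patlak model; Y may hold many voxels
# as columns. Returns list(coef 2 x V, r2 length V, ok scalar for design rank).
.patlak_ols <- function(X, Y) {
  qx <- qr(X)
  if (qx$rank < 2) {
    return(list(coef = matrix(NA_real_, 2, ncol(Y)),
                r2 = rep(NA_real_, ncol(Y)), ok = FALSE))
  }
  coef <- qr.coef(qx, Y)
  rss <- colSums((Y - X %*% coef)^2)
  tss <- colSums(Y^2)
  r2 <- ifelse(tss > 0, 1 - rss / tss, NA_real_)
  list(coef = coef, r2 = r2, ok = TRUE)
}

#' Fit the Patlak model to one voxel's concentration time-course
#'
#' Ordinary least squares of `C_t` on the cumulative plasma integral and the
#' plasma curve, with no intercept. The slope is the leakage rate K_i
#' (min^-1), the second coefficient the plasma fraction v_p. Negative K_i
#' estimates are retained — they carry the noise distribution that the
#' histogram mirroring correction relies on.
#'
#' @param ct concentration time-course, mM.
#' @param times_min frame times, minutes (same length as `ct`).
#' @param vif a `vif` object covering the fit window.
#' @param fit_window numeric length-2, minutes; only frames with
#'   `fit_window[1] <= t <= fit_window[2]` enter the fit. Default: all frames.
#' @return list with `ki` (min^-1), `vp`, `r2` and logical `valid`. A
#'   rank-deficient design or fewer than 3 usable frames gives
#'   `valid = FALSE` with `NA` estimates.
#' @export
patlak_fit_voxel <- function(ct, times_min, vif, fit_window = NULL) {
  stopifnot(length(ct) == length(times_min), inherits(vif, "vif"))
  sel <- rep(TRUE, length(ct))
  if (!is.null(fit_window)) {
    sel <- times_min >= fit_window[1] & times_min <= fit_window[2]
  }
  sel <- sel & is.finite(ct)
  if (sum(sel) < 3) {
    return(list(ki = NA_real_, vp = NA_real_, r2 = NA_real_, valid = FALSE))
  }
  X <- patlak_design(vif, times_min[sel])
  fit <- .patlak_ols(X, cbind(ct[sel]))
  if (!fit$ok) {
    return(list(ki = NA_real_, vp = NA_real_, r2 = NA_real_, valid = FALSE))
  }
  list(ki = unname(fit$coef[1, 1]), vp = unname(fit$coef[2, 1]),
       r2 = unname(fit$r2[1]), valid = TRUE)
}

#' Voxel-wise Patlak leakage map
#'
#' Applies the Patlak fit to every voxel of the analysis mask that survived
#' signal inversion, sharing one design matrix across voxels.
#'
#' @param conc a merged `conc_series`.
#' @param vif a `vif` object.
#' @param analysis_mask 3D logical array of voxels to fit.
#' @param fit_window numeric length-2, minutes (default: all frames).
#' @return a `ki_map`: 3D arrays `ki` (min^-1), `vp`, `r2` and logical
#'   `valid` (fitted voxels). Invalid-voxel counts are reported via `message`.
#' @export
patlak_fit_map <- function(conc, vif, analysis_mask, fit_window = NULL) {
  stopifnot(inherits(conc, "conc_series"), inherits(vif, "vif"),
            identical(dim(analysis_mask), dim(conc$concentration)[1:3]))
  analysis_mask <- analysis_mask & TRUE
  if (!any(analysis_mask)) stop("analysis mask is empty")
  n_invalid <- sum(analysis_mask & !conc$valid)
  use <- analysis_mask & conc$valid
  if (!any(use)) stop("no valid voxels inside the analysis mask")

  sel <- rep(TRUE, length(conc$frame_times))
  if (!is.null(fit_window)) {
    sel <- conc$frame_times >= fit_window[1] & conc$frame_times <= fit_window[2]
  }
  if (sum(sel) < 3) stop("fewer than 3 frames inside the fit window")

  d <- dim(analysis_mask)
  nvox <- prod(d)
  m <- matrix(conc$concentration, nvox, length(conc$frame_times))
  Y <- t(m[as.vector(use), sel, drop = FALSE])
  X <- patlak_design(vif, conc$frame_times[sel])
  fit <- .patlak_ols(X, Y)

  ki <- vp <- r2 <- array(NA_real_, d)
  valid <- array(FALSE, d)
  if (fit$ok) {
    ki[use] <- fit$coef[1, ]
    vp[use] <- fit$coef[2, ]
    r2[use] <- fit$r2
    valid[use] <- TRUE
  }
  message(sprintf("patlak_fit_map: %d voxels fitted, %d excluded as invalid",
                  sum(valid), n_invalid))
  structure(list(ki = ki, vp = vp, fit_quality = r2, valid = valid),
            class = "ki_map")
}
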