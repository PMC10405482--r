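const_vif <- function(times_min, value = 1) {
  bbbpatlak:::new_vif(times_min, rep(value, length(times_min)))
}

test_that("noiseless linear time-course gives exact (ki, vp)", {
  # C_p = 1 mM from t = 0, C_t = 1e-3 * t + 0.02 sampled at 1..10 min
  vif <- const_vif(0:10)
  t <- 1:10
  ct <- 1e-3 * t + 0.02
  fit <- patlak_fit_voxel(ct, t, vif)
  expect_equal(fit$ki, 1e-3, tolerance = 1e-12)
  expect_equal(fit$vp, 0.02, tolerance = 1e-12)
  expect_true(fit$valid)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
})

test_that("zero time-course fits to zero and rank deficiency is flagged", {
  vif <- const_vif(0:10)
  fit <- patlak_fit_voxel(rep(0, 10), 1:10, vif)
  expect_equal(fit$ki, 0)
  expect_equal(fit$vp, 0)

  # C_p == 0 over the window: two zero regressors, no unique solution
  zero_vif <- const_vif(0:10, 0)
  fit0 <- patlak_fit_voxel(1:10 * 1e-3, 1:10, zero_vif)
  expect_false(fit0$valid)
  expect_true(is.na(fit0$ki))

  # fewer than 3 usable frames
  expect_false(patlak_fit_voxel(c(1, 2), c(1, 2), vif)$valid)
})

test_that("OLS matches the brute-force SSE grid search on noisy voxels", {
  prot <- short_protocol()
  vif <- simulate_vif(prot, peak_conc = 5)
  X <- bbbpatlak:::patlak_design(vif, vif$times)
  set.seed(41)
  for (rep in 1:20) {
    ki_true <- runif(1, -1e-3, 3e-3)
    vp_true <- runif(1, 0.005, 0.03)
    ct <- ki_true * X[, 1] + vp_true * X[, 2] + rnorm(nrow(X), 0, 2e-3)
    fit <- patlak_fit_voxel(ct, vif$times, vif)
    oracle <- patlak_grid_oracle(ct, vif$times, vif,
                                 ki_range = fit$ki + c(-30, 30) * 1e-5,
                                 vp_range = fit$vp + c(-30, 30) * 1e-4)
    expect_lte(abs(fit$ki - oracle$ki), oracle$ki_step)
    expect_lte(abs(fit$vp - oracle$vp), oracle$vp_step)
  }
})

test_that("voxel estimates are unbiased and symmetric under the null", {
  prot <- short_protocol()
  vif <- simulate_vif(prot, peak_conc = 5)
  X <- bbbpatlak:::patlak_design(vif, vif$times)
  XtXinv_Xt <- solve(crossprod(X), t(X))
  ki_true <- 2e-3; vp_true <- 0.015; sigma <- 3e-3
  set.seed(7)
  n_rep <- 10000
  noise <- matrix(rnorm(nrow(X) * n_rep, 0, sigma), nrow(X), n_rep)
  ct0 <- ki_true * X[, 1] + vp_true * X[, 2]
  est <- XtXinv_Xt %*% (ct0 + noise)
  se_mean <- sd(est[1, ]) / sqrt(n_rep)
  expect_lt(abs(mean(est[1, ]) - ki_true), 3 * se_mean)

  # under ki_true = 0, the ki estimate distribution is symmetric:
  est0 <- XtXinv_Xt %*% (vp_true * X[, 2] + noise)
  k <- est0[1, ] - mean(est0[1, ])
  skew <- mean(k^3) / mean(k^2)^1.5
  expect_lt(abs(skew), 0.1)
})

test_that("the fit is invariant to joint scaling of tissue and plasma curves", {
  vif <- const_vif(0:10, 2)
  t <- 1:10
  ct <- 2e-3 * t * 2 + 0.01 * 2
  f1 <- patlak_fit_voxel(ct, t, vif)
  vif2 <- bbbpatlak:::new_vif(0:10, rep(4, 11))
  f2 <- patlak_fit_voxel(2 * ct, t, vif2)
  expect_equal(f1$ki, f2$ki, tolerance = 1e-10)
  expect_equal(f1$vp, f2$vp, tolerance = 1e-10)
})

test_that("map fitting agrees with the single-voxel path and recovers truth", {
  prot <- short_protocol()
  cfg <- tiny_config(signal_noise_sd = 0)
  s <- simulate_subject(cfg, prot, 1)
  cf <- signal_to_concentration(s$dce_fast, s$t1map, prot)
  cs <- signal_to_concentration(s$dce_slow, s$t1map, prot)
  merged <- merge_dual_time(cf, cs)
  vif <- extract_vif(merged, s$masks$vif)
  mask <- s$masks$nawm | s$masks$wmh
  window <- c(prot$bolus_arrival / 60, Inf)
  km <- suppressMessages(patlak_fit_map(merged, vif, mask, window))

  # noiseless forward model is recovered to numerical precision
  expect_lt(max(abs(km$ki[mask] - s$truth$ki_true[mask])), 1e-9)
  expect_lt(max(abs(km$vp[mask] - s$truth$vp_true[mask])), 1e-9)

  # single-voxel consistency
  idx <- which(mask & s$truth$leaking, arr.ind = TRUE)[1, , drop = FALSE]
  one <- array(FALSE, dim(mask)); one[idx] <- TRUE
  km1 <- suppressMessages(patlak_fit_map(merged, vif, one, window))
  sel <- merged$frame_times >= window[1]
  fv <- patlak_fit_voxel(merged$concentration[idx[1], idx[2], idx[3], ][sel],
                         merged$frame_times[sel], vif)
  expect_equal(km1$ki[one], fv$ki, tolerance = 1e-12)
  expect_equal(km1$vp[one], fv$vp, tolerance = 1e-12)

  expect_error(patlak_fit_map(merged, vif, array(FALSE, dim(mask))), "empty")
})
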