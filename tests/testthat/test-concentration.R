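make_series <- function(sig_matrix, times_s, d = NULL) {
  # sig_matrix: frames in columns, voxels in rows
  if (is.null(d)) d <- c(nrow(sig_matrix), 1, 1)
  dce_series(array(sig_matrix, c(d, ncol(sig_matrix))), times_s, "fast")
}

test_that("constant baseline signal maps to zero concentration", {
  prot <- short_protocol()
  ft <- protocol_frame_times(prot)$fast
  t1 <- array(0.95, c(3, 1, 1))
  s0 <- spgr_signal(1 / 0.95, prot$repetition_time, prot$flip_angle, 100)
  sig <- matrix(s0, 3, length(ft))
  conc <- signal_to_concentration(make_series(sig, ft), t1, prot)
  expect_true(all(abs(conc$concentration) < 1e-12))
  expect_true(all(conc$valid))
  expect_equal(conc$frame_times, ft / 60)
})

test_that("SPGR forward/inverse round trip recovers concentration to 1e-6 mM", {
  prot <- short_protocol()
  ft <- protocol_frame_times(prot)$fast
  # property sweep over flip angle, TR, T1 and concentration
  grid <- expand.grid(flip = c(2, 10, 25, 40, 59),
                      tr = c(0.0025, 0.005, 0.012, 0.019),
                      t1 = c(0.35, 0.9, 1.6, 3.9),
                      C = c(0, 0.05, 0.5, 2, 5))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    p <- acquisition_protocol(repetition_time = g$tr, flip_angle = g$flip,
                              n_fast_frames = prot$n_fast_frames,
                              n_precontrast_fast = prot$n_precontrast_fast)
    ftp <- protocol_frame_times(p)$fast
    C_t <- ifelse(ftp < p$bolus_arrival, 0, g$C)
    r1 <- 1 / g$t1 + p$contrast_relaxivity * C_t
    sig <- matrix(spgr_signal(r1, g$tr, g$flip, 50), 1, length(ftp),
                  byrow = TRUE)
    conc <- signal_to_concentration(make_series(sig, ftp, c(1, 1, 1)),
                                    array(g$t1, c(1, 1, 1)), p)
    expect_lt(max(abs(conc$concentration[1, 1, 1, ] - C_t)), 1e-6)
  }
})

test_that("concentration scales inversely with relaxivity", {
  prot <- short_protocol()
  ft <- protocol_frame_times(prot)$fast
  C_t <- ifelse(ft < prot$bolus_arrival, 0, 0.8)
  r1 <- 1 / 1.1 + prot$contrast_relaxivity * C_t
  sig <- matrix(spgr_signal(r1, prot$repetition_time, prot$flip_angle, 80),
                1, length(ft), byrow = TRUE)
  series <- make_series(sig, ft, c(1, 1, 1))
  t1 <- array(1.1, c(1, 1, 1))
  c1 <- signal_to_concentration(series, t1, prot)
  prot2 <- prot
  prot2$contrast_relaxivity <- 2 * prot$contrast_relaxivity
  c2 <- signal_to_concentration(series, t1, prot2)
  expect_equal(c2$concentration, c1$concentration / 2, tolerance = 1e-12)
})

test_that("unattainable signal ratios flag the voxel instead of clamping", {
  prot <- short_protocol()
  ft <- protocol_frame_times(prot)$fast
  s0 <- spgr_signal(1 / 0.95, prot$repetition_time, prot$flip_angle, 100)
  sig <- matrix(s0, 2, length(ft))
  sig[2, length(ft)] <- 20 * s0          # ratio far beyond the SPGR ceiling
  conc <- signal_to_concentration(make_series(sig, ft, c(2, 1, 1)),
                                  array(0.95, c(2, 1, 1)), prot)
  expect_true(conc$valid[1, 1, 1])
  expect_false(conc$valid[2, 1, 1])
  expect_true(all(is.na(conc$concentration[2, 1, 1, ])))
})

test_that("merging keeps fast frames on ties and sorts timestamps", {
  d <- c(2, 2, 1)
  fast <- toy_conc(c(10, 11, 12), c(0, 1, 2) / 60, d)
  slow_disjoint <- toy_conc(c(20, 21), c(10, 20) / 60, d)
  m <- merge_dual_time(fast, slow_disjoint)
  expect_equal(m$frame_times * 60, c(0, 1, 2, 10, 20))
  expect_equal(m$concentration[1, 1, 1, ], c(10, 11, 12, 20, 21))

  # tie within half the fast interval: fast frame wins, no duplicates
  slow_tied <- toy_conc(c(99, 30), c(2, 10) / 60, d)
  m2 <- merge_dual_time(fast, slow_tied)
  expect_equal(m2$frame_times * 60, c(0, 1, 2, 10))
  expect_equal(m2$concentration[1, 1, 1, ], c(10, 11, 12, 30))
  expect_true(all(diff(m2$frame_times) > 0))

  # empty slow series: identity
  slow_empty <- toy_conc(numeric(0), numeric(0), d)
  m3 <- merge_dual_time(fast, slow_empty)
  expect_equal(m3$frame_times, fast$frame_times)
  expect_equal(m3$concentration, fast$concentration)

  # mismatched grids
  expect_error(merge_dual_time(fast, toy_conc(1, 1, c(3, 3, 1))), "grid")
})

test_that("VIF extraction averages the mask, honours hematocrit and scales linearly", {
  d <- c(2, 2, 1)
  conc <- toy_conc(c(1, 2), c(1, 2) / 60, d)
  conc$concentration[2, 1, 1, 1] <- 3     # voxels 1 and 3 mM at frame 1
  mask <- array(FALSE, d); mask[1:2, 1, 1] <- TRUE
  v <- extract_vif(conc, mask)
  expect_equal(v$cp[1], 2)                # mean of 1 and 3

  uniform <- toy_conc(c(1, 1.5), c(1, 2) / 60, d)
  expect_equal(extract_vif(uniform, mask)$cp, c(1, 1.5))
  expect_equal(extract_vif(uniform, mask, hematocrit = 0.45)$cp,
               c(1, 1.5) / 0.55)

  scaled <- uniform
  scaled$concentration <- 3 * uniform$concentration
  expect_equal(extract_vif(scaled, mask)$cp, 3 * extract_vif(uniform, mask)$cp)

  expect_error(extract_vif(uniform, array(FALSE, d)), "empty")
  bad <- uniform; bad$valid[1, 1, 1] <- FALSE
  expect_message(extract_vif(bad, mask), "1 invalid")
})
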