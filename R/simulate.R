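#' Synthetic-cohort simulation configuration
#'
#' Parameters of the seeded cohort generator. Group-level design targets
#' (leaking fractions, mean leakage rates, WMH relative volumes, plasma
#' VEGFA) default to the clinical cohort the pipeline is meant to emulate;
#' the default cohort size is scaled down to 20 patients + 20 controls so a
#' full simulate-fit-report cycle runs in minutes on one CPU.
#'
#' All `*_nawm` / `*_wmh` group parameters are named vectors with entries
#' `control` and `patient`. K_i values are in min^-1, VEGFA in pg/ml.
#'
#' @param n_patients,n_controls cohort sizes (sum >= 2).
#' @param voxel_grid 3 integers, simulation grid.
#' @param leak_fraction_nawm,leak_fraction_wmh per-group mean fraction of
#'   leaking voxels per tissue.
#' @param leak_fraction_sd between-subject SD of the leaking fraction.
#' @param ki_mean_nawm,ki_mean_wmh per-group mean K_i of leaking voxels,
#'   min^-1.
#' @param ki_between_sd between-subject SD of the subject-level mean K_i.
#' @param ki_sd within-subject voxel SD of true K_i in leaking voxels
#'   (Gaussian truncated at 0).
#' @param vp_mean plasma volume fraction of tissue voxels.
#' @param signal_noise_sd additive Gaussian signal noise, as a fraction of
#'   the voxel's pre-contrast baseline signal.
#' @param wmh_rel_volume per-group mean WMH volume relative to the brain
#'   grid (dimensionless).
#' @param vegfa_mean,vegfa_sd per-group plasma VEGFA mean and SD, pg/ml
#'   (draws truncated at 0).
#' @param vegfa_ki_slope coupling of a patient's NAWM mean K_i to their
#'   VEGFA deviation from the patient group mean, (min^-1)/(pg/ml).
#' @param age_range uniform age range, years.
#' @param sex_ratio probability of female sex.
#' @param peak_conc,washout_rate vascular input function parameters
#'   (mM, min^-1).
#' @param rng_seed master seed; identical seed gives a bit-identical cohort.
#' @return a `simulation_config` object.
#' @export
simulation_config <- function(n_patients = 20, n_controls = 20,
                              voxel_grid = c(24, 24, 12),
                              leak_fraction_nawm = c(control = 0.276, patient = 0.370),
                              leak_fraction_wmh = c(control = 0.318, patient = 0.459),
                              leak_fraction_sd = 0.05,
                              ki_mean_nawm = c(control = 1.09e-3, patient = 0.98e-3),
                              ki_mean_wmh = c(control = 0.85e-3, patient = 0.84e-3),
                              ki_between_sd = 0.30e-3,
                              ki_sd = 0.25e-3,
                              vp_mean = 0.01,
                              signal_noise_sd = 0.02,
                              wmh_rel_volume = c(control = 3.5e-3, patient = 16.1e-3),
                              vegfa_mean = c(control = 14.45, patient = 25.26),
                              vegfa_sd = c(control = 10.6, patient = 21.0),
                              vegfa_ki_slope = 4.5e-6,
                              age_range = c(55, 85),
                              sex_ratio = 0.35,
                              peak_conc = 5,
                              washout_rate = 0.06,
                              rng_seed = 20231L) {
  grp <- function(v) {
    stopifnot(all(c("control", "patient") %in% names(v)))
    v[c("control", "patient")]
  }
  cfg <- list(
    n_patients = as.integer(n_patients), n_controls = as.integer(n_controls),
    voxel_grid = as.integer(voxel_grid),
    leak_fraction_nawm = grp(leak_fraction_nawm),
    leak_fraction_wmh = grp(leak_fraction_wmh),
    leak_fraction_sd = leak_fraction_sd,
    ki_mean_nawm = grp(ki_mean_nawm), ki_mean_wmh = grp(ki_mean_wmh),
    ki_between_sd = ki_between_sd, ki_sd = ki_sd,
    vp_mean = vp_mean, signal_noise_sd = signal_noise_sd,
    wmh_rel_volume = grp(wmh_rel_volume),
    vegfa_mean = grp(vegfa_mean), vegfa_sd = grp(vegfa_sd),
    vegfa_ki_slope = vegfa_ki_slope,
    age_range = age_range, sex_ratio = sex_ratio,
    peak_conc = peak_conc, washout_rate = washout_rate,
    rng_seed = as.integer(rng_seed)
  )
  stopifnot(
    cfg$n_patients >= 0, cfg$n_controls >= 0,
    cfg$n_patients + cfg$n_controls >= 2,
    length(cfg$voxel_grid) == 3, all(cfg$voxel_grid >= 1),
    all(cfg$leak_fraction_nawm >= 0), all(cfg$leak_fraction_nawm <= 1),
    all(cfg$leak_fraction_wmh >= 0), all(cfg$leak_fraction_wmh <= 1),
    cfg$ki_sd >= 0, cfg$ki_between_sd >= 0, cfg$leak_fraction_sd >= 0,
    cfg$vp_mean >= 0, cfg$signal_noise_sd >= 0,
    all(cfg$vegfa_sd >= 0), cfg$sex_ratio >= 0, cfg$sex_ratio <= 1,
    cfg$age_range[1] < cfg$age_range[2]
  )
  class(cfg) <- "simulation_config"
  cfg
}

# Deterministic per-subject seed below 2^31, derived from the master seed so
# cohorts are reproducible under any generation order.
subject_seed <- function(config, subject_index) {
  as.integer((abs(config$rng_seed) %% 99991L) * 20011L + subject_index * 211L)
}

.subject_group <- function(config, subject_index) {
  if (subject_index <= config$n_patients) "patient" else "control"
}

# Draws truncated at `lower` by redrawing (means are many SDs above zero, so
# rejection is cheap and keeps the stream deterministic).
.rnorm_trunc <- function(n, mean, sd, lower = 0) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lower)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

# Covariates and subject-level ground-truth parameters. Must be called inside
# the subject's RNG stream; draw order is part of the determinism contract.
.draw_subject_params <- function(config, subject_index, group) {
  g <- group
  age <- stats::runif(1, config$age_range[1], config$age_range[2])
  sex <- if (stats::runif(1) < config$sex_ratio) "female" else "male"
  vegfa <- .rnorm_trunc(1, config$vegfa_mean[[g]], config$vegfa_sd[[g]],
                        lower = 0.5)
  ki_nawm <- .rnorm_trunc(1, config$ki_mean_nawm[[g]], config$ki_between_sd,
                          lower = 1e-4)
  ki_wmh <- .rnorm_trunc(1, config$ki_mean_wmh[[g]], config$ki_between_sd,
                         lower = 1e-4)
  if (g == "patient") {
    ki_nawm <- max(1e-4,
                   ki_nawm + config$vegfa_ki_slope *
                     (vegfa - config$vegfa_mean[["patient"]]))
  }
  clamp01 <- function(x) min(max(x, 0.02), 0.95)
  lf_nawm <- clamp01(stats::rnorm(1, config$leak_fraction_nawm[[g]],
                                  config$leak_fraction_sd))
  lf_wmh <- clamp01(stats::rnorm(1, config$leak_fraction_wmh[[g]],
                                 config$leak_fraction_sd))
  wmh_rel <- max(2 / prod(config$voxel_grid),
                 stats::rnorm(1, config$wmh_rel_volume[[g]],
                              0.25 * config$wmh_rel_volume[[g]]))
  list(age = age, sex = sex, vegfa = vegfa,
       ki_nawm = ki_nawm, ki_wmh = ki_wmh,
       leak_nawm = lf_nawm, leak_wmh = lf_wmh, wmh_rel = wmh_rel)
}

# Box-shaped tissue masks: a VIF block in one corner, a white-matter slab,
# and a WMH box carved out of its centre sized to the target relative volume.
.make_masks <- function(grid, wmh_rel) {
  nx <- grid[1]; ny <- grid[2]; nz <- grid[3]
  if (nx < 10 || ny < 10 || nz < 5) {
    stop("voxel grid too small to place disjoint VIF, NAWM and WMH masks")
  }
  vif <- array(FALSE, grid)
  vif[1:3, 1:3, 1:3] <- TRUE

  wm <- array(FALSE, grid)
  wm[5:(nx - 1), 5:(ny - 1), 2:(nz - 1)] <- TRUE

  target <- max(2, round(wmh_rel * prod(grid)))
  a <- max(1, round(target^(1 / 3)))
  b <- max(1, round(sqrt(target / a)))
  cc <- max(1, round(target / (a * b)))
  wdim <- c(a, b, cc)
  wm_dim <- c(nx - 5, ny - 5, nz - 2)
  if (any(wdim > wm_dim)) {
    stop("voxel grid too small for the requested WMH relative volume")
  }
  lo <- pmax(c(5, 5, 2), c(5, 5, 2) + (wm_dim - wdim) %/% 2)
  wmh <- array(FALSE, grid)
  wmh[lo[1]:(lo[1] + wdim[1] - 1),
      lo[2]:(lo[2] + wdim[2] - 1),
      lo[3]:(lo[3] + wdim[3] - 1)] <- TRUE
  nawm <- wm & !wmh
  list(nawm = nawm, wmh = wmh, vif = vif)
}

#' Simulate one synthetic subject
#'
#' Forward model: true K_i is drawn per voxel (zero-truncated Gaussian in a
#' random subset of leaking voxels, exactly zero elsewhere); tissue
#' concentration follows the Patlak kinetics
#' `C_t(t) = K_i * integral(C_p) + v_p * C_p(t)` against a parametric
#' vascular input function (VIF voxels carry the plasma curve itself,
#' `v_p = 1`); SPGR signal is synthesized per frame from the T1 map and
#' additive Gaussian noise is applied on the signal, not the concentration.
#'
#' Subject `i` always produces the same output for a given configuration:
#' its RNG stream is seeded from `(rng_seed, i)`.
#'
#' @param config a [simulation_config()].
#' @param protocol an [acquisition_protocol()].
#' @param subject_index 1-based index; patients come first, then controls.
#' @return a `synthetic_subject`: `dce_fast`/`dce_slow` ([dce_series()]),
#'   `t1map`, `masks` (list `nawm`, `wmh`, `vif`), `truth` (`ki_true`,
#'   `vp_true`, `leaking`, plus subject-level summary `vl_*_true`,
#'   `ki_*_true`), and `record` (one-row covariate data frame).
#' @export
simulate_subject <- function(config, protocol, subject_index) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(protocol, "acquisition_protocol"),
            subject_index >= 1,
            subject_index <= config$n_patients + config$n_controls)
  group <- .subject_group(config, subject_index)
  grid <- config$voxel_grid

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(subject_seed(config, subject_index))

  par <- .draw_subject_params(config, subject_index, group)
  masks <- .make_masks(grid, par$wmh_rel)

  ki_true <- array(0, grid)
  leaking <- array(FALSE, grid)
  for (tissue in c("nawm", "wmh")) {
    idx <- which(masks[[tissue]])
    n_leak <- round(par[[paste0("leak_", tissue)]] * length(idx))
    if (n_leak > 0) {
      sel <- sample(idx, n_leak)
      leaking[sel] <- TRUE
      ki_true[sel] <- .rnorm_trunc(n_leak, par[[paste0("ki_", tissue)]],
                                   config$ki_sd, lower = 0)
    }
  }
  vp_true <- array(config$vp_mean, grid)
  vp_true[masks$vif] <- 1

  t1 <- array(1.1, grid)
  t1[masks$nawm] <- 0.95
  t1[masks$wmh] <- 1.25
  t1[masks$vif] <- 1.65

  ft <- protocol_frame_times(protocol)
  t_all <- sort(unique(c(ft$fast, ft$slow)))
  cp <- vif_conc(t_all, protocol$bolus_arrival,
                 config$peak_conc, config$washout_rate)
  cum_cp <- as.vector(pracma::cumtrapz(t_all / 60, cp))

  conc <- outer(as.vector(ki_true), cum_cp) +
    outer(as.vector(vp_true), cp)
  conc[as.vector(masks$vif), ] <- rep(cp, each = sum(masks$vif))

  r1 <- 1 / as.vector(t1) + protocol$contrast_relaxivity * conc
  m0 <- 100
  sig <- spgr_signal(r1, protocol$repetition_time, protocol$flip_angle, m0)
  if (config$signal_noise_sd > 0) {
    s0 <- spgr_signal(1 / as.vector(t1), protocol$repetition_time,
                      protocol$flip_angle, m0)
    sig <- sig + stats::rnorm(length(sig)) * config$signal_noise_sd * s0
  }

  take <- function(times) {
    cols <- match(times, t_all)
    array(sig[, cols], c(grid, length(times)))
  }
  truth_summary <- list(
    vl_nawm_true = mean(leaking[masks$nawm]),
    vl_wmh_true = mean(leaking[masks$wmh]),
    ki_nawm_true = par$ki_nawm, ki_wmh_true = par$ki_wmh,
    wmh_rel_volume_true = sum(masks$wmh) / prod(grid)
  )
  record <- data.frame(
    subject_id = sprintf("sub-%03d", subject_index),
    group = group, age = par$age, sex = par$sex,
    vegfa_pg_ml = par$vegfa, stringsAsFactors = FALSE
  )
  structure(list(
    dce_fast = dce_series(take(ft$fast), ft$fast, "fast"),
    dce_slow = dce_series(take(ft$slow), ft$slow, "slow"),
    t1map = t1, masks = masks,
    truth = c(list(ki_true = ki_true, vp_true = vp_true, leaking = leaking),
              truth_summary),
    record = record
  ), class = "synthetic_subject")
}

#' Simulate a full synthetic cohort
#'
#' Generates every subject (patients first, then controls). With `out_dir`
#' the subjects are written to disk as NIfTI volumes with JSON timestamp
#' sidecars plus a `cohort.csv`, and a manifest is returned; with
#' `out_dir = NULL` the subjects are returned in memory.
#'
#' @param config a [simulation_config()].
#' @param protocol an [acquisition_protocol()].
#' @param out_dir output directory (created if missing), or `NULL`.
#' @return with `out_dir`: a `cohort_manifest` (list of subject entries,
#'   config hash, paths). Without: list with `subjects` (list of
#'   `synthetic_subject`), `cohort` (covariate data frame) and `truth`
#'   (per-subject ground-truth summary data frame).
#' @export
simulate_cohort <- function(config, protocol, out_dir = NULL) {
  n <- config$n_patients + config$n_controls
  subjects <- lapply(seq_len(n), function(i) {
    simulate_subject(config, protocol, i)
  })
  cohort <- do.call(rbind, lapply(subjects, `[[`, "record"))
  truth <- do.call(rbind, lapply(subjects, function(s) {
    data.frame(subject_id = s$record$subject_id,
               vl_nawm_true = s$truth$vl_nawm_true,
               vl_wmh_true = s$truth$vl_wmh_true,
               ki_nawm_true = s$truth$ki_nawm_true,
               ki_wmh_true = s$truth$ki_wmh_true,
               wmh_rel_volume_true = s$truth$wmh_rel_volume_true,
               stringsAsFactors = FALSE)
  }))
  if (is.null(out_dir)) {
    return(list(subjects = subjects, cohort = cohort, truth = truth))
  }
  write_cohort_dir(subjects, cohort, config, protocol, out_dir)
}

#' Tabular-only synthetic cohort
#'
#' Draws the subject-level records (covariates plus tissue leakage
#' summaries with a small measurement-error term) without synthesizing any
#' imaging, for fast statistical-layer simulations. Uses the same
#' per-subject RNG streams and ground-truth distributions as
#' [simulate_subject()].
#'
#' @param config a [simulation_config()].
#' @param ki_meas_sd,vl_meas_sd SD of the added measurement error on the
#'   subject-level mean K_i (min^-1) and v_L, emulating the Patlak +
#'   histogram estimation step.
#' @return data frame with columns `subject_id`, `group`, `age`, `sex`,
#'   `vegfa`, `wmh_rel_volume`, `ki_nawm`, `ki_wmh` (10^-3 min^-1),
#'   `vl_nawm`, `vl_wmh`.
#' @export
simulate_cohort_table <- function(config, ki_meas_sd = 0.1e-3,
                                  vl_meas_sd = 0.02) {
  n <- config$n_patients + config$n_controls
  rows <- lapply(seq_len(n), function(i) {
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old_seed)) {
      assign(".Random.seed", old_seed, globalenv())
    })
    set.seed(subject_seed(config, i))
    group <- .subject_group(config, i)
    par <- .draw_subject_params(config, i, group)
    data.frame(
      subject_id = sprintf("sub-%03d", i), group = group,
      age = par$age, sex = par$sex, vegfa = par$vegfa,
      wmh_rel_volume = par$wmh_rel,
      ki_nawm = 1e3 * max(0, par$ki_nawm + stats::rnorm(1, 0, ki_meas_sd)),
      ki_wmh = 1e3 * max(0, par$ki_wmh + stats::rnorm(1, 0, ki_meas_sd)),
      vl_nawm = min(1, max(0, par$leak_nawm + stats::rnorm(1, 0, vl_meas_sd))),
      vl_wmh = min(1, max(0, par$leak_wmh + stats::rnorm(1, 0, vl_meas_sd))),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
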