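#' @importFrom RNifti readNifti writeNifti
NULL

.write_volume <- function(arr, path) {
  RNifti::writeNifti(arr * 1, path)   # coerce logical masks to numeric
  path
}

.write_series <- function(series, path) {
  RNifti::writeNifti(series$signal, path)
  sidecar <- sub("\\.nii(\\.gz)?$", "_timing.json", path)
  jsonlite::write_json(list(frame_times_s = series$frame_times),
                       sidecar, digits = NA)
  path
}

# drop the niftiImage class/attributes, keep a plain numeric array
.strip_nifti <- function(img) {
  a <- as.array(img)
  array(as.numeric(a), dim(a))
}

.read_series <- function(path, label) {
  sidecar <- sub("\\.nii(\\.gz)?$", "_timing.json", path)
  times <- jsonlite::read_json(sidecar, simplifyVector = TRUE)$frame_times_s
  dce_series(.strip_nifti(RNifti::readNifti(path)), times, label)
}

#' Write a simulated cohort to disk
#'
#' One directory per subject holding NIfTI volumes (`dce_fast.nii.gz`,
#' `dce_slow.nii.gz`, `t1map.nii.gz`, tissue masks, ground-truth K_i / v_p
#' maps) with JSON timestamp sidecars, plus `cohort.csv`
#' (`subject_id,group,age,sex,vegfa_pg_ml`), the ground-truth summary table
#' and a `manifest.json` carrying the configuration hash.
#'
#' @param subjects list of `synthetic_subject` objects.
#' @param cohort covariate data frame.
#' @param config,protocol the generating configuration (hashed into the
#'   manifest).
#' @param out_dir target directory.
#' @return a `cohort_manifest` (invisible file path in `$path`).
#' @keywords internal
write_cohort_dir <- function(subjects, cohort, config, protocol, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(subjects, function(s) {
    sd <- file.path(out_dir, s$record$subject_id)
    dir.create(sd, showWarnings = FALSE)
    .write_series(s$dce_fast, file.path(sd, "dce_fast.nii.gz"))
    .write_series(s$dce_slow, file.path(sd, "dce_slow.nii.gz"))
    .write_volume(s$t1map, file.path(sd, "t1map.nii.gz"))
    .write_volume(s$masks$nawm, file.path(sd, "mask_nawm.nii.gz"))
    .write_volume(s$masks$wmh, file.path(sd, "mask_wmh.nii.gz"))
    .write_volume(s$masks$vif, file.path(sd, "mask_vif.nii.gz"))
    .write_volume(s$truth$ki_true, file.path(sd, "ki_true.nii.gz"))
    .write_volume(s$truth$vp_true, file.path(sd, "vp_true.nii.gz"))
    list(subject_id = s$record$subject_id, group = s$record$group,
         dir = s$record$subject_id)
  })
  utils::write.csv(cohort, file.path(out_dir, "cohort.csv"),
                   row.names = FALSE)
  manifest <- list(subjects = entries,
                   config_hash = rlang::hash(config),
                   protocol_hash = rlang::hash(unclass(protocol)),
                   rng_seed = config$rng_seed,
                   path = out_dir)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  class(manifest) <- "cohort_manifest"
  manifest
}

#' Read a cohort manifest
#'
#' @param path manifest file or the cohort directory containing
#'   `manifest.json`.
#' @return a `cohort_manifest`.
#' @export
read_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.json")
  m <- jsonlite::read_json(path, simplifyVector = FALSE)
  m$path <- dirname(path)
  class(m) <- "cohort_manifest"
  m
}

#' Read one subject's volumes from a cohort directory
#'
#' @param dir subject directory written by [simulate_cohort()].
#' @return list with `dce_fast`, `dce_slow`, `t1map`, `masks`.
#' @export
read_subject <- function(dir) {
  vol <- function(f) .strip_nifti(RNifti::readNifti(file.path(dir, f)))
  list(
    dce_fast = .read_series(file.path(dir, "dce_fast.nii.gz"), "fast"),
    dce_slow = .read_series(file.path(dir, "dce_slow.nii.gz"), "slow"),
    t1map = vol("t1map.nii.gz"),
    masks = list(nawm = vol("mask_nawm.nii.gz") > 0.5,
                 wmh = vol("mask_wmh.nii.gz") > 0.5,
                 vif = vol("mask_vif.nii.gz") > 0.5)
  )
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file whose `protocol` and `simulation` sections are passed
#' to [acquisition_protocol()] and [simulation_config()]; remaining entries
#' (`bin_width`, `hematocrit`, `inversion_method`) are kept as options.
#'
#' @param path YAML file.
#' @return list with `protocol`, `simulation`, `options`.
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  protocol <- do.call(acquisition_protocol, as.list(y$protocol))
  sim <- y$simulation
  if (!is.null(sim)) {
    for (nm in grep("^(leak_fraction|ki_mean|wmh_rel|vegfa_mean|vegfa_sd)",
                    names(sim), value = TRUE)) {
      sim[[nm]] <- unlist(sim[[nm]])
    }
    sim <- do.call(simulation_config, sim)
  }
  opts <- y[setdiff(names(y), c("protocol", "simulation"))]
  list(protocol = protocol, simulation = sim, options = opts)
}
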