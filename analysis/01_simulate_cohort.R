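#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study cohort.
#
# 20 cSVD-like patients and 20 controls on a 24 x 24 x 12 grid with the
# default group targets (leaking fractions, mean K_i, WMH volume, plasma
# VEGFA). Imaging volumes go to scratch/ (large, regenerable); the covariate
# table is copied to results/.

library(bbbpatlak)

protocol <- acquisition_protocol()
config <- simulation_config()

cat("Simulating", config$n_patients, "patients and", config$n_controls,
    "controls (seed", config$rng_seed, ")\n")
print(protocol)

manifest <- simulate_cohort(config, protocol, "scratch/cohort")

dir.create("results", showWarnings = FALSE)
invisible(file.copy("scratch/cohort/cohort.csv", "results/cohort.csv", overwrite = TRUE))

cat("Wrote", length(manifest$subjects), "subjects to scratch/cohort",
    "(config hash", manifest$config_hash, ")\n")
cat("Covariate table: results/cohort.csv\n")
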