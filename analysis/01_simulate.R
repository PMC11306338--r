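#!/usr/bin/env Rscript
# Simulate the study's experimental conditions as synthetic cohorts.
#
# Four cohorts of 22 runs (the assay's average repeat count), all sampled at
# 1 Hz over 600 s:
#   control_32, control_35, control_39 - homogeneous ambient heating to
#     31.9 / 34.9 / 39.1 C (enclosure pre-heated; sample essentially
#     equilibrated on arrival),
#   ramped_35 - same 35 C end temperature, but the enclosure sits 7 C lower
#     with the balance supplied by steady local heating, so the sample
#     arrives cold and warms during the early observation window (the
#     microwave / IR-laser / hot-air geometry).
#
# Trace CSVs and ground-truth sidecars go to scratch/sim/ (bulk, not part of
# the deliverable); the manifests there are consumed by 02_features.R.

library(turbikin)

out_dir <- "scratch/sim"
seed0 <- 20260925L

conditions <- list(
  control_32 = thermal_profile(T_ambient = 31.9, tau_equil = 1),
  control_35 = thermal_profile(T_ambient = 34.9, tau_equil = 1),
  control_39 = thermal_profile(T_ambient = 39.1, tau_equil = 1),
  ramped_35  = thermal_profile(T_ambient = 34.9 - 7, T_local = 7,
                               tau_equil = 7)
)

params <- kinetic_params()  # defaults include 10% bubble artifacts

for (i in seq_along(conditions)) {
  name <- names(conditions)[i]
  manifest <- write_cohort(22, params, conditions[[i]], dir = out_dir,
                           seed = seed0 + i, condition = name)
  m <- read_manifest(manifest)
  cat(sprintf("%-11s -> %2d runs, target %.1f C, manifest %s\n",
              name, length(m$files), m$nominal_temp_c, manifest))
}
cat("done; run analysis/02_features.R next\n")
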