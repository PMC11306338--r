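#!/usr/bin/env Rscript
# Screen every simulated run and extract the per-run feature set (final
# O.D., t10, t50, exponent b). Writes results/features.csv and a rejection
# log results/rejections.csv, and prints what was discarded and why.

library(turbikin)

sim_dir <- "scratch/sim"
dir.create("results", showWarnings = FALSE)

manifests <- list.files(sim_dir, pattern = "_manifest\\.json$",
                        full.names = TRUE)
stopifnot(length(manifests) > 0)

all_feats <- list(); all_rej <- list()
for (mp in manifests) {
  m <- read_manifest(mp)
  cf <- cohort_features(read_cohort(m, dir = sim_dir))
  cat(sprintf("%-11s: %2d accepted, %d rejected\n", m$condition,
              nrow(cf$features), nrow(cf$rejections)))
  all_feats[[m$condition]] <- cf$features
  if (nrow(cf$rejections)) {
    all_rej[[m$condition]] <- cbind(cf$rejections, condition = m$condition)
  }
}

features <- do.call(rbind, all_feats)
write.csv(features, "results/features.csv", row.names = FALSE)
rejections <- if (length(all_rej)) do.call(rbind, all_rej) else
  data.frame(run_id = character(), reason = character(),
             condition = character())
write.csv(rejections, "results/rejections.csv", row.names = FALSE)

cat(sprintf("\n%d runs featurized -> results/features.csv\n", nrow(features)))
cat(sprintf("%d runs rejected    -> results/rejections.csv\n",
            nrow(rejections)))
if (nrow(rejections)) print(table(rejections$reason))
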