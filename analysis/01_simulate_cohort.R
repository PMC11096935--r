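#!/usr/bin/env Rscript

# Simulate the study cohort: 15 recordings, each with one ICP plateau
# wave, at the study's physiological set-points (ICP 19.4 -> 42.7 mmHg,
# CBFV 44.2 -> 32.9 cm/s, ABP ~94 mmHg), with per-recording jitter.
# Writes the recordings (CSV), their ground-truth annotations and the
# shared plan to results/data/.

suppressMessages(library(pulsedi))

seed <- 1L
out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

plan <- episode_plan(seed = seed)
write_plan(plan, file.path(out_dir, "plan_template.yaml"))

cohort <- generate_cohort(15, plan, seed = seed)
for (i in seq_along(cohort)) {
  write_recording(cohort[[i]]$recording,
                  file.path(out_dir, sprintf("recording_%02d.csv", i)),
                  overwrite = TRUE)
  write_ground_truth(cohort[[i]]$ground_truth,
                     file.path(out_dir, sprintf("ground_truth_%02d.csv", i)))
}

cat(sprintf("simulated %d recordings of %.0f s at 50 Hz into %s\n",
            length(cohort), plan$total_duration, out_dir))
cat(sprintf("ICP set-points: baseline %.1f mmHg, plateau %.1f mmHg; pulse roundness %.2f -> %.2f\n",
            plan$baseline_icp_mean, plan$plateau_icp_mean,
            plan$baseline_roundness, plan$plateau_roundness))
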