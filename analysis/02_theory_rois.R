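#!/usr/bin/env Rscript
# Step 2: compute the four theory-driven composite ROIs per subject and
# summarize group-level SUVR distributions per tracer; verify the simulated
# cohorts against the calibration targets.

suppressMessages(library(tauroi))

rois <- builtin_rois(default_atlas())
cat("Theory-driven composite ROIs (volume-weighted):\n")
for (roi in rois) {
  cat(sprintf("  %-17s %2d regions\n", roi$name, length(roi$members)))
}

dir.create("results", showWarnings = FALSE)
rows <- list()
for (tr in tracer_presets()) {
  cohort <- load_cohort(file.path("results/cohorts", paste0(tolower(tr), ".csv")))
  rt <- roi_table(cohort, rois)
  tg <- calibration_targets(tr)
  for (grp in c("CU", "nonAD", "AD")) {
    for (nm in names(rois)) {
      v <- rt[[nm]][rt$diagnosis == grp]
      rows[[length(rows) + 1L]] <- data.frame(
        tracer = tr, group = grp, roi = nm, n = length(v),
        mean_suvr = mean(v), sd_suvr = sd(v), target_mean = tg[grp, nm])
    }
  }
}
summary <- do.call(rbind, rows)
summary$abs_dev <- abs(summary$mean_suvr - summary$target_mean)
write.csv(summary, "results/composite_summary.csv", row.names = FALSE)

cat("\nGroup-level composite SUVR, simulated vs calibration target:\n")
print(cbind(summary[c("tracer", "group", "roi", "n")],
            round(summary[c("mean_suvr", "sd_suvr", "target_mean", "abs_dev")], 3)),
      row.names = FALSE)
cat(sprintf("\nLargest |simulated - target| group mean: %.3f SUVR\n",
            max(summary$abs_dev)))
cat("(At the published group sizes this includes sampling noise; the\n")
cat(" calibration itself is verified at n = 5000 per group, +-0.05 SUVR,\n")
cat(" in the package's test suite.)\n")
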