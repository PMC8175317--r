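#!/usr/bin/env Rscript
# Step 3: derive tracer- and contrast-specific data-driven ROIs: 10-fold
# cross-validated extra-trees feature importance, hierarchical clustering of
# regions (1 - Pearson, average linkage), and iterative extraction of the
# top-ranked representative from each cluster.

suppressMessages(library(tauroi))

seed <- 20210527
dir.create("results", showWarnings = FALSE)
selections <- list()

for (tr in tracer_presets()) {
  cohort <- load_cohort(file.path("results/cohorts", paste0(tolower(tr), ".csv")))
  X <- suvr_matrix(cohort)
  for (ct in c("AD_vs_CU", "AD_vs_nonAD")) {
    neg_dx <- if (ct == "AD_vs_CU") "CU" else "nonAD"
    sub <- cohort$diagnosis %in% c(neg_dx, "AD")
    y <- cohort$diagnosis[sub] == "AD"
    dd <- derive_data_driven_roi(X[sub, ], y, K_max = 8, n_folds = 10,
                                 n_trees = 500, seed = seed)
    sel <- dd$selection
    cat(sprintf("%-13s %-11s chosen k = %d, CV AUC = %.3f\n  regions: %s\n",
                tr, ct, sel$chosen_k, sel$trace$score[sel$chosen_k],
                paste(sel$selected, collapse = ", ")))
    selections[[paste(tr, ct, sep = ".")]] <- list(
      tracer = tr, contrast = ct, chosen_k = sel$chosen_k,
      cv_auc = sel$trace$score[sel$chosen_k], selected = sel$selected,
      accuracy_vs_k = data.frame(k = sel$trace$k, cv_auc = sel$trace$score,
                                 se = sel$trace$score_se))
  }
}
jsonlite::write_json(selections, "results/data_driven_selections.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("\nwrote results/data_driven_selections.json\n")
cat("Note: selections on synthetic cohorts are dominated by the strongest\n")
cat("stage I-IV temporal-limbic regions, mirroring the temporal-lobe focus\n")
cat("of data-driven ROIs reported for real cohorts.\n")
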