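contrast_groups <- function(contrast) {
  switch(contrast,
    AD_vs_CU = list(neg = "CU", pos = "AD"),
    AD_vs_nonAD = list(neg = "nonAD", pos = "AD"),
    stop("unknown contrast '", contrast, "'")
  )
}

#' Remove predefined subject subsets from a cohort
#'
#' Implements the sensitivity-analysis exclusions:
#' * `excl_pd_no_dementia` - removes Parkinson's disease patients without
#'   dementia (subtype `"PD"`; `"PDD"` is kept);
#' * `excl_abeta_pos_pd_dlb` - removes amyloid-positive PD, PDD and DLB cases.
#'
#' @param cohort Cohort data.frame with `subtype` and `abeta_status` columns.
#' @param filter_name One of the filter names above.
#' @return The filtered cohort; the number of removed rows is reported via
#'   `message()` and attached as attribute `"removed"`.
#' @export
apply_subset_filter <- function(cohort, filter_name) {
  if (!all(c("subtype", "abeta_status") %in% names(cohort))) {
    stop("cohort must have populated 'subtype' and 'abeta_status' columns")
  }
  drop <- switch(filter_name,
    excl_pd_no_dementia = cohort$subtype == "PD",
    excl_abeta_pos_pd_dlb = cohort$subtype %in% c("PD", "PDD", "DLB") &
      cohort$abeta_status == "pos",
    stop("unknown filter name '", filter_name, "'")
  )
  message("filter ", filter_name, ": removed ", sum(drop), " of ",
          nrow(cohort), " rows")
  out <- cohort[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- sum(drop)
  out
}

#' Cross-tracer common cut-off
#'
#' Arithmetic mean of per-tracer cut-points for one ROI, rounded for
#' reporting; applied e.g. to the three temporal meta-ROI AD-vs-non-AD
#' cut-points to summarize whether a common tau-positivity threshold exists.
#'
#' @param cutpoints Numeric vector of per-tracer cut-points (SUVR).
#' @param digits Rounding for the reported value (default 2, SUVR printed to
#'   two decimals).
#' @return The rounded mean cut-point.
#' @export
#' @examples
#' summarize_common_cutoff(c(1.36, 1.34, 1.34))  # 1.35
summarize_common_cutoff <- function(cutpoints, digits = 2) {
  if (!length(cutpoints) || any(!is.finite(cutpoints))) {
    stop("cutpoints must be finite and non-empty")
  }
  round(mean(cutpoints), digits)
}

roi_stats_row <- function(neg_auc, pos_auc, neg_cut, pos_cut, B, seed) {
  a <- delong_ci(neg_auc, pos_auc)
  cc <- bootstrap_cutpoint_ci(neg_cut, pos_cut, B = B, seed = seed)
  data.frame(
    auc = a$auc, auc_lo = a$ci[1], auc_hi = a$ci[2],
    cutpoint = cc$cutpoint, cut_lo = cc$cut_ci[1], cut_hi = cc$cut_ci[2],
    sensitivity = cc$sensitivity, sens_lo = cc$sens_ci[1], sens_hi = cc$sens_ci[2],
    specificity = cc$specificity, spec_lo = cc$spec_ci[1], spec_hi = cc$spec_ci[2],
    youden_j = cc$youden_j
  )
}

#' Run the full cross-tracer ROI analysis
#'
#' For every tracer cohort and contrast: computes AUC (DeLong CI), Youden
#' cut-point and sensitivity/specificity (stratified bootstrap CIs) for each
#' theory-driven composite ROI; derives the tracer/contrast-specific
#' data-driven ROI and evaluates it the same way; runs the paired DeLong test
#' between the best-performing theory-driven ROI (highest point AUC) and the
#' data-driven ROI; and summarizes per-ROI cut-points across tracers
#' (arithmetic mean). Cut-points are derived either on the stated contrast
#' (`cutpoint_scope = "per_contrast"`, default; for AD vs CU the negative
#' group is restricted to amyloid-negative CU) or always on AD vs
#' amyloid-negative CU (`"ad_vs_abneg_cu"`).
#'
#' @param cohorts Named list of cohort data.frames (names = tracer labels).
#' @param contrasts Character vector among `"AD_vs_CU"`, `"AD_vs_nonAD"`.
#' @param rois Named list of theory-driven [composite_roi()]s; default
#'   [builtin_rois()] on `atlas`.
#' @param atlas Region atlas (default [default_atlas()]).
#' @param subset_filter Optional filter name passed to [apply_subset_filter()]
#'   before analysis.
#' @param B Bootstrap resamples for cut-point CIs.
#' @param seed Integer master seed; all derived seeds are recorded in the
#'   output.
#' @param cutpoint_scope See above.
#' @param K_max,n_trees,n_folds Data-driven selection settings.
#' @param weighting Weighting for the builtin theory-driven ROIs.
#' @return Object of class `tau_report`: list with `table` (one row per
#'   tracer x contrast x ROI), `delong` (best theory vs data-driven, per
#'   tracer x contrast), `cutoff_summary` (per ROI x contrast cross-tracer
#'   mean cut-point), `selections` (data-driven traces), and `config`.
#' @export
run_full_analysis <- function(cohorts,
                              contrasts = c("AD_vs_CU", "AD_vs_nonAD"),
                              rois = NULL, atlas = default_atlas(),
                              subset_filter = NULL, B = 2000, seed = 1,
                              cutpoint_scope = c("per_contrast", "ad_vs_abneg_cu"),
                              K_max = 8, n_trees = 500, n_folds = 10,
                              weighting = "volume_weighted") {
  cutpoint_scope <- match.arg(cutpoint_scope)
  if (is.null(names(cohorts)) || any(!nzchar(names(cohorts)))) {
    stop("cohorts must be a named list (names = tracer labels)")
  }
  if (is.null(rois)) rois <- builtin_rois(atlas, weighting = weighting)
  rows <- list(); dl_rows <- list(); selections <- list()

  for (tr in names(cohorts)) {
    cohort <- cohorts[[tr]]
    validate_cohort(cohort)
    if (!is.null(subset_filter)) cohort <- apply_subset_filter(cohort, subset_filter)
    rt <- roi_table(cohort, rois)
    X <- suvr_matrix(cohort)

    for (ct in contrasts) {
      gr <- contrast_groups(ct)
      is_pos <- cohort$diagnosis == gr$pos
      is_neg <- cohort$diagnosis == gr$neg
      if (!any(is_pos) || !any(is_neg)) {
        warning("contrast ", ct, " for tracer ", tr,
                " has an empty group; skipped")
        next
      }
      # negatives used for cut-point derivation
      cut_neg <- if (cutpoint_scope == "ad_vs_abneg_cu" || ct == "AD_vs_CU") {
        cohort$diagnosis == "CU" & cohort$abeta_status == "neg"
      } else is_neg
      seed_tc <- seed + 1000L * match(tr, names(cohorts)) + 100L * match(ct, contrasts)

      theory_scores <- list()
      for (nm in names(rois)) {
        sc <- rt[[nm]]
        theory_scores[[nm]] <- sc
        st <- roi_stats_row(sc[is_neg], sc[is_pos], sc[cut_neg], sc[is_pos],
                            B = B, seed = seed_tc + match(nm, names(rois)))
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(tracer = tr, contrast = ct, roi = nm, kind = "theory",
                     members = paste(rois[[nm]]$members, collapse = ";"),
                     stringsAsFactors = FALSE), st)
      }

      dd <- derive_data_driven_roi(X[is_pos | is_neg, , drop = FALSE],
                                   is_pos[is_pos | is_neg],
                                   K_max = K_max, n_folds = n_folds,
                                   n_trees = n_trees, seed = seed_tc,
                                   name = "data_driven")
      dsc <- rowMeans(X[, dd$roi$members, drop = FALSE])
      st <- roi_stats_row(dsc[is_neg], dsc[is_pos], dsc[cut_neg], dsc[is_pos],
                          B = B, seed = seed_tc + 99L)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(tracer = tr, contrast = ct, roi = "data_driven",
                   kind = "data_driven",
                   members = paste(dd$roi$members, collapse = ";"),
                   stringsAsFactors = FALSE), st)
      selections[[paste(tr, ct, sep = ".")]] <- dd$selection

      theory_aucs <- vapply(names(rois), function(nm) {
        sc <- theory_scores[[nm]]
        auc_mw(sc[is_neg], sc[is_pos])
      }, numeric(1))
      best <- names(which.max(theory_aucs))
      sub <- is_pos | is_neg
      dl <- delong_paired(theory_scores[[best]][sub], dsc[sub], is_pos[sub])
      dl_rows[[length(dl_rows) + 1L]] <- data.frame(
        tracer = tr, contrast = ct, best_theory_roi = best,
        auc_theory = dl$auc_a, auc_data_driven = dl$auc_b,
        delta = dl$delta, z = dl$z, p = dl$p, stringsAsFactors = FALSE)
    }
  }

  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  delong <- do.call(rbind, dl_rows)
  rownames(delong) <- NULL
  cutoff_summary <- do.call(rbind, lapply(split(
    table, list(table$roi, table$contrast), drop = TRUE), function(d) {
      data.frame(roi = d$roi[1], contrast = d$contrast[1],
                 n_tracers = nrow(d), mean_cutpoint = mean(d$cutpoint),
                 stringsAsFactors = FALSE)
    }))
  rownames(cutoff_summary) <- NULL
  structure(list(table = table, delong = delong, cutoff_summary = cutoff_summary,
                 selections = selections,
                 config = list(tracers = names(cohorts), contrasts = contrasts,
                               B = B, seed = seed, cutpoint_scope = cutpoint_scope,
                               subset_filter = subset_filter, K_max = K_max,
                               n_trees = n_trees, n_folds = n_folds)),
            class = "tau_report")
}

#' @export
print.tau_report <- function(x, ...) {
  cat("Cross-tracer tau-PET ROI diagnostic report\n")
  cat("tracers:", paste(x$config$tracers, collapse = ", "),
      "| contrasts:", paste(x$config$contrasts, collapse = ", "), "\n\n")
  d <- x$table
  d$auc <- sprintf("%.3f (%.3f-%.3f)", d$auc, d$auc_lo, d$auc_hi)
  d$cutpoint <- sprintf("%.2f (%.2f, %.2f)", d$cutpoint, d$cut_lo, d$cut_hi)
  d$sensitivity <- sprintf("%.1f", d$sensitivity)
  d$specificity <- sprintf("%.1f", d$specificity)
  print(d[c("tracer", "contrast", "roi", "auc", "cutpoint",
            "sensitivity", "specificity")], row.names = FALSE)
  cat("\nCross-tracer mean cut-points:\n")
  cs <- x$cutoff_summary
  cs$mean_cutpoint <- sprintf("%.2f", cs$mean_cutpoint)
  print(cs, row.names = FALSE)
  invisible(x)
}

#' Serialize a tau_report to disk
#'
#' Writes `report.json` (full report), `diagnostic_performance.csv` (the
#' per-ROI table) and `selection_traces.json` under `dir`. Output is
#' deterministic: identical reports produce byte-identical files.
#'
#' @param report A `tau_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "tau_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(table = report$table, delong = report$delong,
         cutoff_summary = report$cutoff_summary, config = report$config),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(report$table, file.path(dir, "diagnostic_performance.csv"),
                   row.names = FALSE)
  traces <- lapply(report$selections, function(s) {
    list(chosen_k = s$chosen_k, selected = s$selected,
         trace = data.frame(k = s$trace$k, score = s$trace$score,
                            score_se = s$trace$score_se,
                            representatives = vapply(
                              s$trace$representatives, paste,
                              character(1), collapse = ";")))
  })
  jsonlite::write_json(traces, file.path(dir, "selection_traces.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
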