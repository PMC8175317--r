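# Calibrated tracer presets.
#
# Parameter values were fit once (least squares on the analytic group moments
# of the latent sigmoid model) so that the 4 composite-ROI means/SDs of the
# generated CU / non-AD / AD groups match the published cohort
# characteristics of each tracer; the latent scale is normalized to
# CU Abeta- ~ N(0, 1).  See the methods vignette for the model and the
# calibration targets.
preset_params <- function() {
  list(
    flortaucipir = list(
      offset = 0.6018, gain = 1.2468, noise_sd = 0.1928,
      th1 = 0.4556, th3 = 4.4406, th5 = 6.637, tau = 1.1051,
      sh3 = 0.5485, sh5 = 0.4936,
      cu = list(mean = 0, sd = 1, mean_pos = 0.3006, sd_pos = 0.3),
      nonad = list(mean = 0.2847, sd = 0.3, mean_pos = 1.7927, sd_pos = 2.5),
      ad = list(mean = 5.2642, sd = 2.9137)
    ),
    RO948 = list(
      offset = 0.5618, gain = 1.5291, noise_sd = 0.2384,
      th1 = 0.8263, th3 = 1.4771, th5 = 3.9952, tau = 0.6554,
      sh3 = 0.207, sh5 = 0.5173,
      cu = list(mean = 0, sd = 1, mean_pos = 1.5007, sd_pos = 2.5),
      nonad = list(mean = 0.4396, sd = 1.1644, mean_pos = 0.8623, sd_pos = 0.6457),
      ad = list(mean = 3.2516, sd = 0.8283)
    ),
    MK6240 = list(
      offset = -0.1262, gain = 2.7219, noise_sd = 0.1556,
      th1 = 0.8069, th3 = 3.7302, th5 = 5.8122, tau = 1.5,
      sh3 = 0.7388, sh5 = 1.0656,
      cu = list(mean = 0, sd = 1, mean_pos = 0.3, sd_pos = 0.3),
      nonad = list(mean = -0.1113, sd = 0.4188, mean_pos = 0.673, sd_pos = 1.161),
      ad = list(mean = 8.1439, sd = 4)
    )
  )
}

# Group composition per tracer: published group sizes, clinical subtypes and
# amyloid-positive counts.  PD/PDD pooled counts are split into PD (no
# dementia) and PDD; amyloid-positive non-AD counts are allocated by subtype
# so that the PD/PDD/DLB amyloid-positive subset counts match the published
# supplementary exclusions (26 flortaucipir, 31 RO948).
preset_groups <- function() {
  list(
    flortaucipir = list(
      cu = list(n = 638, pos = 226),
      ad = list(n = 159),
      nonad = data.frame(
        subtype = c("CBS", "DLB", "MSA", "PD", "PDD", "PNFA", "SD", "bvFTD", "VaD", "PSP"),
        n = c(15, 18, 3, 40, 25, 14, 6, 26, 4, 27),
        pos = c(1, 6, 0, 12, 8, 0, 0, 1, 0, 1),
        stringsAsFactors = FALSE
      )
    ),
    RO948 = list(
      cu = list(n = 208, pos = 90),
      ad = list(n = 142),
      nonad = data.frame(
        subtype = c("CBS", "DLB", "FTD", "MSA", "PD", "PDD", "PNFA", "PSP"),
        n = c(3, 30, 23, 13, 30, 17, 3, 24),
        pos = c(2, 12, 7, 3, 12, 7, 1, 8),
        stringsAsFactors = FALSE
      )
    ),
    MK6240 = list(
      cu = list(n = 218, pos = 47),
      ad = list(n = 50),
      nonad = data.frame(
        subtype = c("CBS", "FTD", "PPA", "PSP"),
        n = c(1, 14, 1, 3),
        pos = c(0, 0, 0, 0),
        stringsAsFactors = FALSE
      )
    )
  )
}

#' Names of the calibrated tracer presets
#'
#' @return Character vector: `"flortaucipir"`, `"RO948"`, `"MK6240"`.
#' @export
tracer_presets <- function() names(preset_params())

match_preset <- function(tracer) {
  nm <- tracer_presets()
  i <- match(tolower(tracer), tolower(nm))
  if (is.na(i)) stop("unknown tracer preset '", tracer, "'; available: ",
                     paste(nm, collapse = ", "))
  nm[i]
}

preset_tracer_model <- function(tracer) {
  tracer <- match_preset(tracer)
  p <- preset_params()[[tracer]]
  tracer_model(tracer, offset = p$offset, gain = p$gain, noise_sd = p$noise_sd,
               offtarget_shift = c(III_IV = p$sh3, V_VI = p$sh5,
                                   off_target = p$sh5))
}

preset_onsets <- function(p) {
  c(I_II = p$th1, III_IV = p$th3, V_VI = p$th5, off_target = p$th5 + 2)
}

#' Calibrated cohort configuration for one tracer
#'
#' Builds the full [cohort_config()] emulating the published cohort of the
#' given tracer: group sizes, clinical subtypes, per-group amyloid-positive
#' fractions, and latent-model parameters calibrated to the published
#' composite-ROI means/SDs.
#'
#' @param tracer One of [tracer_presets()] (case-insensitive).
#' @param seed Integer RNG seed.
#' @return A [cohort_config()].
#' @export
#' @examples
#' cfg <- preset_cohort_config("flortaucipir", seed = 1)
#' sum(vapply(cfg$groups, function(g) g$n, numeric(1)))  # 975
preset_cohort_config <- function(tracer, seed = 1L) {
  tracer <- match_preset(tracer)
  p <- preset_params()[[tracer]]
  gr <- preset_groups()[[tracer]]
  groups <- list(
    group_spec("CU", n = gr$cu$n, abeta_pos_fraction = gr$cu$pos / gr$cu$n,
               latent_mean = p$cu$mean, latent_sd = p$cu$sd,
               latent_mean_pos = p$cu$mean_pos, latent_sd_pos = p$cu$sd_pos)
  )
  for (i in seq_len(nrow(gr$nonad))) {
    s <- gr$nonad[i, ]
    groups <- c(groups, list(
      group_spec("nonAD", n = s$n, abeta_pos_fraction = s$pos / s$n,
                 latent_mean = p$nonad$mean, latent_sd = p$nonad$sd,
                 latent_mean_pos = p$nonad$mean_pos, latent_sd_pos = p$nonad$sd_pos,
                 subtype = s$subtype)
    ))
  }
  groups <- c(groups, list(
    group_spec("AD", n = gr$ad$n, abeta_pos_fraction = 1,
               latent_mean = p$ad$mean, latent_sd = p$ad$sd)
  ))
  cohort_config(preset_tracer_model(tracer), default_atlas(), groups,
                stage_onsets = preset_onsets(p), stage_slope = p$tau, seed = seed)
}

#' Large equal-group configuration for calibration checks
#'
#' Same latent model and amyloid fractions as [preset_cohort_config()] but
#' with `n` subjects in each of the three diagnostic groups (non-AD collapsed
#' to a single group with the tracer's overall amyloid-positive fraction).
#' Used to verify by Monte Carlo that generated group means reproduce the
#' calibration targets.
#'
#' @inheritParams preset_cohort_config
#' @param n Subjects per diagnostic group.
#' @return A [cohort_config()].
#' @export
preset_calibration_config <- function(tracer, n = 5000, seed = 1L) {
  tracer <- match_preset(tracer)
  p <- preset_params()[[tracer]]
  gr <- preset_groups()[[tracer]]
  f_nonad <- sum(gr$nonad$pos) / sum(gr$nonad$n)
  groups <- list(
    group_spec("CU", n = n, abeta_pos_fraction = gr$cu$pos / gr$cu$n,
               latent_mean = p$cu$mean, latent_sd = p$cu$sd,
               latent_mean_pos = p$cu$mean_pos, latent_sd_pos = p$cu$sd_pos),
    group_spec("nonAD", n = n, abeta_pos_fraction = f_nonad,
               latent_mean = p$nonad$mean, latent_sd = p$nonad$sd,
               latent_mean_pos = p$nonad$mean_pos, latent_sd_pos = p$nonad$sd_pos),
    group_spec("AD", n = n, abeta_pos_fraction = 1,
               latent_mean = p$ad$mean, latent_sd = p$ad$sd)
  )
  cohort_config(preset_tracer_model(tracer), default_atlas(), groups,
                stage_onsets = preset_onsets(p), stage_slope = p$tau, seed = seed)
}

#' Published composite-ROI calibration targets
#'
#' The group-level composite SUVR means the presets are calibrated to
#' (columns: the four theory-driven composites; rows: CU, nonAD, AD).
#'
#' @param tracer One of [tracer_presets()].
#' @return Numeric matrix 3 x 4.
#' @export
calibration_targets <- function(tracer) {
  tracer <- match_preset(tracer)
  tg <- list(
    flortaucipir = rbind(CU = c(1.14, 1.19, 1.18, 1.08),
                         nonAD = c(1.22, 1.22, 1.20, 1.13),
                         AD = c(1.74, 1.88, 1.88, 1.53)),
    RO948 = rbind(CU = c(1.23, 1.23, 1.22, 1.23),
                  nonAD = c(1.22, 1.22, 1.22, 1.08),
                  AD = c(2.00, 2.15, 2.13, 1.51)),
    MK6240 = rbind(CU = c(0.93, 0.87, 0.86, 1.02),
                   nonAD = c(0.84, 0.81, 0.82, 0.98),
                   AD = c(2.42, 2.80, 2.84, 2.81))
  )[[tracer]]
  colnames(tg) <- c("entorhinal", "early_tau", "temporal_meta", "neocortical_meta")
  tg
}
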