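# Shared fixtures: a small atlas and cohort configurations that exercise the
# full latent model at a size where tests run in milliseconds.

tiny_atlas <- function() {
  data.frame(
    label = c("lh_entorhinal", "rh_entorhinal",
              "lh_amygdala", "rh_amygdala",
              "lh_inferiortemporal", "rh_inferiortemporal",
              "lh_middletemporal", "rh_middletemporal",
              "lh_fusiform", "rh_fusiform",
              "lh_parahippocampal", "rh_parahippocampal",
              "lh_superiorfrontal", "rh_superiorfrontal",
              "lh_precuneus", "rh_precuneus",
              "lh_insula", "rh_insula"),
    stage_class = rep(c("I_II", "III_IV", "III_IV", "III_IV", "III_IV",
                        "III_IV", "V_VI", "V_VI", "off_target"), each = 2),
    volume = rep(c(2000, 1800, 11000, 12000, 9000, 2500, 22000, 10000, 6500),
                 each = 2),
    stringsAsFactors = FALSE
  )
}

tiny_tracer <- function(noise_sd = 0.1, offset = 1, gain = 1, shifts = numeric()) {
  tracer_model("testtracer", offset = offset, gain = gain, noise_sd = noise_sd,
               offtarget_shift = shifts)
}

tiny_config <- function(n_cu = 30, n_nonad = 20, n_ad = 25, seed = 1,
                        noise_sd = 0.1, atlas = tiny_atlas()) {
  cohort_config(
    tracer = tiny_tracer(noise_sd = noise_sd),
    atlas = atlas,
    groups = list(
      group_spec("CU", n = n_cu, abeta_pos_fraction = 0.3,
                 latent_mean = 0, latent_sd = 1,
                 latent_mean_pos = 1, latent_sd_pos = 1.2),
      group_spec("nonAD", n = n_nonad, abeta_pos_fraction = 0.2,
                 latent_mean = 0.2, latent_sd = 1.1, subtype = "PSP"),
      group_spec("AD", n = n_ad, abeta_pos_fraction = 1,
                 latent_mean = 3.5, latent_sd = 1.2)
    ),
    stage_onsets = c(I_II = 1.5, III_IV = 2.5, V_VI = 3.5, off_target = 5.5),
    stage_slope = 0.8, seed = seed
  )
}

# Brute-force oracles -------------------------------------------------------

# all-pairs AUC, ties 1/2
brute_auc <- function(neg, pos) {
  s <- 0
  for (p in pos) s <- s + sum(p > neg) + 0.5 * sum(p == neg)
  s / (length(neg) * length(pos))
}

# exhaustive Youden maximum over every pooled-value threshold (and midpoints)
brute_youden_max <- function(neg, pos) {
  cand <- sort(unique(c(neg, pos, (head(sort(unique(c(neg, pos))), -1) +
                                     tail(sort(unique(c(neg, pos))), -1)) / 2,
                        -Inf, Inf)))
  best <- -Inf
  for (t in cand) {
    j <- mean(pos > t) + mean(neg <= t) - 1
    if (j > best) best <- j
  }
  best
}
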