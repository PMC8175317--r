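test_that("generated cohorts have exactly the configured group sizes", {
  cfg <- tiny_config(n_cu = 30, n_nonad = 20, n_ad = 25)
  cohort <- generate_cohort(cfg)
  expect_equal(nrow(cohort), 75)
  expect_equal(as.vector(table(factor(cohort$diagnosis,
                                      c("CU", "nonAD", "AD")))), c(30, 20, 25))
  expect_equal(ncol(suvr_matrix(cohort)), nrow(tiny_atlas()))
  expect_false(anyDuplicated(cohort$subject_id) > 0)
})

test_that("the same seed reproduces the cohort exactly, different seeds do not", {
  a <- generate_cohort(tiny_config(seed = 11))
  b <- generate_cohort(tiny_config(seed = 11))
  cc <- generate_cohort(tiny_config(seed = 12))
  expect_identical(a, b)
  expect_false(identical(a, cc))
})

test_that("with saturating latent burden and no noise, SUVR -> offset + gain + shift", {
  atlas <- tiny_atlas()
  cfg <- cohort_config(
    tracer = tiny_tracer(noise_sd = 1e-9, offset = 1.1, gain = 0.9,
                         shifts = c(V_VI = 0.2)),
    atlas = atlas,
    groups = list(group_spec("AD", n = 1, abeta_pos_fraction = 1,
                             latent_mean = 60, latent_sd = 1e-9)),
    stage_onsets = c(I_II = 1, III_IV = 2, V_VI = 3, off_target = 5),
    stage_slope = 0.8, seed = 1
  )
  cohort <- generate_cohort(cfg)
  suvr <- suvr_matrix(cohort)[1, ]
  exp_val <- 1.1 + 0.9 + ifelse(atlas$stage_class == "V_VI", 0.2, 0)
  expect_equal(unname(suvr), exp_val, tolerance = 1e-6)
})

test_that("regional SUVR is nondecreasing in latent severity (noise disabled)", {
  zs <- seq(-4, 8, by = 0.5)
  groups <- lapply(zs, function(z) {
    group_spec("CU", n = 1, abeta_pos_fraction = 0,
               latent_mean = z, latent_sd = 1e-12)
  })
  cfg <- cohort_config(tiny_tracer(noise_sd = 1e-12), tiny_atlas(), groups,
                       stage_onsets = c(I_II = 1.5, III_IV = 2.5, V_VI = 3.5,
                                        off_target = 5.5),
                       stage_slope = 0.8, seed = 1)
  suvr <- suvr_matrix(generate_cohort(cfg))
  for (j in seq_len(ncol(suvr))) {
    expect_true(all(diff(suvr[, j]) >= -1e-9), label = colnames(suvr)[j])
  }
})

test_that("earlier stage classes carry at least as much burden as later ones", {
  # equal shifts (all zero): I_II >= III_IV >= V_VI for any z
  zs <- seq(-4, 8, by = 0.5)
  groups <- lapply(zs, function(z) {
    group_spec("CU", n = 1, abeta_pos_fraction = 0,
               latent_mean = z, latent_sd = 1e-12)
  })
  atlas <- tiny_atlas()
  cfg <- cohort_config(tiny_tracer(noise_sd = 1e-12), atlas, groups,
                       stage_onsets = c(I_II = 1.5, III_IV = 2.5, V_VI = 3.5,
                                        off_target = 5.5),
                       stage_slope = 0.8, seed = 1)
  suvr <- suvr_matrix(generate_cohort(cfg))
  early <- rowMeans(suvr[, atlas$stage_class == "I_II", drop = FALSE])
  late <- rowMeans(suvr[, atlas$stage_class == "V_VI", drop = FALSE])
  expect_true(all(early - late >= -1e-9))
})

test_that("amyloid-positive fractions are honoured within a group", {
  cfg <- tiny_config(n_cu = 400, n_nonad = 200, n_ad = 50, seed = 3)
  cohort <- generate_cohort(cfg)
  for (dg in c("CU", "nonAD", "AD")) {
    g <- cohort[cohort$diagnosis == dg, ]
    f_target <- c(CU = 0.3, nonAD = 0.2, AD = 1)[[dg]]
    f_obs <- mean(g$abeta_status == "pos")
    se <- sqrt(f_target * (1 - f_target) / nrow(g))
    expect_lte(abs(f_obs - f_target), max(3 * se, 1 / nrow(g)))
  }
})

test_that("invalid configurations are rejected with a message naming the field", {
  expect_error(group_spec("AD", n = 0, abeta_pos_fraction = 1,
                          latent_mean = 1, latent_sd = 1), "'n'")
  expect_error(group_spec("AD", n = 10, abeta_pos_fraction = 2,
                          latent_mean = 1, latent_sd = 1), "abeta_pos_fraction")
  expect_error(group_spec("AD", n = 10, abeta_pos_fraction = 1,
                          latent_mean = Inf, latent_sd = 1), "latent_mean")
  expect_error(tracer_model("t", offset = 1, gain = -1, noise_sd = 0.1), "gain")
  expect_error(tracer_model("t", offset = 1, gain = 1, noise_sd = 0.1,
                            offtarget_shift = c(bogus = 1)), "stage_class")
  bad_atlas <- tiny_atlas()
  bad_atlas$stage_class[1] <- "stage_zero"
  expect_error(
    cohort_config(tiny_tracer(), bad_atlas, list(group_spec(
      "AD", n = 5, abeta_pos_fraction = 1, latent_mean = 0, latent_sd = 1)),
      stage_onsets = c(I_II = 1, III_IV = 2, V_VI = 3, off_target = 5),
      stage_slope = 0.5),
    "stage_class")
  expect_error(
    cohort_config(tiny_tracer(), tiny_atlas(), list(group_spec(
      "AD", n = 5, abeta_pos_fraction = 1, latent_mean = 0, latent_sd = 1)),
      stage_onsets = c(I_II = 3, III_IV = 2, V_VI = 1, off_target = 5),
      stage_slope = 0.5),
    "stage_onsets")
})

test_that("cohort CSV round trip is the identity and schema errors are caught", {
  cohort <- generate_cohort(tiny_config(n_cu = 5, n_nonad = 3, n_ad = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  save_cohort(cohort, path)
  back <- load_cohort(path)
  expect_equal(back, cohort, tolerance = 1e-12)

  # missing SUVR column
  broken <- cohort
  broken$suvr_lh_entorhinal <- NULL
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(broken, path2, row.names = FALSE)
  expect_error(load_cohort(path2), "suvr")

  # duplicated subject id
  dup <- cohort
  dup$subject_id[2] <- dup$subject_id[1]
  path3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(dup, path3, row.names = FALSE)
  expect_error(load_cohort(path3), "duplicated subject_id")

  # negative SUVR names row and column
  neg <- cohort
  neg$suvr_lh_fusiform[3] <- -0.2
  path4 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(neg, path4, row.names = FALSE)
  expect_error(load_cohort(path4), "suvr_lh_fusiform, row 3")

  # empty file is an error, not an empty table
  path5 <- withr::local_tempfile(fileext = ".csv")
  file.create(path5)
  expect_error(load_cohort(path5), "empty")
})
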