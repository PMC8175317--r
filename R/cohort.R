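#' Tracer model for the synthetic SUVR generator
#'
#' A tracer maps latent regional tau burden (in \[0, 1\]) to SUVR through an
#' affine transform plus additive Gaussian noise:
#' `suvr = offset + gain * burden + class_shift + eps`, `eps ~ N(0, noise_sd^2)`.
#' `gain` sets the tracer's dynamic range; per-stage-class shifts allow
#' class-level baseline differences (e.g. off-target binding).
#'
#' @param name Tracer name (string).
#' @param offset SUVR intercept.
#' @param gain SUVR per unit latent burden; must be > 0.
#' @param noise_sd Regional noise SD in SUVR units; must be > 0.
#' @param offtarget_shift Named numeric vector of per-stage-class SUVR shifts
#'   (names among `I_II`, `III_IV`, `V_VI`, `off_target`); classes not named
#'   default to 0.
#' @return A list of class `tracer_model`.
#' @export
tracer_model <- function(name, offset, gain, noise_sd, offtarget_shift = numeric()) {
  shifts <- stats::setNames(rep(0, length(STAGE_CLASSES)), STAGE_CLASSES)
  if (length(offtarget_shift)) {
    bad <- setdiff(names(offtarget_shift), STAGE_CLASSES)
    if (length(bad)) stop("tracer '", name, "': unknown stage_class in offtarget_shift: ",
                          paste(bad, collapse = ", "))
    shifts[names(offtarget_shift)] <- offtarget_shift
  }
  obj <- list(name = name, offset = offset, gain = gain,
              noise_sd = noise_sd, offtarget_shift = shifts)
  for (f in c("offset", "gain", "noise_sd")) {
    if (!is.numeric(obj[[f]]) || length(obj[[f]]) != 1L || !is.finite(obj[[f]])) {
      stop("tracer '", name, "': field '", f, "' must be a finite number")
    }
  }
  if (obj$gain <= 0) stop("tracer '", name, "': field 'gain' must be > 0")
  if (obj$noise_sd <= 0) stop("tracer '", name, "': field 'noise_sd' must be > 0")
  if (any(!is.finite(shifts))) stop("tracer '", name, "': field 'offtarget_shift' must be finite")
  structure(obj, class = "tracer_model")
}

#' Diagnostic group specification
#'
#' Describes one diagnostic group of the cohort: its size, its
#' amyloid-positive fraction, and the latent tau-burden distribution of each
#' amyloid stratum. Latent burden severity `z` is drawn from
#' `N(latent_mean, latent_sd^2)` for amyloid-negative subjects and from
#' `N(latent_mean_pos, latent_sd_pos^2)` for amyloid-positive subjects
#' (defaulting to the negative-stratum values when not given).
#'
#' @param diagnosis One of `"CU"`, `"AD"`, `"nonAD"`.
#' @param n Number of subjects (positive integer).
#' @param abeta_pos_fraction Proportion amyloid-positive in \[0, 1\].
#' @param latent_mean,latent_sd Latent severity distribution (Abeta-negative
#'   stratum); `latent_sd > 0`.
#' @param latent_mean_pos,latent_sd_pos Optional Abeta-positive stratum values.
#' @param subtype Free-text clinical subtype for non-AD groups (e.g. `"PSP"`,
#'   `"DLB"`, `"PD"`, `"PDD"`); empty for CU/AD.
#' @return A list of class `group_spec`.
#' @export
group_spec <- function(diagnosis, n, abeta_pos_fraction, latent_mean, latent_sd,
                       latent_mean_pos = latent_mean, latent_sd_pos = latent_sd,
                       subtype = "") {
  id <- if (nzchar(subtype)) paste0(diagnosis, "/", subtype) else diagnosis
  if (!diagnosis %in% c("CU", "AD", "nonAD")) {
    stop("group ", id, ": diagnosis must be CU, AD or nonAD")
  }
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1 || n != round(n)) {
    stop("group ", id, ": field 'n' must be a positive integer")
  }
  if (!is.finite(abeta_pos_fraction) || abeta_pos_fraction < 0 || abeta_pos_fraction > 1) {
    stop("group ", id, ": field 'abeta_pos_fraction' must be in [0, 1]")
  }
  for (f in c("latent_mean", "latent_sd", "latent_mean_pos", "latent_sd_pos")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("group ", id, ": field '", f, "' must be a finite number")
    }
  }
  if (latent_sd <= 0 || latent_sd_pos <= 0) {
    stop("group ", id, ": latent_sd must be > 0")
  }
  structure(list(diagnosis = diagnosis, subtype = subtype, n = as.integer(n),
                 abeta_pos_fraction = abeta_pos_fraction,
                 latent_mean = latent_mean, latent_sd = latent_sd,
                 latent_mean_pos = latent_mean_pos, latent_sd_pos = latent_sd_pos),
            class = "group_spec")
}

#' Cohort generator configuration
#'
#' Bundles everything [generate_cohort()] needs: the tracer model, the region
#' atlas, the diagnostic groups, the latent stage-onset parameters and the
#' random seed. Regional burden follows a logistic dose-response in latent
#' severity `z`: `burden_r = plogis((z - theta_class(r)) / stage_slope)`, so
#' regions of earlier Braak stage classes (smaller onset `theta`) accumulate
#' signal before later ones.
#'
#' @param tracer A [tracer_model()].
#' @param atlas A region atlas as returned by [default_atlas()].
#' @param groups List of [group_spec()] objects.
#' @param stage_onsets Named numeric vector of latent onsets, one per stage
#'   class present in the atlas; must satisfy
#'   `theta(I_II) <= theta(III_IV) <= theta(V_VI)`.
#' @param stage_slope Latent slope `tau > 0` of the logistic dose-response.
#' @param seed Integer RNG seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(tracer, atlas, groups, stage_onsets, stage_slope, seed = 1L) {
  cfg <- structure(list(tracer = tracer, atlas = atlas, groups = groups,
                        stage_onsets = stage_onsets, stage_slope = stage_slope,
                        seed = as.integer(seed)),
                   class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(config) {
  if (!inherits(config$tracer, "tracer_model")) stop("config$tracer must be a tracer_model")
  validate_atlas(config$atlas)
  if (!length(config$groups)) stop("config$groups must contain at least one group_spec")
  for (g in config$groups) {
    if (!inherits(g, "group_spec")) stop("config$groups must all be group_spec objects")
  }
  th <- config$stage_onsets
  used <- unique(config$atlas$stage_class)
  miss <- setdiff(used, names(th))
  if (length(miss)) stop("stage_onsets missing for stage_class: ", paste(miss, collapse = ", "))
  if (any(!is.finite(th))) stop("field 'stage_onsets' must be finite")
  ord <- c("I_II", "III_IV", "V_VI")
  have <- ord[ord %in% names(th)]
  if (length(have) > 1L && is.unsorted(th[have])) {
    stop("stage_onsets must satisfy theta(I_II) <= theta(III_IV) <= theta(V_VI)")
  }
  if (!is.finite(config$stage_slope) || config$stage_slope <= 0) {
    stop("field 'stage_slope' must be > 0")
  }
  invisible(config)
}

#' Generate a synthetic regional-SUVR cohort
#'
#' Draws one wide table of subjects under the latent tau-burden model. Per
#' subject, a latent severity `z` is drawn from its amyloid stratum's normal
#' distribution; regional burden follows the logistic stage-onset model; and
#' SUVR is the tracer's affine map of burden plus Gaussian noise, truncated
#' below at 0.05 SUVR. Amyloid status is assigned by exact counts
#' (`round(n * abeta_pos_fraction)` positives per group). Identical
#' configuration and seed yield a byte-identical table.
#'
#' @param config A [cohort_config()].
#' @return A data.frame with one row per subject: `subject_id`, `tracer`,
#'   `diagnosis`, `subtype`, `abeta_status`, then `suvr_<label>` and
#'   `vol_<label>` for every atlas label.
#' @export
#' @examples
#' cfg <- preset_cohort_config("MK6240", seed = 7)
#' cohort <- generate_cohort(cfg)
#' table(cohort$diagnosis)
generate_cohort <- function(config) {
  validate_cohort_config(config)
  set.seed(config$seed)
  atlas <- config$atlas
  tr <- config$tracer
  th_r <- config$stage_onsets[atlas$stage_class]
  shift_r <- tr$offtarget_shift[atlas$stage_class]
  R <- nrow(atlas)

  blocks <- lapply(seq_along(config$groups), function(gi) {
    g <- config$groups[[gi]]
    n_pos <- as.integer(round(g$abeta_pos_fraction * g$n))
    status <- rep(c("pos", "neg"), c(n_pos, g$n - n_pos))
    mu <- ifelse(status == "pos", g$latent_mean_pos, g$latent_mean)
    sd <- ifelse(status == "pos", g$latent_sd_pos, g$latent_sd)
    z <- stats::rnorm(g$n, mu, sd)
    burden <- stats::plogis(outer(z, th_r, "-") / config$stage_slope)
    eps <- matrix(stats::rnorm(g$n * R, 0, tr$noise_sd), g$n, R)
    suvr <- pmax(tr$offset + tr$gain * burden +
                   matrix(shift_r, g$n, R, byrow = TRUE) + eps, 0.05)
    colnames(suvr) <- paste0("suvr_", atlas$label)
    vols <- matrix(atlas$volume, g$n, R, byrow = TRUE)
    colnames(vols) <- paste0("vol_", atlas$label)
    cbind(
      data.frame(group_index = gi, diagnosis = g$diagnosis, subtype = g$subtype,
                 abeta_status = status, stringsAsFactors = FALSE),
      as.data.frame(suvr), as.data.frame(vols)
    )
  })
  out <- do.call(rbind, blocks)
  out <- cbind(
    data.frame(
      subject_id = sprintf("%s_%05d", tr$name, seq_len(nrow(out))),
      tracer = tr$name, stringsAsFactors = FALSE
    ),
    out[setdiff(names(out), "group_index")]
  )
  rownames(out) <- NULL
  out
}

cohort_meta_cols <- c("subject_id", "tracer", "diagnosis", "subtype", "abeta_status")

#' Save / load a cohort table as wide CSV
#'
#' The on-disk format is a UTF-8 CSV with header row, "." decimal, and the
#' columns `subject_id`, `tracer`, `diagnosis`, `subtype`, `abeta_status`
#' followed by `suvr_<label>` and `vol_<label>` pairs. Numeric values are
#' written with 15 significant digits so a save/load round trip reproduces the
#' table.
#'
#' @param cohort A cohort data.frame (as from [generate_cohort()]).
#' @param path File path.
#' @return `load_cohort()` returns the validated cohort data.frame;
#'   `save_cohort()` returns `path` invisibly.
#' @export
save_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  num <- vapply(cohort, is.numeric, logical(1))
  out <- cohort
  out[num] <- lapply(cohort[num], function(x) sprintf("%.15g", x))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname save_cohort
#' @export
load_cohort <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("file is empty: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("cohort file contains no subject rows: ", path)
  validate_cohort(df)
  df
}

validate_cohort <- function(cohort) {
  miss <- setdiff(cohort_meta_cols, names(cohort))
  if (length(miss)) stop("cohort is missing required column(s): ", paste(miss, collapse = ", "))
  suvr_cols <- grep("^suvr_", names(cohort), value = TRUE)
  vol_cols <- grep("^vol_", names(cohort), value = TRUE)
  if (!length(suvr_cols)) stop("cohort is missing required column(s): suvr_<label>")
  labs <- sub("^suvr_", "", suvr_cols)
  miss_vol <- setdiff(paste0("vol_", labs), vol_cols)
  if (length(miss_vol)) stop("cohort is missing required column(s): ", paste(miss_vol, collapse = ", "))
  miss_suvr <- setdiff(paste0("suvr_", sub("^vol_", "", vol_cols)), suvr_cols)
  if (length(miss_suvr)) stop("cohort is missing required column(s): ", paste(miss_suvr, collapse = ", "))
  dup <- cohort$subject_id[duplicated(cohort$subject_id)]
  if (length(dup)) stop("duplicated subject_id: ", paste(unique(dup), collapse = ", "))
  for (cc in c(suvr_cols, vol_cols)) {
    x <- cohort[[cc]]
    if (!is.numeric(x)) stop("column ", cc, " must be numeric")
    bad <- which(!is.finite(x) | x < 0)
    if (length(bad)) stop("negative or non-finite value in column ", cc, ", row ", bad[1])
  }
  invisible(cohort)
}

#' Extract the regional SUVR matrix from a cohort table
#'
#' @param cohort A cohort data.frame.
#' @return Numeric matrix, one row per subject, one column per atlas label
#'   (column names without the `suvr_` prefix).
#' @export
suvr_matrix <- function(cohort) {
  cols <- grep("^suvr_", names(cohort), value = TRUE)
  m <- as.matrix(cohort[cols])
  colnames(m) <- sub("^suvr_", "", cols)
  rownames(m) <- cohort$subject_id
  m
}
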