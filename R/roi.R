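#' Define a composite ROI
#'
#' @param name ROI name.
#' @param members Character vector of atlas labels; non-empty, no duplicates.
#' @param weighting `"volume_weighted"` (default) or `"unweighted"`.
#' @param atlas Optional atlas to validate membership against.
#' @return A list of class `composite_roi`.
#' @export
composite_roi <- function(name, members,
                          weighting = c("volume_weighted", "unweighted"),
                          atlas = NULL) {
  weighting <- match.arg(weighting)
  if (!length(members)) stop("ROI '", name, "': members must be non-empty")
  if (anyDuplicated(members)) {
    stop("ROI '", name, "': duplicated member label(s): ",
         paste(unique(members[duplicated(members)]), collapse = ", "))
  }
  if (!is.null(atlas)) {
    miss <- setdiff(members, atlas$label)
    if (length(miss)) {
      stop("ROI '", name, "': label(s) not in atlas: ", paste(miss, collapse = ", "))
    }
  }
  structure(list(name = name, members = members, weighting = weighting),
            class = "composite_roi")
}

bilateral <- function(base) c(paste0("lh_", base), paste0("rh_", base))

#' The four theory-driven composite ROIs
#'
#' Builds the standard Braak-motivated composites over a bilateral atlas:
#' * `entorhinal` - entorhinal cortex (stage I/II);
#' * `early_tau` - entorhinal, inferior temporal, fusiform, parahippocampal
#'   (regions accumulating tau earliest);
#' * `temporal_meta` - entorhinal, amygdala, inferior/middle temporal,
#'   fusiform, parahippocampal (approximating Braak I-IV);
#' * `neocortical_meta` - widespread neocortical areas (approximating Braak
#'   V/VI): all cortical labels excluding temporal meta-ROI members and
#'   limbic/off-target labels, i.e. the atlas labels of stage class `V_VI`.
#'
#' @param atlas Atlas data.frame; must contain bilateral labels for all
#'   required structures.
#' @param weighting Aggregation rule recorded in each definition.
#' @return Named list of four [composite_roi()] definitions.
#' @export
#' @examples
#' rois <- builtin_rois(default_atlas())
#' rois$temporal_meta$members
builtin_rois <- function(atlas, weighting = c("volume_weighted", "unweighted")) {
  weighting <- match.arg(weighting)
  validate_atlas(atlas)
  ento <- bilateral("entorhinal")
  early <- c(ento, bilateral(c("inferiortemporal", "fusiform", "parahippocampal")))
  temporal <- c(early, bilateral(c("amygdala", "middletemporal")))
  neo <- atlas$label[atlas$stage_class == "V_VI"]
  defs <- list(
    entorhinal = ento,
    early_tau = early,
    temporal_meta = temporal,
    neocortical_meta = neo
  )
  lapply(stats::setNames(names(defs), names(defs)), function(nm) {
    composite_roi(nm, defs[[nm]], weighting = weighting, atlas = atlas)
  })
}

#' Compute per-subject composite SUVR values
#'
#' Aggregates member-region SUVRs into a single composite value per subject:
#' the volume-weighted mean `sum(vol_r * suvr_r) / sum(vol_r)` using each
#' subject's own region volumes, or the unweighted arithmetic mean.
#'
#' @param cohort Cohort data.frame with `suvr_<label>` (and, for volume
#'   weighting, `vol_<label>`) columns.
#' @param roi A [composite_roi()].
#' @return Numeric vector, one value per cohort row.
#' @export
aggregate_roi <- function(cohort, roi) {
  scols <- paste0("suvr_", roi$members)
  miss <- setdiff(scols, names(cohort))
  if (length(miss)) stop("ROI '", roi$name, "': missing member column(s): ",
                         paste(miss, collapse = ", "))
  s <- as.matrix(cohort[scols])
  if (roi$weighting == "volume_weighted") {
    vcols <- paste0("vol_", roi$members)
    missv <- setdiff(vcols, names(cohort))
    if (length(missv)) stop("ROI '", roi$name, "': missing member column(s): ",
                            paste(missv, collapse = ", "))
    v <- as.matrix(cohort[vcols])
    tot <- rowSums(v)
    if (any(tot <= 0)) stop("ROI '", roi$name, "': zero total volume in row ",
                            which(tot <= 0)[1])
    rowSums(s * v) / tot
  } else {
    rowMeans(s)
  }
}

#' Build a composite-ROI table for a cohort
#'
#' @param cohort Cohort data.frame.
#' @param rois List of [composite_roi()] definitions (named list or list with
#'   ROI names inside).
#' @return data.frame with the cohort metadata columns plus one SUVR column
#'   per composite ROI.
#' @export
roi_table <- function(cohort, rois) {
  out <- cohort[intersect(cohort_meta_cols, names(cohort))]
  for (roi in rois) out[[roi$name]] <- aggregate_roi(cohort, roi)
  out
}

#' Read / write composite ROI definitions as YAML
#'
#' Serializes a list of [composite_roi()] definitions (name, members,
#' weighting) to a YAML file and back.
#'
#' @param rois List of [composite_roi()] objects.
#' @param path YAML file path.
#' @param atlas Optional atlas used to validate memberships on read.
#' @return `write_roi_yaml()` returns `path` invisibly; `read_roi_yaml()`
#'   returns a named list of [composite_roi()] objects.
#' @export
write_roi_yaml <- function(rois, path) {
  yaml::write_yaml(lapply(unname(rois), function(r) {
    list(name = r$name, members = as.list(r$members), weighting = r$weighting)
  }), path)
  invisible(path)
}

#' @rdname write_roi_yaml
#' @export
read_roi_yaml <- function(path, atlas = NULL) {
  raw <- yaml::read_yaml(path)
  out <- lapply(raw, function(r) {
    composite_roi(r$name, unlist(r$members), weighting = r$weighting,
                  atlas = atlas)
  })
  stats::setNames(out, vapply(out, function(r) r$name, character(1)))
}
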