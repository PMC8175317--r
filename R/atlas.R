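#' Default cortical + amygdala region atlas
#'
#' Returns the region universe used throughout the package: 31 bilateral
#' cortical labels in Desikan-Killiany style plus the amygdala (64 labels in
#' total, prefixed `lh_`/`rh_`). Each label carries a stage class that encodes
#' where the region falls in the canonical Braak ordering of neurofibrillary
#' tau spread (`I_II` transentorhinal, `III_IV` limbic/temporal, `V_VI`
#' widespread neocortical) or `off_target` for regions dominated by
#' non-specific signal (cingulate, insula, sensorimotor and pericalcarine
#' cortex), and a nominal volume in mm^3 used for volume-weighted composites.
#'
#' @return A data.frame with columns `label`, `stage_class`, `volume`.
#' @export
#' @examples
#' atlas <- default_atlas()
#' table(atlas$stage_class)
default_atlas <- function() {
  vols <- c(
    bankssts = 2500, caudalanteriorcingulate = 2000, caudalmiddlefrontal = 6500,
    cuneus = 3000, entorhinal = 2000, fusiform = 9000, inferiorparietal = 13000,
    inferiortemporal = 11000, insula = 6500, isthmuscingulate = 2500,
    lateraloccipital = 11000, lateralorbitofrontal = 7500, lingual = 6500,
    medialorbitofrontal = 5500, middletemporal = 12000, paracentral = 3500,
    parahippocampal = 2500, parsopercularis = 4500, parsorbitalis = 2500,
    parstriangularis = 4000, pericalcarine = 2000, postcentral = 10000,
    posteriorcingulate = 3000, precentral = 13000, precuneus = 10000,
    rostralanteriorcingulate = 2500, rostralmiddlefrontal = 9500,
    superiorfrontal = 22000, superiorparietal = 12000, superiortemporal = 11500,
    supramarginal = 10000, amygdala = 1800
  )
  stage <- rep("V_VI", length(vols))
  names(stage) <- names(vols)
  stage["entorhinal"] <- "I_II"
  stage[c("amygdala", "parahippocampal", "fusiform",
          "inferiortemporal", "middletemporal")] <- "III_IV"
  stage[c("caudalanteriorcingulate", "rostralanteriorcingulate",
          "posteriorcingulate", "isthmuscingulate", "insula",
          "precentral", "postcentral", "paracentral",
          "pericalcarine")] <- "off_target"
  base <- names(vols)
  data.frame(
    label = c(paste0("lh_", base), paste0("rh_", base)),
    stage_class = rep(stage, 2L),
    volume = rep(unname(vols), 2L),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

STAGE_CLASSES <- c("I_II", "III_IV", "V_VI", "off_target")

validate_atlas <- function(atlas) {
  stopifnot(is.data.frame(atlas))
  req <- c("label", "stage_class", "volume")
  miss <- setdiff(req, names(atlas))
  if (length(miss)) stop("atlas is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(atlas$label)) {
    stop("atlas labels must be unique; duplicated: ",
         paste(unique(atlas$label[duplicated(atlas$label)]), collapse = ", "))
  }
  bad <- setdiff(unique(atlas$stage_class), STAGE_CLASSES)
  if (length(bad)) stop("unknown stage_class: ", paste(bad, collapse = ", "))
  if (any(!is.finite(atlas$volume)) || any(atlas$volume <= 0)) {
    stop("atlas volumes must be positive and finite")
  }
  invisible(atlas)
}
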