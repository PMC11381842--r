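#' White-matter tract registry (JHU ICBM-DTI-81 parcellation)
#'
#' The 48 white-matter tract labels over which per-subject mean FA and MD
#' values are extracted, each tagged with its laterality parcel
#' (`midline`, `left`, `right`). Tract names use lower-case words joined by
#' underscores with an `_L`/`_R` laterality suffix for paired tracts.
#'
#' @return A tibble with columns `roi` (tract label) and `parcel`.
#' @export
#' @examples
#' jhu_tracts()
jhu_tracts <- function() {
  midline <- c(
    "middle_cerebellar_peduncle",
    "pontine_crossing_tract",
    "genu_of_corpus_callosum",
    "body_of_corpus_callosum",
    "splenium_of_corpus_callosum",
    "fornix_column_and_body"
  )
  paired <- c(
    "corticospinal_tract",
    "medial_lemniscus",
    "inferior_cerebellar_peduncle",
    "superior_cerebellar_peduncle",
    "cerebral_peduncle",
    "anterior_limb_of_internal_capsule",
    "posterior_limb_of_internal_capsule",
    "retrolenticular_part_of_internal_capsule",
    "anterior_corona_radiata",
    "superior_corona_radiata",
    "posterior_corona_radiata",
    "posterior_thalamic_radiation",
    "sagittal_stratum",
    "external_capsule",
    "cingulum_cingulate_gyrus",
    "cingulum_hippocampus",
    "fornix_cres_stria_terminalis",
    "superior_longitudinal_fasciculus",
    "superior_fronto_occipital_fasciculus",
    "uncinate_fasciculus",
    "tapetum"
  )
  tibble::tibble(
    roi = c(
      midline,
      paste0(rep(paired, each = 2), c("_R", "_L"))
    ),
    parcel = c(
      rep("midline", length(midline)),
      rep(c("right", "left"), times = length(paired))
    )
  )
}

#' Volumetric ROI registry
#'
#' The 51 regional labels used for the volumetric analysis. Input volume
#' tables carry these 51 columns plus a `total_brain_volume` column used for
#' per-subject normalization (and dropped by [normalize_volumes()]).
#'
#' @return A tibble with column `roi`.
#' @export
volumetric_rois <- function() {
  bilateral <- c(
    "thalamus", "caudate", "putamen", "pallidum", "hippocampus",
    "amygdala", "accumbens_area", "ventral_dc",
    "cerebellum_cortex", "cerebellum_white_matter",
    "cerebral_white_matter", "lateral_ventricle",
    "inferior_lateral_ventricle", "choroid_plexus",
    "frontal_lobe", "parietal_lobe", "temporal_lobe", "occipital_lobe",
    "insula", "cingulate_cortex", "entorhinal_cortex", "fusiform_gyrus",
    "precuneus", "basal_forebrain"
  )
  tibble::tibble(
    roi = c(
      paste0(rep(bilateral, each = 2), c("_R", "_L")),
      "brainstem", "corpus_callosum", "third_ventricle"
    )
  )
}

#' Column name reserved for whole-brain volume in volumetric tables
#' @keywords internal
#' @noRd
total_volume_col <- function() "total_brain_volume"

#' Registered lipid classes
#'
#' The seven lipid functional classes quantified by the panel:
#' ceramides (Cer), lysophosphatidylcholines (LPC), phosphatidylcholines (PC),
#' phosphatidylserines (PS), sphingomyelins (SM), cholesterol esters (CE) and
#' triacylglycerols (TG).
#'
#' @return Character vector of class codes.
#' @export
lipid_classes <- function() {
  c("CE", "Cer", "LPC", "PC", "PS", "SM", "TG")
}

#' Default synthetic lipid panel
#'
#' Builds a lipid annotation table of `n` lipids spread over the seven
#' classes in proportions resembling a quantitative serum lipidomics panel
#' (PC- and TG-heavy), with Metabolomics-Standards-Initiative-style
#' identification levels.
#'
#' @param n Number of lipids (default 201).
#' @return A tibble with columns `lipid`, `class`, `id_level`.
#' @export
default_lipid_panel <- function(n = 201) {
  stopifnot(n >= 7)
  props <- c(CE = 11, Cer = 25, LPC = 20, PC = 60, PS = 10, SM = 30, TG = 45)
  counts <- round(props / sum(props) * n)
  # fix rounding drift on the largest class
  counts["PC"] <- counts["PC"] + (n - sum(counts))
  cls <- rep(names(counts), counts)
  idx <- stats::ave(seq_along(cls), cls, FUN = seq_along)
  out <- tibble::tibble(
    lipid = sprintf("%s_%02d", cls, idx),
    class = cls
  ) |>
    dplyr::arrange(.data$lipid)
  out$id_level <- rep_len(c(1L, 2L, 2L, 3L), n)
  out
}

normalize_roi_name <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[^a-z0-9]+", "_", x)
  gsub("^_|_$", "", x)
}

#' Assign white-matter tracts to midline/left/right parcels
#'
#' Looks each tract up in the packaged 48-tract registry; names are matched
#' case-insensitively and with punctuation/whitespace treated as underscores,
#' so `"corticospinal tract L"` and `"corticospinal_tract_L"` are equivalent.
#'
#' @param roi_ids Character vector of tract labels.
#' @return Character vector of parcels (`"midline"`, `"left"`, `"right"`).
#' @export
#' @examples
#' parcellate_tracts(c("genu of corpus callosum", "corticospinal tract L"))
parcellate_tracts <- function(roi_ids) {
  reg <- jhu_tracts()
  key <- normalize_roi_name(roi_ids)
  hit <- match(key, normalize_roi_name(reg$roi))
  if (anyNA(hit)) {
    stop("unknown tract id(s): ", paste(roi_ids[is.na(hit)], collapse = ", "),
         call. = FALSE)
  }
  reg$parcel[hit]
}
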