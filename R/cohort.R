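#' Construct a TBI lipidomics-imaging cohort
#'
#' Bundles the subject metadata, the lipid concentration table, and the three
#' per-subject ROI metric tables (FA and MD over the 48 white-matter tracts,
#' volumes over the 51 volumetric ROIs plus total brain volume) into a single
#' validated container used by every pipeline stage.
#'
#' Lipid data are expected for patients only; healthy controls contribute
#' imaging data for harmonization and the normative baseline, but no serum
#' samples.
#'
#' @param subjects Tibble with columns `subject_id`, `group`
#'   (`"patient"`/`"control"`), `age`, `sex` (`"M"`/`"F"`), `site`, and for
#'   patients `mri_status`, `ct_status` (`"positive"`/`"negative"`/`NA`),
#'   `time_to_blood_h`, `time_to_scan_h`, `propofol`.
#' @param lipid_raw Tibble of raw concentrations (positive, ug/mL scale):
#'   `subject_id` plus one column per lipid.
#' @param lipid_info Tibble with `lipid`, `class`, `id_level` annotating every
#'   lipid column.
#' @param fa,md Tibbles of tract metrics: `subject_id` plus the 48 tract
#'   columns of [jhu_tracts()]. FA values must lie in \[0, 1\], MD must be
#'   positive.
#' @param vol Tibble of regional volumes: `subject_id`, the 51 columns of
#'   [volumetric_rois()], and `total_brain_volume`.
#' @param lipid_processed Optional tibble of log-standardized concentrations
#'   (filled by [log_standardize()]).
#' @param provenance Optional list (free text, RNG seed) recorded with the
#'   cohort.
#' @param harmonized Named logical vector (`fa`, `md`) marking tables already
#'   ComBat-adjusted (set by [combat_apply()]).
#' @param vol_normalized Whether `vol` is already normalized by total brain
#'   volume (its `total_brain_volume` column dropped).
#' @return An object of class `tbi_cohort`.
#' @seealso [read_cohort()], [write_cohort()], [simulate_cohort()]
#' @export
new_cohort <- function(subjects, lipid_raw, lipid_info, fa, md, vol,
                       lipid_processed = NULL, provenance = list(),
                       harmonized = c(fa = FALSE, md = FALSE),
                       vol_normalized = FALSE) {
  x <- structure(
    list(
      subjects = tibble::as_tibble(subjects),
      lipid_raw = tibble::as_tibble(lipid_raw),
      lipid_processed = if (!is.null(lipid_processed)) {
        tibble::as_tibble(lipid_processed)
      },
      lipid_info = tibble::as_tibble(lipid_info),
      fa = tibble::as_tibble(fa),
      md = tibble::as_tibble(md),
      vol = tibble::as_tibble(vol),
      provenance = provenance
    ),
    class = "tbi_cohort",
    harmonized = harmonized,
    vol_normalized = vol_normalized
  )
  # canonical row order by subject_id
  x$subjects <- dplyr::arrange(x$subjects, .data$subject_id)
  for (tb in c("lipid_raw", "lipid_processed", "fa", "md", "vol")) {
    if (!is.null(x[[tb]])) x[[tb]] <- dplyr::arrange(x[[tb]], .data$subject_id)
  }
  validate_cohort(x)
  x
}

#' Validate a cohort container
#'
#' Checks the structural invariants of a `tbi_cohort`: unique subject ids,
#' ROI column sets matching the packaged registries, strictly positive raw
#' concentrations, FA within \[0, 1\], positive MD and volumes, lipid data
#' present for every patient, and the adult-age inclusion rule (hard error
#' below 8 years, warning for ages in \[8, 18)).
#'
#' @param x A `tbi_cohort`.
#' @return Invisibly `TRUE`; errors describe the first violated invariant.
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "tbi_cohort"))
  sub <- x$subjects
  need <- c("subject_id", "group", "age", "sex", "site")
  miss <- setdiff(need, names(sub))
  if (length(miss) > 0) {
    stop("subjects table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sub$subject_id)) {
    stop("duplicate subject_id: ",
         paste(unique(sub$subject_id[duplicated(sub$subject_id)]),
               collapse = ", "),
         call. = FALSE)
  }
  if (!all(sub$group %in% c("patient", "control"))) {
    stop("group must be 'patient' or 'control'", call. = FALSE)
  }
  if (!all(sub$sex %in% c("M", "F"))) {
    stop("sex must be 'M' or 'F'", call. = FALSE)
  }
  if (any(sub$age < 8)) {
    stop("age below 8 years violates the inclusion criteria", call. = FALSE)
  }
  if (any(sub$age < 18)) {
    warning("age in [8, 18) — cohort inclusion was adults (>= 18 years)",
            call. = FALSE)
  }

  check_ids <- function(tb, label) {
    if (!"subject_id" %in% names(tb)) {
      stop(label, " table lacks a subject_id column", call. = FALSE)
    }
    if (anyDuplicated(tb$subject_id)) {
      stop("duplicate subject_id in ", label, " table", call. = FALSE)
    }
    unknown <- setdiff(tb$subject_id, sub$subject_id)
    if (length(unknown) > 0) {
      stop(label, " table has unknown subject_id: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }

  # ROI registries
  check_rois <- function(tb, expected, label) {
    got <- setdiff(names(tb), "subject_id")
    extra <- setdiff(got, expected)
    missing <- setdiff(expected, got)
    if (length(extra) + length(missing) > 0) {
      stop(label, " columns do not match the registered ROI set",
           if (length(missing)) paste0("; missing: ",
                                       paste(missing, collapse = ", ")),
           if (length(extra)) paste0("; unexpected: ",
                                     paste(extra, collapse = ", ")),
           call. = FALSE)
    }
  }
  tracts <- jhu_tracts()$roi
  check_ids(x$fa, "fa"); check_rois(x$fa, tracts, "fa")
  check_ids(x$md, "md"); check_rois(x$md, tracts, "md")
  check_ids(x$vol, "vol")
  vol_expected <- volumetric_rois()$roi
  if (!attr(x, "vol_normalized")) {
    vol_expected <- c(vol_expected, total_volume_col())
  }
  check_rois(x$vol, vol_expected, "vol")

  fa_vals <- as.matrix(x$fa[, tracts])
  if (any(fa_vals < 0 | fa_vals > 1, na.rm = TRUE)) {
    stop("FA values must lie in [0, 1]", call. = FALSE)
  }
  md_vals <- as.matrix(x$md[, tracts])
  if (any(md_vals <= 0, na.rm = TRUE)) {
    stop("MD values must be positive", call. = FALSE)
  }
  vol_vals <- as.matrix(x$vol[, setdiff(names(x$vol), "subject_id")])
  if (any(vol_vals <= 0, na.rm = TRUE)) {
    stop("volumes must be positive", call. = FALSE)
  }

  # lipids
  check_ids(x$lipid_raw, "lipid")
  lip_cols <- setdiff(names(x$lipid_raw), "subject_id")
  if (!setequal(lip_cols, x$lipid_info$lipid)) {
    stop("lipid columns do not match the lipid annotation table",
         call. = FALSE)
  }
  if (anyDuplicated(x$lipid_info$lipid)) {
    stop("duplicate lipid ids in annotation table", call. = FALSE)
  }
  if (!all(x$lipid_info$class %in% lipid_classes())) {
    stop("unknown lipid class; expected one of ",
         paste(lipid_classes(), collapse = ", "), call. = FALSE)
  }
  conc <- as.matrix(x$lipid_raw[, lip_cols])
  if (any(conc <= 0, na.rm = TRUE)) {
    bad <- lip_cols[apply(conc <= 0, 2, any, na.rm = TRUE)]
    stop("non-positive concentration in lipid(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  patients <- sub$subject_id[sub$group == "patient"]
  no_lip <- setdiff(patients, x$lipid_raw$subject_id)
  if (length(no_lip) > 0) {
    stop("patients without lipid data: ", paste(no_lip, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.tbi_cohort <- function(x, ...) {
  sub <- x$subjects
  cat("<tbi_cohort>\n")
  cat(sprintf("  subjects: %d (%d patients, %d controls) across %d sites\n",
              nrow(sub), sum(sub$group == "patient"),
              sum(sub$group == "control"), dplyr::n_distinct(sub$site)))
  cat(sprintf("  lipids:   %d (%d classes)%s\n",
              nrow(x$lipid_info), dplyr::n_distinct(x$lipid_info$class),
              if (is.null(x$lipid_processed)) "" else ", log-standardized"))
  h <- attr(x, "harmonized")
  cat(sprintf("  FA/MD:    %d tracts%s\n", ncol(x$fa) - 1L,
              if (all(h)) ", harmonized" else ""))
  cat(sprintf("  volumes:  %d ROIs%s\n",
              ncol(x$vol) - 1L - !attr(x, "vol_normalized"),
              if (attr(x, "vol_normalized")) ", TBV-normalized" else ""))
  invisible(x)
}

#' Subject ids of patients in a cohort
#' @param cohort A `tbi_cohort`.
#' @return Character vector.
#' @export
patient_ids <- function(cohort) {
  cohort$subjects$subject_id[cohort$subjects$group == "patient"]
}

#' Extract a lipid matrix from a cohort
#'
#' @param cohort A `tbi_cohort`.
#' @param processed Use the log-standardized values (default) or raw
#'   concentrations.
#' @return Numeric matrix (samples x lipids) with subject ids as rownames.
#' @export
lipid_matrix <- function(cohort, processed = TRUE) {
  tb <- if (processed) cohort$lipid_processed else cohort$lipid_raw
  if (is.null(tb)) {
    stop("cohort has no processed lipid table; run log_standardize() first",
         call. = FALSE)
  }
  m <- as.matrix(tb[, setdiff(names(tb), "subject_id")])
  rownames(m) <- tb$subject_id
  m
}

#' Extract an ROI metric matrix from a cohort
#'
#' @param cohort A `tbi_cohort`.
#' @param modality `"FA"`, `"MD"` or `"VOL"`.
#' @param group Restrict to `"patient"`, `"control"` or keep `"all"`.
#' @return Numeric matrix (subjects x ROIs) with subject ids as rownames.
#' @export
metric_matrix <- function(cohort, modality = c("FA", "MD", "VOL"),
                          group = c("all", "patient", "control")) {
  modality <- match.arg(modality)
  group <- match.arg(group)
  tb <- switch(modality, FA = cohort$fa, MD = cohort$md, VOL = cohort$vol)
  if (group != "all") {
    keep <- cohort$subjects$subject_id[cohort$subjects$group == group]
    tb <- tb[tb$subject_id %in% keep, , drop = FALSE]
  }
  m <- as.matrix(tb[, setdiff(names(tb), "subject_id")])
  rownames(m) <- tb$subject_id
  m
}

#' Log-transform and standardize lipid concentrations
#'
#' Applies the lipid preprocessing used throughout the pipeline: natural-log
#' transform followed by per-lipid standardization to mean 0 and unit sample
#' standard deviation (denominator n - 1), computed over the samples present
#' in the lipid table (patients; controls contribute no serum samples). The
#' raw table is kept unchanged alongside.
#'
#' @param cohort A `tbi_cohort`.
#' @param base Logarithm base (default `exp(1)`).
#' @return The cohort with `$lipid_processed` filled.
#' @export
log_standardize <- function(cohort, base = exp(1)) {
  stopifnot(inherits(cohort, "tbi_cohort"))
  tb <- cohort$lipid_raw
  lip <- setdiff(names(tb), "subject_id")
  m <- as.matrix(tb[, lip])
  if (any(m <= 0, na.rm = TRUE)) {
    stop("concentrations must be strictly positive for the log transform",
         call. = FALSE)
  }
  lm_ <- log(m, base = base)
  mu <- colMeans(lm_, na.rm = TRUE)
  sd_ <- apply(lm_, 2, stats::sd, na.rm = TRUE)
  if (any(sd_ == 0)) {
    stop("zero-variance lipid(s): ",
         paste(lip[sd_ == 0], collapse = ", "), call. = FALSE)
  }
  z <- sweep(sweep(lm_, 2, mu, "-"), 2, sd_, "/")
  out <- tibble::as_tibble(as.data.frame(z))
  out <- dplyr::bind_cols(tibble::tibble(subject_id = tb$subject_id), out)
  cohort$lipid_processed <- out
  cohort
}

#' Normalize regional volumes by total brain volume
#'
#' Divides each subject's ROI volumes by that subject's total brain volume
#' (head-size correction) and drops the total-volume column from the output.
#'
#' @param cohort A `tbi_cohort`, or a plain volume tibble (`subject_id`, ROI
#'   columns, `total_brain_volume`) for which the normalized tibble is
#'   returned directly.
#' @return The cohort with `$vol` normalized (or the normalized tibble).
#' @export
normalize_volumes <- function(cohort) {
  if (!inherits(cohort, "tbi_cohort")) {
    tb <- tibble::as_tibble(cohort)
    return(normalize_volume_table(tb))
  }
  if (attr(cohort, "vol_normalized")) {
    return(cohort)
  }
  cohort$vol <- normalize_volume_table(cohort$vol)
  attr(cohort, "vol_normalized") <- TRUE
  cohort
}

normalize_volume_table <- function(tb) {
  tvc <- total_volume_col()
  if (!tvc %in% names(tb)) {
    stop("volume table lacks a ", tvc, " column", call. = FALSE)
  }
  tot <- tb[[tvc]]
  bad <- is.na(tot) | tot <= 0
  if (any(bad)) {
    stop("missing or non-positive total brain volume for subject(s): ",
         paste(tb$subject_id[bad], collapse = ", "), call. = FALSE)
  }
  rois <- setdiff(names(tb), c("subject_id", tvc))
  tb[rois] <- tb[rois] / tot
  tb[[tvc]] <- NULL
  tb
}
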