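read_table_auto <- function(path) {
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) {
    readr::read_tsv(path, show_col_types = FALSE, comment = "#",
                    progress = FALSE)
  } else {
    readr::read_csv(path, show_col_types = FALSE, comment = "#",
                    progress = FALSE)
  }
}

#' Read a cohort from delimited files
#'
#' Reads the subject metadata, lipid concentration table, lipid annotation
#' sidecar and the three ROI metric tables from CSV/TSV files (format chosen
#' by extension), validates them and assembles a `tbi_cohort`. Row order is
#' canonicalized by `subject_id`; missing optional fields stay missing and
#' are never imputed.
#'
#' @param meta_path Subject metadata file.
#' @param lipid_path Raw lipid concentration file (`subject_id` + one column
#'   per lipid).
#' @param lipid_info_path Two-or-three-column sidecar (`lipid`, `class`,
#'   optional `id_level`).
#' @param roi_paths Named list/vector with elements `fa`, `md`, `vol` giving
#'   the metric table files.
#' @param attrs_path Optional JSON file of cohort attributes written by
#'   [write_cohort()] (harmonization flags, provenance).
#' @return A validated `tbi_cohort`.
#' @export
read_cohort <- function(meta_path, lipid_path, lipid_info_path, roi_paths,
                        attrs_path = NULL) {
  for (p in c(meta_path, lipid_path, lipid_info_path,
              unlist(roi_paths), attrs_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  stopifnot(all(c("fa", "md", "vol") %in% names(roi_paths)))
  subjects <- read_table_auto(meta_path)
  if ("propofol" %in% names(subjects)) {
    subjects$propofol <- as.logical(subjects$propofol)
  }
  info <- read_table_auto(lipid_info_path)
  if (!"id_level" %in% names(info)) info$id_level <- NA_integer_
  attrs <- if (!is.null(attrs_path)) {
    jsonlite::read_json(attrs_path, simplifyVector = TRUE)
  }
  harmonized <- c(fa = FALSE, md = FALSE)
  if (!is.null(attrs)) {
    harmonized[] <- as.logical(unlist(attrs$harmonized)[names(harmonized)])
  }
  new_cohort(
    subjects = subjects,
    lipid_raw = read_table_auto(lipid_path),
    lipid_info = info,
    fa = read_table_auto(roi_paths[["fa"]]),
    md = read_table_auto(roi_paths[["md"]]),
    vol = read_table_auto(roi_paths[["vol"]]),
    provenance = if (!is.null(attrs)) attrs$provenance else list(),
    harmonized = harmonized,
    vol_normalized = !is.null(attrs) && isTRUE(attrs$vol_normalized)
  )
}

#' Write a cohort to a directory of delimited files
#'
#' Writes `meta.csv`, `lipids.csv`, `lipid_info.csv`, `fa.csv`, `md.csv`,
#' `vol.csv` (and `lipids_processed.csv` when present) plus an
#' `attributes.json` recording harmonization flags and provenance, in the
#' layout [read_cohort()] expects. Numeric values round-trip exactly.
#'
#' @param cohort A `tbi_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "tbi_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(tb, name) {
    readr::write_csv(tb, file.path(dir, name), progress = FALSE)
  }
  wr(cohort$subjects, "meta.csv")
  wr(cohort$lipid_raw, "lipids.csv")
  wr(cohort$lipid_info, "lipid_info.csv")
  if (!is.null(cohort$lipid_processed)) {
    wr(cohort$lipid_processed, "lipids_processed.csv")
  }
  wr(cohort$fa, "fa.csv")
  wr(cohort$md, "md.csv")
  wr(cohort$vol, "vol.csv")
  jsonlite::write_json(
    list(
      harmonized = as.list(attr(cohort, "harmonized")),
      vol_normalized = attr(cohort, "vol_normalized"),
      provenance = cohort$provenance
    ),
    file.path(dir, "attributes.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory produced by [write_cohort()].
#' @return A `tbi_cohort`.
#' @export
read_cohort_dir <- function(dir) {
  x <- read_cohort(
    meta_path = file.path(dir, "meta.csv"),
    lipid_path = file.path(dir, "lipids.csv"),
    lipid_info_path = file.path(dir, "lipid_info.csv"),
    roi_paths = list(fa = file.path(dir, "fa.csv"),
                     md = file.path(dir, "md.csv"),
                     vol = file.path(dir, "vol.csv")),
    attrs_path = file.path(dir, "attributes.json")
  )
  pp <- file.path(dir, "lipids_processed.csv")
  if (file.exists(pp)) x$lipid_processed <- read_table_auto(pp)
  x
}

meta_header <- function(meta) {
  c("# lipidtract result",
    vapply(names(meta), function(k) sprintf("# %s: %s", k, meta[[k]]),
           character(1)))
}

write_tab_with_meta <- function(tb, path, meta = list()) {
  writeLines(meta_header(meta), path)
  readr::write_csv(tb, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' Write a pipeline result to delimited text
#'
#' Generic writer for pipeline outputs. Every file starts with a `#`
#' metadata header (result class, and any `seed`/`config_hash` recorded on
#' the object), followed by a deterministic CSV body whose numeric values
#' round-trip exactly; writing the result of [read_results()] back out
#' reproduces the file byte for byte.
#'
#' Matrix-valued results (`correlation_result`) write one file per component
#' (`_r`, `_p`, `_p_holm`, `_mask`) next to `path`.
#'
#' @param obj A pipeline result (abnormality profile, correlation result,
#'   frequency table, KS table, AUC report, network, or plain data frame).
#' @param path Output file path (`.csv`).
#' @param ... Unused.
#' @return Invisibly, the path(s) written.
#' @export
write_results <- function(obj, path, ...) UseMethod("write_results")

result_meta <- function(obj, class_label) {
  meta <- list(class = class_label)
  for (k in c("seed", "config_hash")) {
    v <- attr(obj, k, exact = TRUE)
    if (!is.null(v)) meta[[k]] <- v
  }
  meta
}

#' @rdname write_results
#' @export
write_results.data.frame <- function(obj, path, ...) {
  meta <- attr(obj, "lt_meta", exact = TRUE)
  if (is.null(meta)) meta <- result_meta(obj, class(obj)[1])
  plain <- obj
  attr(plain, "lt_meta") <- NULL
  # list-columns are not representable in CSV
  plain <- plain[, !vapply(plain, is.list, logical(1)), drop = FALSE]
  write_tab_with_meta(tibble::as_tibble(plain), path, meta)
}

#' @rdname write_results
#' @export
write_results.abnormality_profile <- function(obj, path, ...) {
  write_tab_with_meta(obj$burden, path,
                      result_meta(obj, "abnormality_profile"))
}

#' @rdname write_results
#' @export
write_results.frequency_table <- function(obj, path, ...) {
  base <- sub("\\.csv$", "", path)
  p1 <- paste0(base, "_lipid.csv")
  p2 <- paste0(base, "_roi.csv")
  write_tab_with_meta(obj$lipid, p1, result_meta(obj, "frequency_table"))
  write_tab_with_meta(obj$roi, p2, result_meta(obj, "frequency_table"))
  invisible(c(p1, p2))
}

#' @rdname write_results
#' @export
write_results.correlation_result <- function(obj, path, ...) {
  base <- sub("\\.csv$", "", path)
  comps <- c("r", "p", "p_holm", "mask")
  written <- character(0)
  for (cm in comps) {
    if (is.null(obj[[cm]])) next
    m <- obj[[cm]]
    tb <- dplyr::bind_cols(tibble::tibble(lipid = rownames(m)),
                           tibble::as_tibble(as.data.frame(m)))
    p <- paste0(base, "_", cm, ".csv")
    write_tab_with_meta(tb, p, result_meta(obj, "correlation_result"))
    written <- c(written, p)
  }
  invisible(written)
}

#' @rdname write_results
#' @export
write_results.auc_report <- function(obj, path, ...) {
  tb <- obj$results
  tb$features <- NULL
  write_tab_with_meta(tb, path, result_meta(obj, "auc_report"))
}

#' @rdname write_results
#' @export
write_results.partial_corr_graph <- function(obj, path, ...) {
  write_tab_with_meta(obj$edges, path,
                      result_meta(obj, "partial_corr_graph"))
}

#' @rdname write_results
#' @export
write_results.ks_result <- function(obj, path, ...) {
  write_tab_with_meta(tibble::as_tibble(obj), path,
                      result_meta(obj, "ks_result"))
}

#' Read a result file written by [write_results()]
#'
#' @param path File written by [write_results()].
#' @return A tibble with the parsed `#` metadata header attached as the
#'   `lt_meta` attribute, so a subsequent [write_results()] reproduces the
#'   file exactly.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, n = 50)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr[-1]) {
    kv <- sub("^# ", "", h)
    k <- sub(":.*$", "", kv)
    meta[[k]] <- sub("^[^:]+: ", "", kv)
  }
  tb <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  attr(tb, "lt_meta") <- meta
  tb
}
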