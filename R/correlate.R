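#' Lipid-by-ROI Pearson correlation matrices
#'
#' Correlates every processed (log-standardized) lipid with every ROI metric
#' value across patients, the group with serum samples. Returns the full
#' lipids x ROIs matrix of Pearson r together with two-sided p-values from
#' the t distribution on n - 2 degrees of freedom, computed pairwise on
#' complete observations.
#'
#' @param cohort A `tbi_cohort` with processed lipids (see
#'   [log_standardize()]).
#' @param modality `"FA"`, `"MD"` or `"VOL"`.
#' @return An object of class `correlation_result` with elements `modality`,
#'   `r`, `p` (lipids x ROIs matrices), `n`, and after [holm_filter()] also
#'   `p_holm`, `mask` and `alpha`.
#' @export
lipid_roi_correlate <- function(cohort, modality = c("FA", "MD", "VOL")) {
  modality <- match.arg(modality)
  stopifnot(inherits(cohort, "tbi_cohort"))
  lip <- lipid_matrix(cohort, processed = TRUE)
  met <- metric_matrix(cohort, modality, group = "patient")
  ids <- intersect(rownames(lip), rownames(met))
  if (length(ids) < 10) {
    stop("need at least 10 patients with both lipid and imaging data",
         call. = FALSE)
  }
  lip <- lip[ids, , drop = FALSE]
  met <- met[ids, , drop = FALSE]
  sd_l <- apply(lip, 2, stats::sd, na.rm = TRUE)
  sd_m <- apply(met, 2, stats::sd, na.rm = TRUE)
  if (any(sd_l == 0)) {
    stop("zero-variance lipid(s): ",
         paste(colnames(lip)[sd_l == 0], collapse = ", "), call. = FALSE)
  }
  if (any(sd_m == 0)) {
    stop("zero-variance ROI(s): ",
         paste(colnames(met)[sd_m == 0], collapse = ", "), call. = FALSE)
  }
  r <- stats::cor(lip, met, use = "pairwise.complete.obs")
  n <- crossprod(!is.na(lip), !is.na(met))
  r_cl <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  tstat <- r_cl * sqrt((n - 2) / (1 - r_cl^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  structure(
    list(modality = modality, r = r, p = p, n = n),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> %s: %d lipids x %d ROIs\n",
              x$modality, nrow(x$r), ncol(x$r)))
  if (!is.null(x$mask)) {
    cat(sprintf("  Holm-significant at alpha = %g: %d of %d pairs\n",
                x$alpha, sum(x$mask), length(x$mask)))
  }
  invisible(x)
}

#' Holm filtering of a correlation matrix
#'
#' Applies the Holm step-down family-wise-error correction jointly over all
#' lipid-by-ROI p-values of the modality (family size = n_lipids x n_ROIs by
#' default, the matrix-wide reading of adjusting the full correlation
#' matrix), and records the significance mask at the adjusted level.
#'
#' @param result A `correlation_result`.
#' @param alpha Significance level on the adjusted p-values (default 0.05).
#' @param family `"matrix"` (all pairs jointly, default) or `"per_lipid"`
#'   (Holm within each lipid's row, a sensitivity-analysis option).
#' @return The `correlation_result` with `p_holm`, `mask` and `alpha` set.
#' @export
holm_filter <- function(result, alpha = 0.05,
                        family = c("matrix", "per_lipid")) {
  stopifnot(inherits(result, "correlation_result"))
  family <- match.arg(family)
  p <- result$p
  if (family == "matrix") {
    adj <- matrix(stats::p.adjust(as.vector(p), method = "holm"),
                  nrow(p), ncol(p), dimnames = dimnames(p))
  } else {
    adj <- t(apply(p, 1, stats::p.adjust, method = "holm"))
    dimnames(adj) <- dimnames(p)
  }
  result$p_holm <- adj
  result$mask <- adj < alpha
  result$alpha <- alpha
  result$family <- family
  result
}

#' Frequency of significant correlations per lipid and per ROI
#'
#' Summarizes a Holm-filtered correlation matrix into the relative-frequency
#' tables: for each lipid, the count `k` of ROIs with a significant
#' correlation and the relative frequency `f = k / n_roi`; and symmetrically
#' per ROI across the lipids. Lipids are ranked by frequency (descending),
#' ties broken lexicographically.
#'
#' @param result A `correlation_result` after [holm_filter()].
#' @param lipid_info Optional lipid annotation tibble (adds class and
#'   identification level to the lipid table).
#' @return An object of class `frequency_table`: list with tibbles `lipid`
#'   (`lipid`, `k`, `freq`, `n_roi`, optionally `class`, `id_level`) and
#'   `roi` (`roi`, `k`, `freq`, `n_lipid`).
#' @export
frequency_table <- function(result, lipid_info = NULL) {
  stopifnot(inherits(result, "correlation_result"))
  if (is.null(result$mask)) {
    stop("run holm_filter() before frequency_table()", call. = FALSE)
  }
  mask <- result$mask
  n_roi <- ncol(mask)
  lipid <- tibble::tibble(
    lipid = rownames(mask),
    k = as.integer(rowSums(mask)),
    n_roi = n_roi,
    freq = unname(rowSums(mask)) / n_roi
  ) |>
    dplyr::arrange(dplyr::desc(.data$freq), .data$lipid)
  if (!is.null(lipid_info)) {
    lipid <- dplyr::left_join(lipid, lipid_info, by = "lipid") |>
      dplyr::relocate("class", "id_level", .after = "lipid")
  }
  roi <- tibble::tibble(
    roi = colnames(mask),
    k = as.integer(colSums(mask)),
    n_lipid = nrow(mask),
    freq = unname(colSums(mask)) / nrow(mask)
  ) |>
    dplyr::arrange(dplyr::desc(.data$freq), .data$roi)
  structure(list(lipid = lipid, roi = roi, modality = result$modality),
            class = "frequency_table")
}

#' @export
print.frequency_table <- function(x, ...) {
  cat(sprintf("<frequency_table> %s\n", x$modality))
  print(utils::head(x$lipid, 10))
  invisible(x)
}

#' Per-ROI summary of significant correlation values
#'
#' For each ROI, collects the Holm-significant correlation values across all
#' lipids, their mean and the resulting sign label — the per-tract data
#' behind beanplot-style displays of whether a tract is overall positively
#' or negatively associated with lipid concentrations. ROIs with no
#' significant lipid are reported with a missing mean, not zero.
#'
#' @param result A `correlation_result` after [holm_filter()].
#' @return A tibble: `roi`, `n_sig`, `mean_r`, `sign`
#'   (`"positive"`/`"negative"`/`NA`), and list-column `r_values`.
#' @export
roi_sign_summary <- function(result) {
  stopifnot(inherits(result, "correlation_result"))
  if (is.null(result$mask)) {
    stop("run holm_filter() before roi_sign_summary()", call. = FALSE)
  }
  purrr::map(colnames(result$mask), function(v) {
    rv <- result$r[result$mask[, v], v]
    tibble::tibble(
      roi = v,
      n_sig = length(rv),
      mean_r = if (length(rv) > 0) mean(rv) else NA_real_,
      sign = if (length(rv) == 0) NA_character_
             else if (mean(rv) >= 0) "positive" else "negative",
      r_values = list(unname(rv))
    )
  }) |>
    dplyr::bind_rows()
}

#' Lipid-class versus tract-injury correlation matrix
#'
#' Correlates, across patients, the summed *raw* concentration of each lipid
#' class with the binary abnormal flag of each tract (a point-biserial
#' correlation), yielding the tracts x classes matrix relating circulating
#' lipid classes to the anatomical distribution of injury. Rows and columns
#' are ordered by average-linkage hierarchical clustering of the correlation
#' matrix (correlation distance), mirroring the dendrogram ordering of
#' heatmap displays.
#'
#' Tracts abnormal in none or all patients have an undefined correlation and
#' are reported as missing.
#'
#' @param cohort A `tbi_cohort`.
#' @param profiles An `abnormality_profile` from [flag_abnormal()].
#' @return An object of class `class_injury_matrix`: tibble `roi`, `class`,
#'   `r`, with attributes `roi_order` and `class_order`.
#' @export
class_injury_correlation <- function(cohort, profiles) {
  stopifnot(inherits(cohort, "tbi_cohort"),
            inherits(profiles, "abnormality_profile"))
  raw <- lipid_matrix(cohort, processed = FALSE)
  info <- cohort$lipid_info
  cls <- sort(unique(info$class))
  class_sum <- sapply(cls, function(cl) {
    rowSums(raw[, info$lipid[info$class == cl], drop = FALSE])
  })
  flags <- profiles$flags |>
    dplyr::select("subject_id", "roi", "abnormal") |>
    tidyr::pivot_wider(names_from = "roi", values_from = "abnormal")
  ids <- intersect(rownames(class_sum), flags$subject_id)
  class_sum <- class_sum[ids, , drop = FALSE]
  fm <- as.matrix(flags[match(ids, flags$subject_id), -1])
  storage.mode(fm) <- "numeric"

  rmat <- matrix(NA_real_, ncol(fm), length(cls),
                 dimnames = list(colnames(fm), cls))
  for (v in colnames(fm)) {
    f <- fm[, v]
    ok <- !is.na(f)
    if (sum(ok) < 3 || stats::var(f[ok]) == 0) next  # all-0 or all-1 flags
    rmat[v, ] <- stats::cor(class_sum[ok, , drop = FALSE], f[ok])
  }

  order_by_clust <- function(m) {
    keep <- rowSums(is.na(m)) == 0
    if (sum(keep) < 3) return(rownames(m))
    cm <- suppressWarnings(stats::cor(t(m[keep, , drop = FALSE])))
    cm[is.na(cm)] <- 0
    hc <- stats::hclust(stats::as.dist(1 - cm), method = "average")
    c(rownames(m)[keep][hc$order], rownames(m)[!keep])
  }
  roi_order <- order_by_clust(rmat)
  class_order <- order_by_clust(t(rmat))

  out <- tibble::tibble(
    roi = rep(rownames(rmat), each = ncol(rmat)),
    class = rep(colnames(rmat), times = nrow(rmat)),
    r = as.vector(t(rmat))
  )
  structure(out, class = c("class_injury_matrix", class(out)),
            roi_order = roi_order, class_order = class_order)
}
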