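#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a normative model set
#'
#' @param x A `normative_models` object.
#' @param ... Unused.
#' @return One row per (modality, roi) with coefficients and residual SD.
#' @export
tidy.normative_models <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Tidy an abnormality profile
#'
#' @param x An `abnormality_profile`.
#' @param ... Unused.
#' @return The long per-patient, per-tract flag table.
#' @export
tidy.abnormality_profile <- function(x, ...) x$flags

#' One-row summary of an abnormality profile
#'
#' @param x An `abnormality_profile`.
#' @param ... Unused.
#' @return Tibble with patient count and burden summary statistics.
#' @export
glance.abnormality_profile <- function(x, ...) {
  b <- x$burden$burden
  tibble::tibble(
    n_patients = length(b), band = x$band,
    mean_burden = mean(b), median_burden = stats::median(b),
    q25_burden = unname(stats::quantile(b, 0.25)),
    q75_burden = unname(stats::quantile(b, 0.75))
  )
}

#' Tidy a ComBat model
#'
#' @param x A `combat_model`.
#' @param ... Unused.
#' @return One row per (site, roi) with raw and shrunken site effects.
#' @export
tidy.combat_model <- function(x, ...) {
  tibble::tibble(
    modality = x$modality,
    site = rep(x$sites, times = length(x$rois)),
    roi = rep(x$rois, each = length(x$sites)),
    gamma_hat = as.vector(x$gamma_hat),
    gamma_star = as.vector(x$gamma_star),
    delta_hat = as.vector(x$delta_hat),
    delta_star = as.vector(x$delta_star)
  )
}

#' Tidy a correlation result into long form
#'
#' @param x A `correlation_result`.
#' @param ... Unused.
#' @return One row per lipid-ROI pair: `lipid`, `roi`, `r`, `p`, and when
#'   Holm-filtered also `p_holm`, `significant`.
#' @export
tidy.correlation_result <- function(x, ...) {
  out <- tibble::tibble(
    modality = x$modality,
    lipid = rep(rownames(x$r), times = ncol(x$r)),
    roi = rep(colnames(x$r), each = nrow(x$r)),
    r = as.vector(x$r),
    p = as.vector(x$p)
  )
  if (!is.null(x$p_holm)) {
    out$p_holm <- as.vector(x$p_holm)
    out$significant <- as.vector(x$mask)
  }
  out
}

#' Tidy an AUC report (per-repeat results)
#'
#' @param x An `auc_report`.
#' @param ... Unused.
#' @return The per-repeat tibble.
#' @export
tidy.auc_report <- function(x, ...) x$results

#' One-row summary of an AUC report
#'
#' @param x An `auc_report`.
#' @param ... Unused.
#' @return Settings plus mean/median/IQR of the held-out AUC.
#' @export
glance.auc_report <- function(x, ...) {
  a <- x$results$auc
  tibble::tibble(
    penalty = x$spec$penalty, features = x$spec$features,
    scope = x$spec$scope, n_repeats = x$spec$n_repeats,
    n_subjects = x$n_subjects, n_pos = x$n_pos, n_neg = x$n_neg,
    mean_auc = mean(a), median_auc = stats::median(a),
    q25_auc = unname(stats::quantile(a, 0.25)),
    q75_auc = unname(stats::quantile(a, 0.75))
  )
}

#' Tidy a partial-correlation graph (edge list)
#'
#' @param x A `partial_corr_graph`.
#' @param ... Unused.
#' @return The edge tibble.
#' @export
tidy.partial_corr_graph <- function(x, ...) x$edges

#' One-row summary of a partial-correlation graph
#'
#' @param x A `partial_corr_graph`.
#' @param ... Unused.
#' @return Node/edge counts by type.
#' @export
glance.partial_corr_graph <- function(x, ...) {
  e <- x$edges
  lipids <- x$nodes$node[x$nodes$type == "lipid"]
  tracts <- x$nodes$node[x$nodes$type == "tract"]
  kind <- function(a, b) {
    ifelse(a %in% lipids & b %in% lipids, "lipid-lipid",
      ifelse(a %in% tracts & b %in% tracts, "tract-tract",
        ifelse((a %in% lipids & b %in% tracts) |
                 (a %in% tracts & b %in% lipids), "lipid-tract",
               "covariate")))
  }
  tibble::tibble(
    modality = x$modality, alpha = x$alpha, n = x$n,
    n_nodes = nrow(x$nodes), n_edges = nrow(e),
    n_lipid_lipid = sum(kind(e$from, e$to) == "lipid-lipid"),
    n_lipid_tract = sum(kind(e$from, e$to) == "lipid-tract"),
    n_tract_tract = sum(kind(e$from, e$to) == "tract-tract"),
    n_covariate = sum(kind(e$from, e$to) == "covariate"),
    n_negative = sum(e$sign == "negative")
  )
}
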