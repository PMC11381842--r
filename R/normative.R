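#' Fit normative healthy-control baselines per tract
#'
#' For each of the 48 tracts and each diffusion metric (FA, MD), fits an
#' ordinary least-squares regression of the control values on sex and a
#' second-degree polynomial in age, defining the covariate-adjusted healthy
#' baseline. The residual SD (denominator n - 4, the residual degrees of
#' freedom) defines the width of the baseline band used to flag patient
#' abnormalities.
#'
#' @param cohort A harmonized `tbi_cohort` with at least 10 controls.
#' @return An object of class `normative_models`: a tibble with one row per
#'   (modality, roi) holding `intercept`, `b_sex`, `b_age`, `b_age2`,
#'   `sigma` (residual SD) and `n`.
#' @export
fit_normative <- function(cohort) {
  stopifnot(inherits(cohort, "tbi_cohort"))
  sub <- cohort$subjects
  ctrl <- sub[sub$group == "control", ]
  if (nrow(ctrl) < 10) {
    stop("need at least 10 controls to fit normative baselines",
         call. = FALSE)
  }
  X <- cbind(intercept = 1, normative_design(ctrl))
  if (qr(X)$rank < ncol(X)) {
    stop("rank-deficient normative design (e.g., a single sex among controls)",
         call. = FALSE)
  }
  n <- nrow(X)
  fit_one <- function(modality) {
    y <- metric_matrix(cohort, modality)[ctrl$subject_id, , drop = FALSE]
    coefs <- solve(crossprod(X), crossprod(X, y))
    res <- y - X %*% coefs
    sigma <- sqrt(colSums(res^2) / (n - ncol(X)))
    tibble::tibble(
      modality = modality,
      roi = colnames(y),
      intercept = unname(coefs["intercept", ]),
      b_sex = unname(coefs["male", ]),
      b_age = unname(coefs["age", ]),
      b_age2 = unname(coefs["age2", ]),
      sigma = unname(sigma),
      n = n
    )
  }
  out <- dplyr::bind_rows(fit_one("FA"), fit_one("MD"))
  structure(out, class = c("normative_models", class(out)))
}

normative_design <- function(subjects) {
  cbind(male = as.numeric(subjects$sex == "M"),
        age = subjects$age, age2 = subjects$age^2)
}

predict_normative <- function(models, subjects, modality) {
  m <- models[models$modality == modality, ]
  X <- cbind(1, normative_design(subjects))
  coefs <- t(as.matrix(m[, c("intercept", "b_sex", "b_age", "b_age2")]))
  mu <- X %*% coefs
  colnames(mu) <- m$roi
  mu
}

#' Flag abnormal tracts and compute the burden of injury
#'
#' For every patient and tract, compares the FA and MD values against the
#' normative prediction for that patient's age and sex. A metric is "out"
#' when it deviates from the prediction by more than `band` residual SDs
#' (two-sided); a tract is abnormal only when *both* FA and MD are out. The
#' burden of injury is the percentage of evaluable tracts that are abnormal.
#'
#' Tracts with a missing FA or MD value are excluded from both the numerator
#' and the denominator of that patient's burden.
#'
#' @param cohort A harmonized `tbi_cohort`.
#' @param models A `normative_models` object from [fit_normative()].
#' @param band Width of the baseline band in residual SDs (default 1).
#' @return An object of class `abnormality_profile`: list with `flags` (long
#'   tibble: `subject_id`, `roi`, `fa_dev`, `md_dev`, `fa_out`, `md_out`,
#'   `abnormal`) and `burden` (tibble: `subject_id`, `n_roi`, `n_abnormal`,
#'   `burden` in percent).
#' @export
flag_abnormal <- function(cohort, models, band = 1) {
  stopifnot(inherits(cohort, "tbi_cohort"),
            inherits(models, "normative_models"))
  sub <- cohort$subjects
  pats <- sub[sub$group == "patient", ]
  fa <- metric_matrix(cohort, "FA")[pats$subject_id, , drop = FALSE]
  md <- metric_matrix(cohort, "MD")[pats$subject_id, , drop = FALSE]
  mu_fa <- predict_normative(models, pats, "FA")[, colnames(fa), drop = FALSE]
  mu_md <- predict_normative(models, pats, "MD")[, colnames(md), drop = FALSE]
  s_fa <- models$sigma[models$modality == "FA"][
    match(colnames(fa), models$roi[models$modality == "FA"])]
  s_md <- models$sigma[models$modality == "MD"][
    match(colnames(md), models$roi[models$modality == "MD"])]

  fa_dev <- sweep(fa - mu_fa, 2, s_fa, "/")
  md_dev <- sweep(md - mu_md, 2, s_md, "/")
  fa_out <- abs(fa_dev) > band
  md_out <- abs(md_dev) > band
  abnormal <- fa_out & md_out
  # a tract with either metric missing is not evaluable for this patient
  abnormal[is.na(fa_dev) | is.na(md_dev)] <- NA

  flags <- tibble::tibble(
    subject_id = rep(pats$subject_id, times = ncol(fa)),
    roi = rep(colnames(fa), each = nrow(fa)),
    fa_dev = as.vector(fa_dev),
    md_dev = as.vector(md_dev),
    fa_out = as.vector(fa_out),
    md_out = as.vector(md_out),
    abnormal = as.vector(abnormal)
  ) |>
    dplyr::arrange(.data$subject_id, .data$roi)

  burden <- flags |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      n_roi = sum(!is.na(.data$abnormal)),
      n_abnormal = sum(.data$abnormal, na.rm = TRUE),
      burden = 100 * .data$n_abnormal / .data$n_roi,
      .groups = "drop"
    )

  structure(list(flags = flags, burden = burden, band = band),
            class = "abnormality_profile")
}

#' @export
print.abnormality_profile <- function(x, ...) {
  cat(sprintf("<abnormality_profile> %d patients, band = %g SD\n",
              nrow(x$burden), x$band))
  cat(sprintf("  burden of injury: median %.1f%% (IQR %.1f-%.1f%%)\n",
              stats::median(x$burden$burden),
              stats::quantile(x$burden$burden, 0.25),
              stats::quantile(x$burden$burden, 0.75)))
  invisible(x)
}

#' Per-tract group comparison by two-sample Kolmogorov-Smirnov tests
#'
#' Tests, tract by tract, whether the patient and control distributions of a
#' diffusion metric differ, with Benjamini-Hochberg false-discovery-rate
#' adjustment across the tracts of the modality. The exact two-sample KS
#' p-value is used when both groups have at most 100 subjects, the
#' asymptotic approximation otherwise.
#'
#' @param cohort A harmonized `tbi_cohort` with at least 5 subjects per
#'   group.
#' @param modality `"FA"` or `"MD"`.
#' @param alpha Significance level on the adjusted p-values (default 0.05).
#' @return A tibble of class `ks_result`: `modality`, `roi`, `D`, `p`, `q`,
#'   `significant`.
#' @export
ks_group_comparison <- function(cohort, modality = c("FA", "MD"),
                                alpha = 0.05) {
  modality <- match.arg(modality)
  pat <- metric_matrix(cohort, modality, group = "patient")
  ctl <- metric_matrix(cohort, modality, group = "control")
  if (nrow(pat) < 5 || nrow(ctl) < 5) {
    stop("need at least 5 subjects per group", call. = FALSE)
  }
  exact <- nrow(pat) <= 100 && nrow(ctl) <= 100
  res <- purrr::map(colnames(pat), function(v) {
    x <- pat[, v][!is.na(pat[, v])]
    y <- ctl[, v][!is.na(ctl[, v])]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      return(tibble::tibble(roi = v, D = 0, p = 1))
    }
    kt <- suppressWarnings(stats::ks.test(x, y, exact = exact))
    tibble::tibble(roi = v, D = unname(kt$statistic), p = unname(kt$p.value))
  }) |>
    dplyr::bind_rows()
  res$q <- stats::p.adjust(res$p, method = "BH")
  res$significant <- res$q < alpha
  out <- dplyr::bind_cols(tibble::tibble(modality = modality), res)
  structure(out, class = c("ks_result", class(out)))
}
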