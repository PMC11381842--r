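#' Fit a reference-anchored ComBat harmonization model
#'
#' Estimates the parametric empirical-Bayes location/scale model that removes
#' scanner/site effects from an ROI metric while preserving the biological
#' covariates (sex, age, age squared). Following the usual practice for
#' multi-site patient studies with traveling healthy controls, the model —
#' per-ROI covariate regression, pooled residual scale, and the shrunken
#' per-site additive (`gamma*`) and multiplicative (`delta*`) effects — is
#' estimated on the reference subjects (controls by default) and can then be
#' applied to any subject scanned at a known site.
#'
#' The estimation mirrors the standard parametric ComBat algorithm: per-ROI
#' least squares with site indicators, standardization by the pooled residual
#' SD, normal/inverse-gamma priors across ROIs fit by moments, and the
#' iterative conditional posterior-mean solver (relative tolerance 1e-4,
#' at most 100 iterations).
#'
#' @param cohort A `tbi_cohort`.
#' @param modality `"FA"` or `"MD"`.
#' @param reference `"controls"` (default) to anchor estimation on healthy
#'   controls, or `"all"` to estimate from every subject.
#' @return An object of class `combat_model`.
#' @export
combat_fit <- function(cohort, modality = c("FA", "MD"),
                       reference = c("controls", "all")) {
  modality <- match.arg(modality)
  reference <- match.arg(reference)
  stopifnot(inherits(cohort, "tbi_cohort"))
  sub <- cohort$subjects
  keep <- if (reference == "controls") sub$group == "control" else rep(TRUE, nrow(sub))
  ref <- sub[keep, ]
  y <- metric_matrix(cohort, modality)[ref$subject_id, , drop = FALSE]

  site <- factor(ref$site)
  if (nlevels(site) < 2) {
    stop("harmonization needs at least 2 sites among reference subjects",
         call. = FALSE)
  }
  n_per <- table(site)
  if (any(n_per < 3)) {
    stop("site(s) with fewer than 3 reference subjects: ",
         paste(names(n_per)[n_per < 3], collapse = ", "), call. = FALSE)
  }

  age_center <- mean(ref$age)
  X <- combat_design(ref, age_center)
  B <- stats::model.matrix(~ 0 + site)
  D <- cbind(B, X)
  if (qr(D)$rank < ncol(D)) {
    stop("singular covariate design (e.g., a single sex or constant age)",
         call. = FALSE)
  }

  n <- nrow(y)
  S <- nlevels(site)
  bhat <- solve(crossprod(D), crossprod(D, y))
  w <- as.numeric(n_per) / n
  alpha <- as.numeric(w %*% bhat[seq_len(S), , drop = FALSE])
  beta <- bhat[-seq_len(S), , drop = FALSE]
  fitted <- D %*% bhat
  var_pooled <- colMeans((y - fitted)^2)
  if (any(var_pooled <= 0)) {
    stop("zero residual variance in ROI(s): ",
         paste(colnames(y)[var_pooled <= 0], collapse = ", "), call. = FALSE)
  }
  sigma <- sqrt(var_pooled)

  stand_mean <- outer(rep(1, n), alpha) + X %*% beta
  z <- sweep(y - stand_mean, 2, sigma, "/")

  gamma_hat <- apply(z, 2, function(col) tapply(col, site, mean))
  delta_hat <- apply(z, 2, function(col) tapply(col, site, stats::var))

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  for (s in seq_len(S)) {
    g <- gamma_hat[s, ]
    d <- delta_hat[s, ]
    g_bar <- mean(g)
    t2 <- stats::var(g)
    m <- mean(d)
    s2 <- stats::var(d)
    a_prior <- (2 * s2 + m^2) / s2
    b_prior <- (m * s2 + m^3) / s2
    ns <- as.numeric(n_per[s])
    zs <- z[site == levels(site)[s], , drop = FALSE]
    g_old <- g
    d_old <- d
    for (it in seq_len(100)) {
      g_new <- (t2 * ns * g + d_old * g_bar) / (t2 * ns + d_old)
      sum2 <- colSums(sweep(zs, 2, g_new, "-")^2)
      d_new <- (0.5 * sum2 + b_prior) / (ns / 2 + a_prior - 1)
      change <- max(abs(g_new - g_old) / abs(g_old),
                    abs(d_new - d_old) / abs(d_old))
      g_old <- g_new
      d_old <- d_new
      if (change < 1e-4) break
    }
    gamma_star[s, ] <- g_old
    delta_star[s, ] <- d_old
  }

  structure(
    list(
      modality = modality,
      reference = reference,
      rois = colnames(y),
      sites = levels(site),
      n_per_site = as.numeric(n_per),
      age_center = age_center,
      alpha = stats::setNames(alpha, colnames(y)),
      beta = beta,
      sigma = stats::setNames(sigma, colnames(y)),
      gamma_hat = gamma_hat,
      delta_hat = delta_hat,
      gamma_star = gamma_star,
      delta_star = delta_star
    ),
    class = "combat_model"
  )
}

combat_design <- function(subjects, age_center) {
  a <- subjects$age - age_center
  cbind(male = as.numeric(subjects$sex == "M"), age = a, age2 = a^2)
}

#' @export
print.combat_model <- function(x, ...) {
  cat(sprintf("<combat_model> %s, %d ROIs, %d sites (reference: %s)\n",
              x$modality, length(x$rois), length(x$sites), x$reference))
  cat(sprintf("  |gamma*| range: %.4f - %.4f; delta* range: %.3f - %.3f\n",
              min(abs(x$gamma_star)), max(abs(x$gamma_star)),
              min(x$delta_star), max(x$delta_star)))
  invisible(x)
}

#' Apply a fitted ComBat model to a cohort
#'
#' Adjusts every subject's ROI values of the model's modality:
#' `y* = sigma * (z - gamma*) / sqrt(delta*) + alpha + X beta`, where `z` is
#' the standardized residual under the reference fit. Covariate-linked
#' variation is preserved; only the site location/scale is removed. Subjects
#' at a site unknown to the model are a hard error.
#'
#' @param cohort A `tbi_cohort`.
#' @param model A `combat_model` from [combat_fit()].
#' @return The cohort with the harmonized metric table and its harmonized
#'   flag set.
#' @export
combat_apply <- function(cohort, model) {
  stopifnot(inherits(cohort, "tbi_cohort"), inherits(model, "combat_model"))
  sub <- cohort$subjects
  unknown <- setdiff(unique(sub$site), model$sites)
  if (length(unknown) > 0) {
    stop("site(s) not present in the harmonization model: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  slot <- tolower(model$modality)
  tb <- cohort[[slot]]
  y <- as.matrix(tb[, model$rois])
  X <- combat_design(sub, model$age_center)
  mean_part <- outer(rep(1, nrow(y)), model$alpha) + X %*% model$beta
  z <- sweep(y - mean_part, 2, model$sigma, "/")
  si <- match(sub$site, model$sites)
  z_adj <- (z - model$gamma_star[si, , drop = FALSE]) /
    sqrt(model$delta_star[si, , drop = FALSE])
  y_star <- sweep(z_adj, 2, model$sigma, "*") + mean_part
  tb[, model$rois] <- tibble::as_tibble(as.data.frame(y_star))
  cohort[[slot]] <- tb
  h <- attr(cohort, "harmonized")
  h[slot] <- TRUE
  attr(cohort, "harmonized") <- h
  cohort
}

#' Harmonize a cohort end to end
#'
#' Convenience wrapper: fits and applies reference-anchored ComBat to the FA
#' and MD tables, and normalizes regional volumes by total brain volume
#' (volumes are not ComBat-adjusted).
#'
#' @param cohort A `tbi_cohort`.
#' @param reference Passed to [combat_fit()].
#' @return The harmonized cohort.
#' @export
harmonize <- function(cohort, reference = c("controls", "all")) {
  reference <- match.arg(reference)
  for (m in c("FA", "MD")) {
    cohort <- combat_apply(cohort, combat_fit(cohort, m, reference))
  }
  normalize_volumes(cohort)
}
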