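#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions the generator emulates: a multi-site TBI
#' MRI sub-study with 103 patients and 104 imaging-only healthy controls
#' scanned on nine scanners, a 201-lipid quantitative serum panel in seven
#' classes, scanner-specific additive and multiplicative effects on the
#' diffusion metrics, age and sex effects on every ROI, per-patient planted
#' injured tract sets (FA decreased, MD increased), planted lipid-tract
#' correlations, and a logistic dependence of MRI positivity on a designated
#' lipid subset.
#'
#' @param n_patients,n_controls,n_sites,n_lipids Cohort dimensions.
#' @param injury_fraction Expected fraction of a patient's 48 tracts that
#'   are injured. Each patient draws an injury propensity from a Beta
#'   distribution with this mean (shape 1.2, long right tail — mostly mild
#'   injuries with a severe tail, as in clinical TBI cohorts) and tracts
#'   are injured independently at that per-patient rate.
#' @param fa_shift_sd,md_shift_sd Injury effect sizes in units of the
#'   control residual SD of the tract (FA shifted down, MD up).
#' @param site_additive_sd Scale of additive scanner offsets, in residual-SD
#'   units.
#' @param site_multiplicative_sd SD of the log multiplicative scanner factor.
#' @param assoc_strength Population correlation magnitude planted between
#'   each designated lipid and its designated tract metric; must be in
#'   \[0, 1).
#' @param n_assoc_pairs Number of planted lipid-tract pairs (split between
#'   FA, positive sign, and MD, negative sign).
#' @param mri_effect Log-odds contribution per standardized unit of each
#'   MRI-informative lipid.
#' @param n_mri_lipids Number of MRI-informative lipids.
#' @param n_mri_missing Patients with missing MRI status (the cohort the
#'   generator emulates had one).
#' @param within_class_cor,between_class_cor Exchangeable correlations of
#'   log lipid levels within and between lipid classes.
#' @param seed RNG seed; the generator is fully reproducible given the seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 103,
                       n_controls = 104,
                       n_sites = 9,
                       n_lipids = 201,
                       injury_fraction = 0.15,
                       fa_shift_sd = 3,
                       md_shift_sd = 3,
                       site_additive_sd = 0.5,
                       site_multiplicative_sd = 0.2,
                       assoc_strength = 0.5,
                       n_assoc_pairs = 30,
                       mri_effect = 1,
                       n_mri_lipids = 10,
                       n_mri_missing = 1,
                       within_class_cor = 0.4,
                       between_class_cor = 0.1,
                       seed = 1) {
  cfg <- list(
    n_patients = as.integer(n_patients), n_controls = as.integer(n_controls),
    n_sites = as.integer(n_sites), n_lipids = as.integer(n_lipids),
    injury_fraction = injury_fraction,
    fa_shift_sd = fa_shift_sd, md_shift_sd = md_shift_sd,
    site_additive_sd = site_additive_sd,
    site_multiplicative_sd = site_multiplicative_sd,
    assoc_strength = assoc_strength,
    n_assoc_pairs = as.integer(n_assoc_pairs),
    mri_effect = mri_effect, n_mri_lipids = as.integer(n_mri_lipids),
    n_mri_missing = as.integer(n_mri_missing),
    within_class_cor = within_class_cor,
    between_class_cor = between_class_cor,
    seed = as.integer(seed)
  )
  with(cfg, {
    stopifnot(
      n_patients >= 2, n_controls >= 2, n_sites >= 2, n_lipids >= 7,
      injury_fraction >= 0, injury_fraction <= 1,
      fa_shift_sd >= 0, md_shift_sd >= 0,
      site_additive_sd >= 0, site_multiplicative_sd >= 0,
      assoc_strength >= 0, assoc_strength < 1,
      n_assoc_pairs >= 0, n_mri_lipids >= 0,
      within_class_cor >= 0, within_class_cor < 1,
      between_class_cor >= 0, between_class_cor <= within_class_cor
    )
  })
  structure(cfg, class = "sim_config")
}

# near-even site allocation guarantees >= 3 reference subjects per site
# for cohorts of realistic size
allocate_sites <- function(n, sites) {
  sample(rep_len(sites, n))
}

lipid_cholesky <- function(info, within, between) {
  L <- nrow(info)
  sigma <- matrix(between, L, L)
  same <- outer(info$class, info$class, "==")
  sigma[same] <- within
  diag(sigma) <- 1
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) {
    stop("lipid correlation structure is not positive definite; ",
         "lower within/between class correlations", call. = FALSE)
  }
  ch
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws a complete `tbi_cohort` under the generative model described in
#' [sim_config()] together with the ground truth needed to validate each
#' downstream stage: the injured-tract set of every patient, the planted
#' lipid-tract associations with their signs, the MRI-informative lipid set
#' and the scanner effects.
#'
#' Control tract values are baseline(age, sex) + scanner effect + Gaussian
#' noise, with a linear sex offset and a quadratic age trend; patients
#' additionally receive `-fa_shift_sd * sigma` on FA and `+md_shift_sd *
#' sigma` on MD in their injured tracts. Log lipid levels are drawn from a
#' class-structured multivariate normal; each planted pair couples the lipid
#' to the observed tract metric so the population correlation is
#' approximately `+/- assoc_strength` (positive for FA, negative for MD).
#' MRI positivity follows a logistic model on the informative lipids. FA is
#' clamped to (0, 1) and MD/volumes to positive values; clamp counts are
#' recorded in the cohort provenance.
#'
#' @param config A [sim_config()].
#' @return A list with elements `cohort` (a `tbi_cohort`) and `truth` (list
#'   with `injured_rois`, `associated_pairs`, `mri_informative_lipids`,
#'   `site_effects`).
#' @export
#' @examples
#' sim <- simulate_cohort(sim_config(n_patients = 12, n_controls = 12,
#'                                   n_sites = 2, n_lipids = 14, seed = 1))
#' sim$cohort
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  np <- config$n_patients
  nc <- config$n_controls
  n <- np + nc
  tracts <- jhu_tracts()$roi
  nt <- length(tracts)
  vol_rois <- volumetric_rois()$roi
  sites <- sprintf("site%02d", seq_len(config$n_sites))

  subjects <- tibble::tibble(
    subject_id = c(sprintf("P%03d", seq_len(np)), sprintf("C%03d", seq_len(nc))),
    group = rep(c("patient", "control"), c(np, nc)),
    age = stats::runif(n, 18, 75),
    sex = ifelse(stats::runif(n) < rep(c(0.75, 0.60), c(np, nc)), "M", "F"),
    site = c(allocate_sites(np, sites), allocate_sites(nc, sites)),
    mri_status = NA_character_,
    ct_status = NA_character_,
    time_to_blood_h = NA_real_,
    time_to_scan_h = NA_real_,
    propofol = NA
  )
  is_pat <- subjects$group == "patient"
  subjects$time_to_blood_h[is_pat] <- stats::runif(np, 1, 24)
  subjects$time_to_scan_h[is_pat] <- stats::runif(np, 24, 672)
  subjects$propofol[is_pat] <- stats::runif(np) < 0.3

  clamps <- c(fa = 0L, md = 0L, vol = 0L)

  # --- tract metrics (FA, MD) ------------------------------------------
  age_c <- subjects$age - 45
  male <- as.numeric(subjects$sex == "M")
  site_idx <- match(subjects$site, sites)

  draw_modality <- function(dir, mu_range, sigma_base, shift_sd) {
    mu <- stats::runif(nt, mu_range[1], mu_range[2])
    sigma <- sigma_base * stats::runif(nt, 0.8, 1.2)
    b_sex <- stats::rnorm(nt, 0, 0.3) * sigma
    b_age <- dir * stats::runif(nt, 0.3, 0.7) * sigma / 30
    b_age2 <- dir * stats::runif(nt, 0.05, 0.2) * sigma / 900
    gamma <- matrix(stats::rnorm(config$n_sites * nt, 0,
                                 config$site_additive_sd), config$n_sites, nt)
    gamma <- sweep(gamma, 2, sigma, "*")
    delta <- matrix(exp(stats::rnorm(config$n_sites * nt, 0,
                                     config$site_multiplicative_sd)),
                    config$n_sites, nt)
    eps <- matrix(stats::rnorm(n * nt), n, nt)
    vals <- outer(rep(1, n), mu) +
      outer(male, b_sex) + outer(age_c, b_age) + outer(age_c^2, b_age2) +
      gamma[site_idx, , drop = FALSE] +
      delta[site_idx, , drop = FALSE] * sweep(eps, 2, sigma, "*")
    list(vals = vals, sigma = sigma, gamma = gamma, delta = delta,
         b_age = b_age, shift = shift_sd * sigma)
  }

  fa_sim <- draw_modality(-1, c(0.35, 0.60), 0.02, config$fa_shift_sd)
  md_sim <- draw_modality(+1, c(0.70, 0.90), 0.03, config$md_shift_sd)

  # per-patient injury propensity: Beta with mean injury_fraction and a
  # long right tail, mirroring the clinical mix of mostly mild and some
  # severe injuries; tracts are then injured independently at that rate
  f <- config$injury_fraction
  propensity <- rep(0, n)
  if (f >= 1) {
    propensity[is_pat] <- 1
  } else if (f > 0) {
    a <- 1.2
    propensity[is_pat] <- stats::rbeta(np, a, a * (1 - f) / f)
  }
  injured <- lapply(seq_len(n), function(i) {
    if (!is_pat[i] || propensity[i] == 0) return(integer(0))
    which(stats::runif(nt) < propensity[i])
  })
  for (i in seq_len(n)) {
    idx <- injured[[i]]
    if (length(idx) > 0) {
      fa_sim$vals[i, idx] <- fa_sim$vals[i, idx] - fa_sim$shift[idx]
      md_sim$vals[i, idx] <- md_sim$vals[i, idx] + md_sim$shift[idx]
    }
  }
  clamps["fa"] <- sum(fa_sim$vals < 0.001 | fa_sim$vals > 0.999)
  fa_sim$vals <- pmin(pmax(fa_sim$vals, 0.001), 0.999)
  clamps["md"] <- sum(md_sim$vals < 1e-4)
  md_sim$vals <- pmax(md_sim$vals, 1e-4)

  # --- volumes ----------------------------------------------------------
  nv <- length(vol_rois)
  vol_mu <- stats::runif(nv, 3000, 30000)
  head_factor <- pmax(stats::rnorm(n, 1, 0.08), 0.7)
  vol_vals <- outer(head_factor, vol_mu) *
    (1 + 0.05 * matrix(stats::rnorm(n * nv), n, nv))
  clamps["vol"] <- sum(vol_vals <= 0)
  vol_vals <- pmax(vol_vals, 1)
  total_vol <- 1.45e6 * head_factor * (1 + 0.01 * stats::rnorm(n))

  # --- lipids (patients only) ------------------------------------------
  info <- default_lipid_panel(config$n_lipids)
  ch <- lipid_cholesky(info, config$within_class_cor,
                       config$between_class_cor)
  z <- matrix(stats::rnorm(np * config$n_lipids), np) %*% ch
  colnames(z) <- info$lipid

  assoc <- tibble::tibble(lipid = character(0), roi = character(0),
                          modality = character(0), sign = integer(0))
  if (config$n_assoc_pairs > 0 && config$assoc_strength > 0) {
    k <- min(config$n_assoc_pairs, config$n_lipids)
    lips <- sample(info$lipid, k)
    mods <- rep_len(c("FA", "MD"), k)
    rois <- sample(tracts, k, replace = TRUE)
    sgn <- ifelse(mods == "FA", 1L, -1L)
    rho <- config$assoc_strength
    for (j in seq_len(k)) {
      metric <- if (mods[j] == "FA") fa_sim$vals else md_sim$vals
      w <- as.numeric(scale(metric[is_pat, match(rois[j], tracts)]))
      jj <- match(lips[j], info$lipid)
      z[, jj] <- sgn[j] * rho * w + sqrt(1 - rho^2) * z[, jj]
    }
    assoc <- tibble::tibble(lipid = lips, roi = rois, modality = mods,
                            sign = sgn)
  }

  mri_lipids <- character(0)
  eta <- rep(stats::qlogis(0.6), np)
  if (config$n_mri_lipids > 0 && config$mri_effect != 0) {
    mri_lipids <- sample(setdiff(info$lipid, assoc$lipid),
                         min(config$n_mri_lipids,
                             config$n_lipids - nrow(assoc)))
    eta <- eta + config$mri_effect *
      rowSums(z[, mri_lipids, drop = FALSE])
  }
  mri_pos <- stats::runif(np) < stats::plogis(eta)
  subjects$mri_status[is_pat] <- ifelse(mri_pos, "positive", "negative")
  ct_pos <- (mri_pos & stats::runif(np) < 0.83) |
    (!mri_pos & stats::runif(np) < 0.05)
  subjects$ct_status[is_pat] <- ifelse(ct_pos, "positive", "negative")
  if (config$n_mri_missing > 0) {
    drop_idx <- sample(np, min(config$n_mri_missing, np))
    subjects$mri_status[which(is_pat)[drop_idx]] <- NA_character_
  }

  mu_lip <- stats::runif(config$n_lipids, log(0.5), log(50))
  conc <- exp(sweep(0.5 * z, 2, mu_lip, "+"))

  pat_ids <- subjects$subject_id[is_pat]
  as_tb <- function(vals, cols, ids) {
    colnames(vals) <- cols
    dplyr::bind_cols(tibble::tibble(subject_id = ids),
                     tibble::as_tibble(as.data.frame(vals)))
  }
  vol_tb <- as_tb(cbind(vol_vals, total_vol),
                  c(vol_rois, total_volume_col()), subjects$subject_id)

  cohort <- new_cohort(
    subjects = subjects,
    lipid_raw = as_tb(conc, info$lipid, pat_ids),
    lipid_info = info,
    fa = as_tb(fa_sim$vals, tracts, subjects$subject_id),
    md = as_tb(md_sim$vals, tracts, subjects$subject_id),
    vol = vol_tb,
    provenance = list(
      generator = "lipidtract::simulate_cohort",
      seed = config$seed,
      clamped = as.list(clamps)
    )
  )

  site_effects <- dplyr::bind_rows(
    tidyr::expand_grid(site = sites, roi = tracts) |>
      dplyr::mutate(modality = "FA",
                    gamma = as.vector(t(fa_sim$gamma)),
                    delta = as.vector(t(fa_sim$delta))),
    tidyr::expand_grid(site = sites, roi = tracts) |>
      dplyr::mutate(modality = "MD",
                    gamma = as.vector(t(md_sim$gamma)),
                    delta = as.vector(t(md_sim$delta)))
  )

  truth <- list(
    injured_rois = stats::setNames(
      lapply(which(is_pat), function(i) tracts[injured[[i]]]), pat_ids),
    associated_pairs = assoc,
    mri_informative_lipids = mri_lipids,
    site_effects = site_effects,
    baseline = list(
      fa_age_slope = fa_sim$b_age, md_age_slope = md_sim$b_age,
      fa_sigma = fa_sim$sigma, md_sigma = md_sim$sigma
    ),
    config = config
  )
  list(cohort = cohort, truth = truth)
}

#' Generate a null cohort (no planted effects)
#'
#' As [simulate_cohort()] but with no injuries, no lipid-tract couplings and
#' no lipid effect on MRI status; scanner effects are retained so the
#' harmonization stage still has work to do. The returned ground-truth sets
#' are empty.
#'
#' @param config A [sim_config()]; its effect parameters are overridden.
#' @return As [simulate_cohort()].
#' @export
simulate_null_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  config$injury_fraction <- 0
  config$assoc_strength <- 0
  config$n_assoc_pairs <- 0L
  config$mri_effect <- 0
  simulate_cohort(config)
}
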