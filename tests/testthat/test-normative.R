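test_that("noise-free baselines are recovered exactly", {
  co <- noise_free_metrics(small_cohort(n_patients = 5, n_controls = 40,
                                        seed = 51)$cohort)
  models <- fit_normative(co)
  expect_lt(max(models$sigma), 1e-10)
  fa1 <- models[models$modality == "FA" & models$roi == jhu_tracts()$roi[1], ]
  # planted function: 0.4 + 0.002*i - 0.002*(age-45) + 5e-5*(age-45)^2 + 0.01*male
  expect_equal(fa1$b_sex, 0.01, tolerance = 1e-8)
  expect_equal(fa1$b_age2, 5e-5, tolerance = 1e-8)
  expect_equal(fa1$b_age, -0.002 - 2 * 45 * 5e-5, tolerance = 1e-8)
})

test_that("control coefficients are recovered within sampling error", {
  sim <- simulate_cohort(sim_config(
    n_patients = 5, n_controls = 500, n_sites = 2,
    site_additive_sd = 0, site_multiplicative_sd = 0, seed = 52
  ))
  models <- fit_normative(sim$cohort)
  fa <- models[models$modality == "FA", ]
  # age slope at the centre of the age grid: d/dage (b_age + 2*b_age2*age)
  est_slope <- fa$b_age + 2 * fa$b_age2 * 45
  true_slope <- sim$truth$baseline$fa_age_slope
  se <- fa$sigma / (sd(sim$cohort$subjects$age) * sqrt(fa$n))
  expect_gte(mean(abs(est_slope - true_slope) < 3 * se), 0.9)
  expect_equal(fa$sigma, sim$truth$baseline$fa_sigma, tolerance = 0.15)
})

test_that("fitting is invariant to subject order and guards its preconditions", {
  sim <- small_cohort(seed = 53)
  co <- sim$cohort
  perm <- sample(nrow(co$subjects))
  co2 <- new_cohort(co$subjects[perm, ], co$lipid_raw, co$lipid_info,
                    co$fa[rev(seq_len(nrow(co$fa))), ], co$md, co$vol)
  expect_equal(fit_normative(co2), fit_normative(co))

  few <- simulate_cohort(sim_config(n_patients = 20, n_controls = 5,
                                    n_sites = 2, seed = 54))
  expect_error(fit_normative(few$cohort), "at least 10 controls")

  one_sex <- co
  one_sex$subjects$sex <- "M"
  expect_error(fit_normative(one_sex), "rank-deficient")
})

test_that("burden arithmetic matches the joint FA-and-MD flag definition", {
  sim <- small_cohort(n_patients = 4, n_controls = 40, seed = 55)
  co <- sim$cohort
  models <- fit_normative(co)
  # pin every patient exactly to its covariate-adjusted baseline
  predict_mu <- function(modality, subjects) {
    m <- models[models$modality == modality, ]
    X <- cbind(1, subjects$sex == "M", subjects$age, subjects$age^2)
    mu <- X %*% t(as.matrix(m[, c("intercept", "b_sex", "b_age", "b_age2")]))
    colnames(mu) <- m$roi
    mu
  }
  pats <- co$subjects[co$subjects$group == "patient", ]
  rows <- match(pats$subject_id, co$fa$subject_id)
  tracts <- jhu_tracts()$roi
  co$fa[rows, tracts] <- tibble::as_tibble(as.data.frame(predict_mu("FA", pats)))
  co$md[rows, tracts] <- tibble::as_tibble(as.data.frame(predict_mu("MD", pats)))
  pr0 <- flag_abnormal(co, models)
  expect_true(all(pr0$burden$burden == 0))

  # displace both metrics by 5 residual SDs in 12 of 48 tracts -> burden
  # 25.0; FA-only displacement in 6 more tracts must not count
  pid <- pats$subject_id[1]
  row <- which(co$fa$subject_id == pid)
  s_fa <- models$sigma[models$modality == "FA"][match(tracts, models$roi[models$modality == "FA"])]
  s_md <- models$sigma[models$modality == "MD"][match(tracts, models$roi[models$modality == "MD"])]
  co$fa[row, tracts[1:12]] <- co$fa[row, tracts[1:12]] - 5 * s_fa[1:12]
  co$md[row, tracts[1:12]] <- co$md[row, tracts[1:12]] + 5 * s_md[1:12]
  co$fa[row, tracts[13:18]] <- co$fa[row, tracts[13:18]] - 5 * s_fa[13:18]
  pr <- flag_abnormal(co, models)
  b <- pr$burden[pr$burden$subject_id == pid, ]
  expect_equal(b$n_abnormal, 12L)
  expect_equal(b$burden, 25.0)
  flags <- pr$flags[pr$flags$subject_id == pid, ]
  expect_true(all(flags$fa_out[match(tracts[13:18], flags$roi)]))
  expect_false(any(flags$abnormal[match(tracts[13:18], flags$roi)]))
})

test_that("tracts with missing values drop out of numerator and denominator", {
  sim <- small_cohort(seed = 56)
  co <- harmonize(log_standardize(sim$cohort))
  pid <- patient_ids(co)[1]
  co$fa[co$fa$subject_id == pid, jhu_tracts()$roi[1]] <- NA_real_
  pr <- flag_abnormal(co, fit_normative(co))
  b <- pr$burden[pr$burden$subject_id == pid, ]
  expect_equal(b$n_roi, 47L)
  others <- pr$burden[pr$burden$subject_id != pid, ]
  expect_true(all(others$n_roi == 48L))
})

test_that("KS group comparison handles identical and disjoint samples", {
  sim <- simulate_cohort(sim_config(n_patients = 6, n_controls = 6,
                                    n_sites = 2, seed = 57))
  co <- sim$cohort
  t1 <- jhu_tracts()$roi[1]
  t2 <- jhu_tracts()$roi[2]
  pats <- co$subjects$group == "patient"
  # identical samples on tract 1
  vals <- seq(0.3, 0.55, length.out = 6)
  co$fa[[t1]][!pats] <- vals
  co$fa[[t1]][pats] <- vals
  # disjoint supports on tract 2
  co$fa[[t2]][pats] <- c(0.1, 0.12, 0.14, 0.16, 0.18, 0.2)
  co$fa[[t2]][!pats] <- c(0.4, 0.42, 0.44, 0.46, 0.48, 0.5)
  res <- ks_group_comparison(co, "FA")
  expect_equal(res$D[res$roi == t1], 0)
  expect_equal(res$p[res$roi == t1], 1)
  expect_equal(res$D[res$roi == t2], 1)
  expect_true(all(res$q >= res$p - 1e-15))
})

test_that("a shifted tract is detected while the false-positive rate stays controlled", {
  sim <- simulate_null_cohort(sim_config(n_patients = 100, n_controls = 100,
                                         n_sites = 2, site_additive_sd = 0,
                                         seed = 58))
  co <- sim$cohort
  t1 <- jhu_tracts()$roi[5]
  pats <- co$subjects$group == "patient"
  co$fa[[t1]][pats] <- co$fa[[t1]][pats] + 3 * sd(co$fa[[t1]][!pats])
  res <- ks_group_comparison(co, "FA")
  expect_true(res$significant[res$roi == t1])
  expect_lte(mean(res$significant[res$roi != t1]), 0.05 + 0.07)
})
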