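test_that("correlations match a first-principles oracle and flag degenerate input", {
  sim <- small_cohort(n_patients = 10, n_controls = 10, seed = 61)
  co <- log_standardize(sim$cohort)
  res <- lipid_roi_correlate(co, "FA")
  z <- lipid_matrix(co)
  fa <- metric_matrix(co, "FA", group = "patient")
  set.seed(61)
  for (i in sample(nrow(res$r), 4)) {
    for (j in sample(ncol(res$r), 4)) {
      expect_equal(res$r[i, j], oracle_pearson(z[, i], fa[rownames(z), j]),
                   tolerance = 1e-12)
    }
  }
  # a lipid duplicated into an ROI column correlates perfectly
  co2 <- co
  t1 <- jhu_tracts()$roi[1]
  pats <- co2$subjects$group == "patient"
  co2$fa[[t1]][pats] <- 0.4 + 0.01 * (z[, 1] - min(z[, 1]) + 0.1)
  res2 <- lipid_roi_correlate(co2, "FA")
  expect_equal(unname(res2$r[1, t1]), 1, tolerance = 1e-12)
  expect_lt(res2$p[1, t1], 1e-12)

  co3 <- co
  co3$fa[[t1]][pats] <- 0.5
  expect_error(lipid_roi_correlate(co3, "FA"), t1)
})

test_that("Holm adjustment reproduces hand-computed step-down values", {
  p <- c(0.01, 0.02, 0.03)
  expect_equal(oracle_holm(p), c(0.03, 0.04, 0.04))

  res <- structure(
    list(modality = "FA",
         r = matrix(0.1, 1, 3, dimnames = list("l1", c("a", "b", "c"))),
         p = matrix(p, 1, 3, dimnames = list("l1", c("a", "b", "c"))),
         n = matrix(20, 1, 3)),
    class = "correlation_result"
  )
  out <- holm_filter(res, alpha = 0.05)
  expect_equal(as.vector(out$p_holm), c(0.03, 0.04, 0.04))
  expect_true(all(out$mask))

  # all-ones and the single-test identity
  res$p[] <- 1
  expect_false(any(holm_filter(res)$mask))
  res1 <- res
  res1$r <- res1$r[, 1, drop = FALSE]
  res1$p <- matrix(0.04, 1, 1, dimnames = list("l1", "a"))
  out1 <- holm_filter(res1)
  expect_equal(as.vector(out1$p_holm), 0.04)
})

test_that("Holm mask is a subset of the raw mask and adjusted p never smaller", {
  sim <- small_cohort(n_patients = 30, n_controls = 10, n_lipids = 30,
                      seed = 62, assoc_strength = 0.8, n_assoc_pairs = 10)
  co <- log_standardize(sim$cohort)
  res <- holm_filter(lipid_roi_correlate(co, "FA"))
  expect_true(all(res$p_holm >= res$p - 1e-15))
  expect_true(all(res$p[res$mask] < res$alpha))
})

test_that("frequency tables follow the k/N arithmetic with deterministic ranking", {
  mask <- matrix(FALSE, 4, 48,
                 dimnames = list(c("b_lip", "a_lip", "d_lip", "c_lip"),
                                 jhu_tracts()$roi))
  mask["b_lip", 1:23] <- TRUE
  mask["a_lip", 1:23] <- TRUE
  mask["d_lip", 1:5] <- TRUE
  res <- structure(
    list(modality = "FA", r = mask * 0.5, p = 1 - mask,
         p_holm = 1 - mask, mask = mask, alpha = 0.05),
    class = "correlation_result"
  )
  ft <- frequency_table(res)
  expect_equal(ft$lipid$lipid, c("a_lip", "b_lip", "d_lip", "c_lip"))
  expect_equal(ft$lipid$k, c(23L, 23L, 5L, 0L))
  expect_equal(round(ft$lipid$freq[1], 3), 0.479)
  expect_equal(ft$lipid$freq * 48, ft$lipid$k)  # f * N is integral
  expect_equal(ft$roi$k[ft$roi$roi == jhu_tracts()$roi[1]], 3L)

  # empty mask
  res$mask[] <- FALSE
  ft0 <- frequency_table(res)
  expect_true(all(ft0$lipid$freq == 0))
})

test_that("sign summaries average significant correlations and keep gaps missing", {
  r <- matrix(c(0.3, 0.1, -0.2, 0.5), 2, 2,
              dimnames = list(c("l1", "l2"), c("roi_a", "roi_b")))
  mask <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2,
                 dimnames = dimnames(r))
  res <- structure(list(modality = "FA", r = r, p = r * 0, p_holm = r * 0,
                        mask = mask, alpha = 0.05),
                   class = "correlation_result")
  ss <- roi_sign_summary(res)
  expect_equal(ss$mean_r[ss$roi == "roi_a"], 0.2)
  expect_equal(ss$sign[ss$roi == "roi_a"], "positive")
  expect_true(is.na(ss$mean_r[ss$roi == "roi_b"]))
  expect_true(is.na(ss$sign[ss$roi == "roi_b"]))
})

test_that("planted FA couplings yield positive tract means and MD negative", {
  sim <- simulate_cohort(sim_config(
    n_patients = 103, n_controls = 20, n_sites = 2, assoc_strength = 0.6,
    n_assoc_pairs = 20, seed = 63
  ))
  co <- log_standardize(sim$cohort)
  pairs <- sim$truth$associated_pairs
  for (m in c("FA", "MD")) {
    res <- holm_filter(lipid_roi_correlate(co, m))
    ss <- roi_sign_summary(res)
    hit <- ss[ss$roi %in% pairs$roi[pairs$modality == m] & ss$n_sig > 0, ]
    expect_gt(nrow(hit), 0)
    if (m == "FA") expect_true(all(hit$mean_r > 0))
    if (m == "MD") expect_true(all(hit$mean_r < 0))
  }
})

test_that("class-injury correlations detect a planted SM-burden link", {
  sim <- simulate_cohort(sim_config(n_patients = 60, n_controls = 40,
                                    n_sites = 2, injury_fraction = 0.3,
                                    seed = 64))
  co <- harmonize(log_standardize(sim$cohort))
  profiles <- flag_abnormal(co, fit_normative(co))
  # plant: patients with more abnormal tracts have lower SM concentrations
  nb <- profiles$burden
  scale_factor <- exp(-0.3 * nb$n_abnormal[match(patient_ids(co),
                                                 nb$subject_id)])
  sm <- co$lipid_info$lipid[co$lipid_info$class == "SM"]
  co$lipid_raw[sm] <- co$lipid_raw[sm] * scale_factor
  cim <- class_injury_correlation(co, profiles)
  tb <- tibble::as_tibble(cim)
  expect_lt(mean(tb$r[tb$class == "SM"], na.rm = TRUE), -0.1)
  # SM is the most negative class by a clear margin
  class_means <- tapply(tb$r, tb$class, mean, na.rm = TRUE)
  expect_equal(names(which.min(class_means)), "SM")
  # a tract abnormal in no patient is missing
  none <- profiles$flags |>
    dplyr::group_by(roi) |>
    dplyr::summarise(any = any(abnormal)) |>
    dplyr::filter(!any)
  if (nrow(none) > 0) {
    expect_true(all(is.na(tb$r[tb$roi %in% none$roi])))
  }
})

test_that("class-injury correlations are near zero without a planted link", {
  sim <- simulate_cohort(sim_config(n_patients = 400, n_controls = 60,
                                    n_sites = 2, injury_fraction = 0.3,
                                    n_assoc_pairs = 0, mri_effect = 0,
                                    seed = 65))
  co <- harmonize(log_standardize(sim$cohort))
  profiles <- flag_abnormal(co, fit_normative(co))
  tb <- tibble::as_tibble(class_injury_correlation(co, profiles))
  expect_lt(max(abs(tb$r), na.rm = TRUE), 0.25)
  expect_lt(abs(mean(tb$r, na.rm = TRUE)), 0.05)
})
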