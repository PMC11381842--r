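test_that("harmonization refuses degenerate site structure", {
  sim <- small_cohort(seed = 41)
  co <- sim$cohort
  co$subjects$site <- "site01"
  expect_error(combat_fit(co, "FA"), "at least 2 sites")

  co2 <- sim$cohort
  ctrl_idx <- which(co2$subjects$group == "control")
  co2$subjects$site[ctrl_idx[1:2]] <- "site_tiny"
  expect_error(combat_fit(co2, "FA"), "site_tiny")
})

test_that("a planted additive site offset is recovered by the model", {
  sim <- simulate_cohort(sim_config(
    n_patients = 10, n_controls = 600, n_sites = 2,
    site_additive_sd = 0, site_multiplicative_sd = 0, injury_fraction = 0,
    seed = 43
  ))
  co <- sim$cohort
  ctrl <- co$subjects$group == "control"
  siteA <- co$subjects$site == "site01"
  tracts <- setdiff(names(co$fa), "subject_id")
  # plant +0.05 on one site's FA (value scale)
  co$fa[siteA, tracts] <- co$fa[siteA, tracts] + 0.05
  m <- combat_fit(co, "FA", reference = "controls")
  # site-effect contrast on the value scale recovers the planted offset
  contrast <- (m$gamma_star["site01", ] - m$gamma_star["site02", ]) * m$sigma
  expect_true(all(abs(contrast - 0.05) < 0.01))
})

test_that("empirical Bayes shrinks spurious site effects under the null", {
  sim <- simulate_cohort(sim_config(
    n_patients = 10, n_controls = 120, n_sites = 3,
    site_additive_sd = 0, site_multiplicative_sd = 0, injury_fraction = 0,
    seed = 44
  ))
  m <- combat_fit(sim$cohort, "FA")
  # with no planted effects, shrunken gamma* stays below the per-site
  # standard error of a site mean (in standardized units, about 1/sqrt(n_s))
  se <- 1 / sqrt(min(m$n_per_site))
  expect_lt(mean(abs(m$gamma_star)), se)
  expect_lt(mean(abs(m$gamma_star)), mean(abs(m$gamma_hat)))
})

test_that("harmonization removes planted site effects and is nearly idempotent", {
  sim <- simulate_cohort(sim_config(
    n_patients = 20, n_controls = 600, n_sites = 3,
    site_additive_sd = 1.0, site_multiplicative_sd = 0.3,
    injury_fraction = 0, seed = 45
  ))
  co <- sim$cohort
  ctrl <- co$subjects[co$subjects$group == "control", ]
  spread <- function(cohort) {
    fa <- metric_matrix(cohort, "FA")[ctrl$subject_id, ]
    mean(apply(fa, 2, function(v) {
      mu <- tapply(v, ctrl$site, mean)
      max(mu) - min(mu)
    }))
  }
  before <- spread(co)
  co_h <- combat_apply(co, combat_fit(co, "FA"))
  after <- spread(co_h)
  expect_lt(after, 0.1 * before)
  expect_true(attr(co_h, "harmonized")[["fa"]])

  # second pass changes values far less than the first
  co_hh <- combat_apply(co_h, combat_fit(co_h, "FA"))
  d1 <- mean(abs(metric_matrix(co_h, "FA") - metric_matrix(co, "FA")))
  d2 <- mean(abs(metric_matrix(co_hh, "FA") - metric_matrix(co_h, "FA")))
  expect_lt(d2, 0.1 * d1)
})

test_that("harmonization preserves covariate effects and within-site ranks", {
  sim <- simulate_cohort(sim_config(
    n_patients = 20, n_controls = 450, n_sites = 3,
    site_additive_sd = 1.0, injury_fraction = 0, seed = 46
  ))
  co_h <- combat_apply(sim$cohort, combat_fit(sim$cohort, "FA"))
  ctrl <- co_h$subjects[co_h$subjects$group == "control", ]
  fa <- metric_matrix(co_h, "FA")[ctrl$subject_id, ]
  slope_true <- sim$truth$baseline$fa_age_slope
  covered <- vapply(seq_len(ncol(fa)), function(v) {
    fit <- stats::lm(fa[, v] ~ male + age + age2,
                     data = data.frame(male = ctrl$sex == "M",
                                       age = ctrl$age - 45,
                                       age2 = (ctrl$age - 45)^2))
    ci <- stats::confint(fit, "age", level = 0.99)
    ci[1] <= slope_true[v] && slope_true[v] <= ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.9)

  # monotone per (site, ROI) on the covariate-adjusted residual scale:
  # the location/scale adjustment rescales residuals, so residual ranks
  # within a site are exactly preserved
  m <- combat_fit(sim$cohort, "FA")
  resid_of <- function(cohort) {
    y <- metric_matrix(cohort, "FA")[ctrl$subject_id, ]
    a <- ctrl$age - m$age_center
    X <- cbind(as.numeric(ctrl$sex == "M"), a, a^2)
    y - outer(rep(1, nrow(y)), m$alpha) - X %*% m$beta
  }
  raw_res <- resid_of(sim$cohort)
  h_res <- resid_of(co_h)
  s1 <- ctrl$site == ctrl$site[1]
  expect_equal(rank(h_res[s1, 3]), rank(raw_res[s1, 3]))
})

test_that("with no site effects harmonization is close to the identity", {
  sim <- simulate_cohort(sim_config(
    n_patients = 20, n_controls = 200, n_sites = 3,
    site_additive_sd = 0, site_multiplicative_sd = 0,
    injury_fraction = 0, seed = 47
  ))
  co <- sim$cohort
  co_h <- combat_apply(co, combat_fit(co, "FA"))
  change <- abs(metric_matrix(co_h, "FA") - metric_matrix(co, "FA"))
  rel <- sweep(change, 2, sim$truth$baseline$fa_sigma, "/")
  expect_lt(mean(rel), 0.5)
})

test_that("the estimation-on-all mode reproduces the reference ComBat", {
  skip_if_not_installed("sva")
  sim <- simulate_cohort(sim_config(n_patients = 40, n_controls = 60,
                                    n_sites = 3, seed = 48))
  co <- sim$cohort
  mine <- t(metric_matrix(combat_apply(co, combat_fit(co, "FA", "all")), "FA"))
  sub <- co$subjects
  mod <- stats::model.matrix(~ sex + age + I(age^2), data = sub)
  ref <- suppressMessages(
    sva::ComBat(dat = t(metric_matrix(co, "FA")), batch = sub$site,
                mod = mod)
  )
  expect_equal(mine, ref, tolerance = 1e-8)
})

test_that("applying a model to an unknown site is a hard error", {
  sim <- small_cohort(seed = 49)
  m <- combat_fit(sim$cohort, "FA")
  co <- sim$cohort
  co$subjects$site[1] <- "site_new"
  expect_error(combat_apply(co, m), "site_new")
})
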