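# small cohorts for fast unit tests; all fixtures are generated in code
small_cohort <- function(n_patients = 20, n_controls = 24, n_sites = 2,
                         n_lipids = 14, seed = 42, ...) {
  simulate_cohort(sim_config(
    n_patients = n_patients, n_controls = n_controls, n_sites = n_sites,
    n_lipids = n_lipids, seed = seed, ...
  ))
}

# deterministic FA/MD as an exact function of age and sex (no noise):
# baseline 0.5 - 0.002*(age-45) + 0.00005*(age-45)^2 + 0.01*male, shifted
# per ROI so tracts differ
noise_free_metrics <- function(cohort) {
  sub <- cohort$subjects
  a <- sub$age - 45
  male <- as.numeric(sub$sex == "M")
  tracts <- setdiff(names(cohort$fa), "subject_id")
  for (i in seq_along(tracts)) {
    mu <- 0.4 + 0.002 * i - 0.002 * a + 5e-5 * a^2 + 0.01 * male
    cohort$fa[[tracts[i]]] <- mu
    cohort$md[[tracts[i]]] <- 0.8 + 0.001 * i + 0.001 * a +
      2e-5 * a^2 - 0.005 * male
  }
  cohort
}

# independent brute-force Pearson correlation (loops and first principles)
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2)
  syy <- sum((y - my)^2)
  sxy / sqrt(sxx * syy)
}

# independent Holm step-down adjustment from its definition
oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, min(1, (m - i + 1) * p[o[i]]))
    adj[o[i]] <- running
  }
  adj
}

# independent two-sample KS statistic via the ECDF definition
oracle_ks_d <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  fx <- vapply(grid, function(g) mean(x <= g), numeric(1))
  fy <- vapply(grid, function(g) mean(y <= g), numeric(1))
  max(abs(fx - fy))
}
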