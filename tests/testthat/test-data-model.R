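test_that("log standardization matches the analytic example and errors on degenerate input", {
  sim <- small_cohort(n_patients = 3, n_controls = 4, seed = 2)
  co <- sim$cohort
  lip <- setdiff(names(co$lipid_raw), "subject_id")
  co$lipid_raw[[lip[1]]] <- c(1, exp(1), exp(2))
  co2 <- log_standardize(co)
  expect_equal(co2$lipid_processed[[lip[1]]], c(-1, 0, 1), tolerance = 1e-12)
  # raw table untouched
  expect_equal(co2$lipid_raw[[lip[1]]], c(1, exp(1), exp(2)))

  co$lipid_raw[[lip[2]]] <- c(5, 5, 5)
  expect_error(log_standardize(co), lip[2])

  co$lipid_raw[[lip[2]]] <- c(5, 5, 6)
  co$lipid_raw[[lip[3]]][1] <- -1
  expect_error(validate_cohort(co), "non-positive concentration")
})

test_that("processed columns have mean 0 and unit sample SD", {
  co <- log_standardize(small_cohort(n_patients = 100, n_controls = 10,
                                     seed = 5)$cohort)
  z <- lipid_matrix(co)
  expect_lt(max(abs(colMeans(z))), 1e-10)
  expect_lt(max(abs(apply(z, 2, sd) - 1)), 1e-10)
})

test_that("standardization is invertible back to raw concentrations", {
  co <- log_standardize(small_cohort(seed = 8)$cohort)
  raw <- lipid_matrix(co, processed = FALSE)
  z <- lipid_matrix(co)
  lraw <- log(raw)
  mu <- colMeans(lraw)
  s <- apply(lraw, 2, sd)
  rebuilt <- exp(sweep(sweep(z, 2, s, "*"), 2, mu, "+"))
  expect_equal(rebuilt, raw, tolerance = 1e-10)
})

test_that("cohort validation rejects constructed invariant violations", {
  base <- small_cohort(seed = 11)$cohort
  break_and_check <- list(
    list(msg = "duplicate subject_id", f = function(co) {
      co$subjects$subject_id[2] <- co$subjects$subject_id[1]
      co
    }),
    list(msg = "inclusion", f = function(co) {
      co$subjects$age[1] <- 6
      co
    }),
    list(msg = "sex", f = function(co) {
      co$subjects$sex[1] <- "X"
      co
    }),
    list(msg = "registered ROI set", f = function(co) {
      names(co$fa)[2] <- "not_a_tract"
      co
    }),
    list(msg = "FA values", f = function(co) {
      co$fa[[2]][1] <- 1.2
      co
    }),
    list(msg = "MD values", f = function(co) {
      co$md[[2]][1] <- -0.1
      co
    }),
    list(msg = "patients without lipid data", f = function(co) {
      co$lipid_raw <- co$lipid_raw[-1, ]
      co
    })
  )
  for (case in break_and_check) {
    expect_error(validate_cohort(case$f(base)), case$msg)
  }
  # under-18 adult-cohort rule warns rather than errors
  co <- base
  co$subjects$age[1] <- 16
  expect_warning(validate_cohort(co), "18")
})

test_that("a cohort round-trips through disk exactly", {
  co <- log_standardize(small_cohort(seed = 21)$cohort)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  co2 <- read_cohort_dir(dir)
  expect_equal(co2$subjects, co$subjects)
  expect_equal(co2$lipid_info, co$lipid_info)
  for (tb in c("lipid_raw", "lipid_processed", "fa", "md", "vol")) {
    expect_equal(as.data.frame(co2[[tb]]), as.data.frame(co[[tb]]),
                 tolerance = 1e-12)
  }
  expect_equal(attr(co2, "harmonized"), attr(co, "harmonized"))
  # flags survive the round trip for a processed cohort too
  co_h <- harmonize(co)
  write_cohort(co_h, dir)
  co_h2 <- read_cohort_dir(dir)
  expect_true(attr(co_h2, "vol_normalized"))
  expect_equal(as.data.frame(co_h2$vol), as.data.frame(co_h$vol),
               tolerance = 1e-12)
})

test_that("reading rejects corrupted files with a clear message", {
  co <- small_cohort(seed = 22)$cohort
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  meta <- readr::read_csv(file.path(dir, "meta.csv"), show_col_types = FALSE)
  meta$subject_id[2] <- meta$subject_id[1]
  readr::write_csv(meta, file.path(dir, "meta.csv"))
  expect_error(read_cohort_dir(dir), "duplicate subject_id")
  expect_error(read_cohort(
    meta_path = file.path(dir, "nope.csv"),
    lipid_path = file.path(dir, "lipids.csv"),
    lipid_info_path = file.path(dir, "lipid_info.csv"),
    roi_paths = list(fa = file.path(dir, "fa.csv"),
                     md = file.path(dir, "md.csv"),
                     vol = file.path(dir, "vol.csv"))
  ), "not found")
})

test_that("result files are idempotent under write-read-write", {
  sim <- small_cohort(seed = 31)
  co <- harmonize(log_standardize(sim$cohort))
  profiles <- flag_abnormal(co, fit_normative(co))
  attr(profiles, "seed") <- 31L
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "burden.csv")
  p2 <- file.path(dir, "burden2.csv")
  write_results(profiles, p1)
  tb <- read_results(p1)
  expect_equal(attr(tb, "lt_meta")$seed, "31")
  write_results(tb, p2)
  expect_identical(readLines(p1), readLines(p2))
  # one row per patient with a burden column
  expect_setequal(tb$subject_id, patient_ids(co))
  expect_true(all(tb$burden >= 0 & tb$burden <= 100))
})

test_that("volume normalization follows the arithmetic and is scale invariant", {
  vol_tb <- tibble::tibble(
    subject_id = c("a", "b"),
    region_x = c(150, 300),
    total_brain_volume = c(1500, 1500)
  )
  out <- normalize_volumes(vol_tb)
  expect_equal(out$region_x, c(0.1, 0.2))
  expect_false("total_brain_volume" %in% names(out))

  doubled <- vol_tb
  doubled$region_x <- doubled$region_x * 2
  doubled$total_brain_volume <- doubled$total_brain_volume * 2
  expect_equal(normalize_volumes(doubled)$region_x, out$region_x)

  vol_tb$total_brain_volume[1] <- 0
  expect_error(normalize_volumes(vol_tb), "total brain volume")

  # cohort-level: every normalized value equals the hand quotient
  co <- small_cohort(seed = 33)$cohort
  raw <- co$vol
  out_co <- normalize_volumes(co)
  rois <- setdiff(names(out_co$vol), "subject_id")
  expect_equal(as.matrix(out_co$vol[, rois]),
               as.matrix(raw[, rois]) / raw$total_brain_volume,
               tolerance = 1e-12)
})
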