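#' Pipeline configuration
#'
#' Bundles the settings for [run_pipeline()]: exactly one data source (a
#' directory of cohort files, or a [sim_config()] to simulate), the output
#' directory, stage toggles, significance levels and the master seed. The
#' master seed deterministically derives per-stage substream seeds so stages
#' are reproducible in isolation.
#'
#' @param data_dir Directory readable by [read_cohort_dir()], or `NULL` to
#'   simulate.
#' @param simulate A [sim_config()], or `NULL` to read files. Exactly one of
#'   `data_dir`/`simulate` must be given.
#' @param out_dir Output directory for all artifacts.
#' @param stages Character vector of stages to run, a subset of
#'   `c("burden", "correlation", "classification", "network")`;
#'   preprocessing and harmonization always run.
#' @param alpha Significance level for Holm-filtered correlations and
#'   network edges.
#' @param n_repeats Repeated holdout splits per classifier cell.
#' @param seed Master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(data_dir = NULL, simulate = sim_config(),
                            out_dir = tempfile("lipidtract_run_"),
                            stages = c("burden", "correlation",
                                       "classification", "network"),
                            alpha = 0.05, n_repeats = 100, seed = 1) {
  if (is.null(data_dir) == is.null(simulate)) {
    stop("give exactly one data source: data_dir or simulate", call. = FALSE)
  }
  stages <- match.arg(stages, several.ok = TRUE)
  structure(
    list(data_dir = data_dir, simulate = simulate, out_dir = out_dir,
         stages = stages, alpha = alpha, n_repeats = n_repeats,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

stage_seeds <- function(seed) {
  set.seed(seed)
  stats::setNames(sample.int(2^31 - 1, 4),
                  c("simulate", "classification", "network", "spare"))
}

config_hash <- function(config) {
  # identifies the statistical settings; paths and stage toggles are
  # excluded so artifacts shared between partial runs stay comparable
  flat <- unlist(config[c("alpha", "n_repeats", "seed")])
  if (!is.null(config$simulate)) flat <- c(flat, unlist(config$simulate))
  substr(rlang::hash(paste(names(flat), flat, sep = "=", collapse = ";")),
         1, 12)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order: load or simulate the cohort; log-standardize
#' the lipids; harmonize (controls-anchored ComBat for FA and MD, total-brain
#' -volume normalization for volumes); fit normative baselines, flag
#' abnormal tracts, compute burden of injury and per-tract KS group
#' comparisons; lipid-by-ROI correlations with Holm filtering, frequency
#' tables, sign summaries and the class-by-tract injury matrix; the 8-cell
#' classification grid; and the FA and MD partial-correlation networks.
#' Every artifact is written under `config$out_dir` and listed, with an MD5
#' checksum, in `manifest.json` alongside the resolved configuration.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest as a list. Artifacts on disk.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seeds <- stage_seeds(config$seed)
  hash <- config_hash(config)
  written <- character(0)
  note <- function(...) message("[lipidtract] ", sprintf(...))

  tag <- function(obj) {
    attr(obj, "seed") <- config$seed
    attr(obj, "config_hash") <- hash
    obj
  }
  emit <- function(obj, name) {
    paths <- write_results(tag(obj), file.path(out, name))
    written <<- c(written, if (is.null(paths)) file.path(out, name) else paths)
  }

  # --- data -------------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim_cfg <- config$simulate
    sim_cfg$seed <- seeds[["simulate"]]
    note("simulating cohort (seed %d)", sim_cfg$seed)
    sim <- simulate_cohort(sim_cfg)
    cohort <- sim$cohort
    truth_path <- file.path(out, "ground_truth.json")
    jsonlite::write_json(
      list(injured_rois = sim$truth$injured_rois,
           associated_pairs = sim$truth$associated_pairs,
           mri_informative_lipids = sim$truth$mri_informative_lipids),
      truth_path, auto_unbox = FALSE, pretty = TRUE, digits = NA
    )
    written <- c(written, truth_path)
  } else {
    note("reading cohort from %s", config$data_dir)
    cohort <- read_cohort_dir(config$data_dir)
  }

  # --- preprocess + harmonize (always run) -------------------------------
  note("preprocessing lipids and harmonizing metrics")
  cohort <- log_standardize(cohort)
  cohort <- harmonize(cohort, reference = "controls")
  cohort_dir <- file.path(out, "cohort")
  write_cohort(cohort, cohort_dir)
  written <- c(written, list.files(cohort_dir, full.names = TRUE))

  models <- fit_normative(cohort)
  profiles <- NULL

  if ("burden" %in% config$stages) {
    note("burden of injury and KS group comparisons")
    profiles <- flag_abnormal(cohort, models)
    emit(profiles, "burden.csv")
    emit(tag(profiles$flags), "abnormal_flags.csv")
    for (m in c("FA", "MD")) {
      emit(ks_group_comparison(cohort, m, alpha = config$alpha),
           sprintf("ks_%s.csv", tolower(m)))
    }
  }

  freqs <- list()
  if ("correlation" %in% config$stages) {
    note("lipid-ROI correlations with Holm filtering")
    for (m in c("FA", "MD", "VOL")) {
      cr <- holm_filter(lipid_roi_correlate(cohort, m), alpha = config$alpha)
      ft <- frequency_table(cr, cohort$lipid_info)
      freqs[[m]] <- ft
      emit(cr, sprintf("correlations_%s.csv", tolower(m)))
      emit(ft, sprintf("frequency_%s.csv", tolower(m)))
      ss <- roi_sign_summary(cr)
      ss$r_values <- NULL
      emit(tag(ss), sprintf("roi_signs_%s.csv", tolower(m)))
    }
    if (!is.null(profiles)) {
      emit(tag(tibble::as_tibble(class_injury_correlation(cohort, profiles))),
           "class_injury.csv")
    }
  }

  if ("classification" %in% config$stages) {
    note("classification grid (8 cells x %d repeats)", config$n_repeats)
    grid <- classification_grid(cohort, n_repeats = config$n_repeats,
                                seed = seeds[["classification"]])
    emit(tag(dplyr::select(grid, -"report")), "auc_grid.csv")
  }

  if ("network" %in% config$stages && length(freqs) > 0) {
    note("partial-correlation networks")
    for (m in c("FA", "MD")) {
      top <- suppressWarnings(select_top_lipids(freqs[[m]]))
      if (length(top) < 2) {
        note("skipping %s network: fewer than 2 lipids selected", m)
        next
      }
      g <- build_network(cohort, m, top, alpha = config$alpha)
      emit(g, sprintf("network_%s.csv", tolower(m)))
      gml <- file.path(out, sprintf("network_%s.graphml", tolower(m)))
      write_graphml(g, gml)
      written <- c(written, gml)
    }
  }

  manifest <- list(
    config = list(
      seed = config$seed, alpha = config$alpha,
      n_repeats = config$n_repeats, stages = config$stages,
      source = if (is.null(config$simulate)) "files" else "simulate",
      config_hash = hash,
      simulate = if (!is.null(config$simulate)) {
        unclass(config$simulate)
      }
    ),
    stage_seeds = as.list(seeds),
    artifacts = lapply(sort(unique(written)), function(p) {
      list(file = basename(p),
           relpath = sub(paste0("^", out, "/?"), "", p),
           md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
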