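#' Select the most frequently correlated lipids for the network stage
#'
#' Picks the `n` lipids with the highest counts of Holm-significant
#' correlations (20% of the panel by default, i.e. 40 of 201), restricted to
#' lipids with at least one significant correlation. Ties at the cutoff are
#' broken lexicographically; if fewer than `n` lipids have any significant
#' correlation, all of them are returned with a warning.
#'
#' @param freq A `frequency_table` from [frequency_table()].
#' @param n Number of lipids; default `round(0.2 * n_lipids)`.
#' @return Character vector of selected lipid ids.
#' @export
select_top_lipids <- function(freq, n = NULL) {
  stopifnot(inherits(freq, "frequency_table"))
  tb <- freq$lipid
  if (is.null(n)) n <- round(0.2 * nrow(tb))
  tb <- tb[tb$k > 0, ]
  tb <- dplyr::arrange(tb, dplyr::desc(.data$k), .data$lipid)
  if (nrow(tb) < n) {
    warning("only ", nrow(tb), " lipids have a significant correlation; ",
            "selecting all of them", call. = FALSE)
    return(tb$lipid)
  }
  utils::head(tb$lipid, n)
}

residualize <- function(m, covars) {
  q <- qr(cbind(1, covars))
  if (q$rank < ncol(covars) + 1) {
    stop("collinear covariates in partial-correlation conditioning set",
         call. = FALSE)
  }
  qr.resid(q, m)
}

#' Covariate-controlled partial-correlation network
#'
#' Builds the signed partial-correlation graph over the selected lipids, the
#' 48 white-matter tracts of a diffusion modality, and the four clinical
#' covariates (age, time from injury to blood draw, time from injury to MRI,
#' propofol administration). For every pair of analysis variables
#' (lipid-lipid, lipid-tract, tract-tract) the Pearson correlation of their
#' residuals after regressing out the four covariates is computed, with
#' significance from the t distribution on n - 2 - 4 degrees of freedom.
#' Edges between an analysis variable and a covariate condition on the other
#' three covariates. Only edges with p below `alpha` are retained (no
#' multiplicity adjustment, by design); tracts stay individual nodes tagged
#' with their midline/left/right parcel.
#'
#' @param cohort A harmonized `tbi_cohort` with processed lipids.
#' @param modality `"FA"` or `"MD"`.
#' @param lipids Character vector of lipid ids to include (typically from
#'   [select_top_lipids()]).
#' @param alpha Edge-retention significance level (default 0.05).
#' @return An object of class `partial_corr_graph`: list with `nodes`
#'   (tibble: `node`, `type`, `group`), `edges` (tibble: `from`, `to`,
#'   `partial_r`, `p`, `sign`), `alpha`, `n`, `modality`.
#' @export
build_network <- function(cohort, modality = c("FA", "MD"), lipids,
                          alpha = 0.05) {
  modality <- match.arg(modality)
  stopifnot(inherits(cohort, "tbi_cohort"))
  sub <- cohort$subjects
  pats <- sub[sub$group == "patient", ]
  lip <- lipid_matrix(cohort, processed = TRUE)
  missing_lip <- setdiff(lipids, colnames(lip))
  if (length(missing_lip) > 0) {
    stop("unknown lipid(s): ", paste(missing_lip, collapse = ", "),
         call. = FALSE)
  }
  met <- metric_matrix(cohort, modality, group = "patient")
  ids <- intersect(rownames(lip), rownames(met))
  pats <- pats[match(ids, pats$subject_id), ]
  covars <- cbind(
    age = pats$age,
    time_to_blood_h = pats$time_to_blood_h,
    time_to_scan_h = pats$time_to_scan_h,
    propofol = as.numeric(pats$propofol)
  )
  ok <- stats::complete.cases(covars)
  ids <- ids[ok]
  covars <- covars[ok, , drop = FALSE]
  n <- length(ids)
  k <- ncol(covars)
  if (n <= k + 3) {
    stop("too few patients with complete covariates for partial correlations",
         call. = FALSE)
  }

  vars <- cbind(lip[ids, lipids, drop = FALSE], met[ids, , drop = FALSE])
  tracts <- colnames(met)

  p_from_r <- function(r, df) {
    r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
    2 * stats::pt(-abs(r) * sqrt(df / (1 - r^2)), df = df)
  }

  # analysis-variable pairs, conditioning on all four covariates
  res <- residualize(vars, covars)
  pr <- stats::cor(res)
  df_vv <- n - 2 - k
  pv <- p_from_r(pr, df_vv)
  iu <- which(upper.tri(pr), arr.ind = TRUE)
  edges_vv <- tibble::tibble(
    from = rownames(pr)[iu[, 1]],
    to = colnames(pr)[iu[, 2]],
    partial_r = pr[iu],
    p = pv[iu]
  )

  # variable-covariate pairs, conditioning on the other three covariates
  edges_vc <- purrr::map(seq_len(k), function(j) {
    other <- covars[, -j, drop = FALSE]
    rc <- residualize(cbind(covars[, j], vars), other)
    r_j <- stats::cor(rc[, 1], rc[, -1])
    df_vc <- n - 2 - (k - 1)
    tibble::tibble(
      from = colnames(vars),
      to = colnames(covars)[j],
      partial_r = as.numeric(r_j),
      p = as.numeric(p_from_r(r_j, df_vc))
    )
  }) |>
    dplyr::bind_rows()

  edges <- dplyr::bind_rows(edges_vv, edges_vc) |>
    dplyr::filter(.data$p < alpha) |>
    dplyr::mutate(sign = ifelse(.data$partial_r >= 0, "positive", "negative")) |>
    dplyr::arrange(.data$from, .data$to)

  info <- cohort$lipid_info
  nodes <- dplyr::bind_rows(
    tibble::tibble(node = lipids, type = "lipid",
                   group = info$class[match(lipids, info$lipid)]),
    tibble::tibble(node = tracts, type = "tract",
                   group = parcellate_tracts(tracts)),
    tibble::tibble(node = colnames(covars), type = "covariate",
                   group = "covariate")
  )

  structure(
    list(nodes = nodes, edges = edges, alpha = alpha, n = n,
         modality = modality),
    class = "partial_corr_graph"
  )
}

#' @export
print.partial_corr_graph <- function(x, ...) {
  cat(sprintf("<partial_corr_graph> %s: %d nodes, %d edges at alpha = %g (n = %d)\n",
              x$modality, nrow(x$nodes), nrow(x$edges), x$alpha, x$n))
  invisible(x)
}

#' Convert a partial-correlation graph to igraph
#'
#' @param graph A `partial_corr_graph`.
#' @return An undirected `igraph` object with node attributes `type` and
#'   `group` and edge attributes `partial_r`, `p`, `sign`.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "partial_corr_graph"))
  igraph::graph_from_data_frame(
    d = graph$edges, directed = FALSE,
    vertices = as.data.frame(graph$nodes)
  )
}

#' Write a partial-correlation graph to GraphML
#'
#' @param graph A `partial_corr_graph`.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(as_igraph(graph), path, format = "graphml")
  invisible(path)
}
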