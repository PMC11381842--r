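#' Rank lipids by Welch two-sample t-test
#'
#' Ranks lipids by their ability to separate MRI-positive from MRI-negative
#' patients: a Welch (unequal-variance) two-sample t-test per lipid, sorted
#' by ascending p-value with deterministic lexicographic tie-breaking on the
#' lipid id.
#'
#' @param x Numeric matrix (samples x lipids) of processed lipid values.
#' @param labels Factor or character vector of two classes, one per row of
#'   `x`.
#' @return A tibble `lipid`, `t`, `df`, `p`, `rank`, ordered by rank.
#' @export
welch_rank <- function(x, labels) {
  labels <- as.factor(as.character(labels))
  if (nlevels(labels) != 2) {
    stop("labels must have exactly two classes", call. = FALSE)
  }
  g1 <- labels == levels(labels)[1]
  n1 <- sum(g1)
  n2 <- sum(!g1)
  if (n1 < 2 || n2 < 2) {
    stop("each class needs at least 2 samples", call. = FALSE)
  }
  m1 <- colMeans(x[g1, , drop = FALSE])
  m2 <- colMeans(x[!g1, , drop = FALSE])
  v1 <- apply(x[g1, , drop = FALSE], 2, stats::var)
  v2 <- apply(x[!g1, , drop = FALSE], 2, stats::var)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df = df)
  out <- tibble::tibble(lipid = colnames(x), t = unname(tstat),
                        df = unname(df), p = unname(p)) |>
    dplyr::arrange(.data$p, .data$lipid)
  out$rank <- seq_len(nrow(out))
  out
}

#' Rank lipids by random-forest variable importance
#'
#' Fits a random-forest classifier (500 trees, sqrt(p) candidate features
#' per split, impurity-decrease importance) of the class labels on all
#' lipids and ranks lipids by descending importance, ties broken
#' lexicographically. Deterministic for a fixed seed.
#'
#' @inheritParams welch_rank
#' @param seed Integer seed for the forest.
#' @param num_trees Number of trees (default 500).
#' @return A tibble `lipid`, `importance`, `rank`, ordered by rank.
#' @export
rf_rank <- function(x, labels, seed = 1, num_trees = 500) {
  labels <- as.factor(as.character(labels))
  if (nlevels(labels) != 2) {
    stop("labels must have exactly two classes", call. = FALSE)
  }
  if (min(table(labels)) < 2) {
    stop("each class needs at least 2 samples", call. = FALSE)
  }
  df <- as.data.frame(x)
  # protect against non-syntactic lipid names; restore below
  orig <- colnames(x)
  colnames(df) <- sprintf("V%d", seq_along(orig))
  df$.class <- labels
  fit <- ranger::ranger(
    dependent.variable.name = ".class", data = df,
    num.trees = num_trees, mtry = floor(sqrt(ncol(x))),
    importance = "impurity", seed = seed, num.threads = 1,
    respect.unordered.factors = "order"
  )
  imp <- unname(fit$variable.importance[sprintf("V%d", seq_along(orig))])
  out <- tibble::tibble(lipid = orig, importance = imp) |>
    dplyr::arrange(dplyr::desc(.data$importance), .data$lipid)
  out$rank <- seq_len(nrow(out))
  out
}

#' Intersect the top-k lipids of the two rankings
#'
#' The two-stage filter: the intersection of the Welch top-k and the
#' random-forest top-k lipid sets. An empty intersection falls back, with a
#' warning, to the union of the two top-k sets so downstream models still
#' have features.
#'
#' @param welch_ranked,rf_ranked Tibbles from [welch_rank()] and
#'   [rf_rank()] over the same lipid universe.
#' @param top_k Depth of each ranking to intersect (default 30).
#' @return Character vector of selected lipids (sorted).
#' @export
select_features <- function(welch_ranked, rf_ranked, top_k = 30) {
  if (!setequal(welch_ranked$lipid, rf_ranked$lipid)) {
    stop("rankings cover different lipid universes", call. = FALSE)
  }
  a <- utils::head(welch_ranked$lipid, top_k)
  b <- utils::head(rf_ranked$lipid, top_k)
  sel <- intersect(a, b)
  if (length(sel) == 0) {
    warning("empty top-", top_k,
            " intersection; falling back to the union of both sets",
            call. = FALSE)
    sel <- union(a, b)
  }
  sort(sel)
}

#' Rank-based AUC of a score against binary labels
#'
#' Area under the ROC curve via the Wilcoxon rank-sum identity; ties in the
#' score contribute 1/2.
#'
#' @param score Numeric vector of predicted scores.
#' @param labels Logical or 0/1 vector, `TRUE`/1 = positive.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(score, labels) {
  y <- as.logical(labels)
  n1 <- sum(y)
  n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

classifier_frame <- function(cohort, scope = c("all_patients", "ct_negative")) {
  scope <- match.arg(scope)
  sub <- cohort$subjects
  keep <- sub$group == "patient" & !is.na(sub$mri_status)
  if (scope == "ct_negative") {
    keep <- keep & !is.na(sub$ct_status) & sub$ct_status == "negative"
  }
  ids <- sub$subject_id[keep]
  x <- lipid_matrix(cohort, processed = TRUE)
  ids <- intersect(ids, rownames(x))
  y <- sub$mri_status[match(ids, sub$subject_id)] == "positive"
  list(x = x[ids, , drop = FALSE], y = y, ids = ids)
}

#' Repeated-holdout evaluation of penalized MRI-positivity classifiers
#'
#' Evaluates a penalized logistic regression of MRI positivity on the lipid
#' profile by repeated stratified 70/30 train/test splits. In the
#' `"filtered"` feature mode the two-stage filter (Welch top-k intersected
#' with random-forest top-k) is re-run inside every training split — feature
#' selection never sees the test set; the `"full"` mode uses all lipids. The
#' regularization strength is chosen by 5-fold cross-validation on the
#' training split (`lambda.min`), and the held-out AUC is recorded per
#' repeat.
#'
#' @param cohort A `tbi_cohort` with processed lipids and MRI status.
#' @param penalty `"lasso"` (alpha = 1) or `"ridge"` (alpha = 0).
#' @param features `"filtered"` or `"full"`.
#' @param scope `"all_patients"` or `"ct_negative"`.
#' @param n_repeats Number of repeated splits (default 100).
#' @param train_fraction Training fraction (default 0.7).
#' @param top_k Depth of each filter ranking (default 30).
#' @param seed Master seed; the whole report is deterministic given it.
#' @return An object of class `auc_report`: list with `results` (tibble:
#'   `repeat_id`, `auc`, `n_features`, list-column `features`), `spec`
#'   (settings), `n_subjects`, `n_pos`, `n_neg`.
#' @export
evaluate_classifier <- function(cohort,
                                penalty = c("lasso", "ridge"),
                                features = c("filtered", "full"),
                                scope = c("all_patients", "ct_negative"),
                                n_repeats = 100,
                                train_fraction = 0.7,
                                top_k = 30,
                                seed = 1) {
  penalty <- match.arg(penalty)
  features <- match.arg(features)
  scope <- match.arg(scope)
  stopifnot(train_fraction > 0, train_fraction < 1)
  fr <- classifier_frame(cohort, scope)
  n <- length(fr$y)
  if (n < 10) stop("fewer than 10 subjects in scope", call. = FALSE)
  if (n < 20) warning("fewer than 20 subjects in scope", call. = FALSE)
  if (length(unique(fr$y)) < 2) {
    stop("both MRI classes must be present", call. = FALSE)
  }
  if (round(train_fraction * min(sum(fr$y), sum(!fr$y))) < 2) {
    stop("a class is too small to keep 2 members in every training split",
         call. = FALSE)
  }
  alpha <- if (penalty == "lasso") 1 else 0

  set.seed(seed)
  pos <- which(fr$y)
  neg <- which(!fr$y)
  results <- purrr::map(seq_len(n_repeats), function(rep_i) {
    tr <- c(sample(pos, round(train_fraction * length(pos))),
            sample(neg, round(train_fraction * length(neg))))
    te <- setdiff(seq_len(n), tr)
    xtr <- fr$x[tr, , drop = FALSE]
    ytr <- fr$y[tr]
    sel <- colnames(fr$x)
    if (features == "filtered") {
      wr <- welch_rank(xtr, ifelse(ytr, "pos", "neg"))
      rr <- rf_rank(xtr, ifelse(ytr, "pos", "neg"),
                    seed = sample.int(.Machine$integer.max, 1))
      sel <- suppressWarnings(select_features(wr, rr, top_k))
    }
    # class-stratified folds keep both classes in every cv training set
    # even for small, unbalanced scopes such as the CT-negative subgroup
    foldid <- integer(length(ytr))
    for (cl in c(TRUE, FALSE)) {
      idx <- sample(which(ytr == cl))
      foldid[idx] <- rep_len(1:5, length(idx))
    }
    fit <- glmnet::cv.glmnet(xtr[, sel, drop = FALSE], as.numeric(ytr),
                             family = "binomial", alpha = alpha,
                             foldid = foldid)
    score <- as.numeric(stats::predict(fit, fr$x[te, sel, drop = FALSE],
                                       s = "lambda.min", type = "link"))
    tibble::tibble(repeat_id = rep_i,
                   auc = auc_score(score, fr$y[te]),
                   n_features = length(sel),
                   features = list(sel))
  }) |>
    dplyr::bind_rows()

  structure(
    list(
      results = results,
      spec = list(penalty = penalty, features = features, scope = scope,
                  n_repeats = n_repeats, train_fraction = train_fraction,
                  top_k = top_k, seed = seed),
      n_subjects = n, n_pos = length(pos), n_neg = length(neg)
    ),
    class = "auc_report"
  )
}

#' @export
print.auc_report <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<auc_report> %s / %s / %s: %d repeats on %d subjects (%d+/%d-)\n",
              s$penalty, s$features, s$scope, s$n_repeats,
              x$n_subjects, x$n_pos, x$n_neg))
  a <- x$results$auc
  cat(sprintf("  AUC mean %.3f, median %.3f, IQR %.3f-%.3f\n",
              mean(a), stats::median(a),
              stats::quantile(a, 0.25), stats::quantile(a, 0.75)))
  invisible(x)
}

#' Run the full 8-cell classification grid
#'
#' Evaluates every combination of penalty (lasso, ridge), feature mode
#' (filtered, full) and cohort scope (all patients, CT-negative subgroup) —
#' the eight AUC cells of the analysis — and returns the aggregate per cell.
#'
#' @inheritParams evaluate_classifier
#' @return A tibble with one row per cell: `scope`, `features`, `penalty`,
#'   `mean_auc`, `median_auc`, `q25`, `q75`, `n_subjects`, plus a
#'   list-column `report` of the underlying `auc_report` objects.
#' @export
classification_grid <- function(cohort, n_repeats = 100, top_k = 30,
                                seed = 1) {
  grid <- tidyr::expand_grid(
    scope = c("all_patients", "ct_negative"),
    features = c("filtered", "full"),
    penalty = c("lasso", "ridge")
  )
  reports <- purrr::pmap(grid, function(scope, features, penalty) {
    evaluate_classifier(cohort, penalty = penalty, features = features,
                        scope = scope, n_repeats = n_repeats, top_k = top_k,
                        seed = seed)
  })
  dplyr::mutate(
    grid,
    mean_auc = purrr::map_dbl(reports, ~ mean(.x$results$auc)),
    median_auc = purrr::map_dbl(reports, ~ stats::median(.x$results$auc)),
    q25 = purrr::map_dbl(reports, ~ stats::quantile(.x$results$auc, 0.25)),
    q75 = purrr::map_dbl(reports, ~ stats::quantile(.x$results$auc, 0.75)),
    n_subjects = purrr::map_int(reports, ~ .x$n_subjects),
    report = reports
  )
}
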