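# Evaluation metrics, ROC convex hull of a classifier ensemble,
# probability-ranking AUROC, factor-importance rank fusion and the
# three-dataset study driver.

#' Sensitivity, specificity and misclassification error
#'
#' Standard definitions from the confusion counts, with MI hearts as the
#' positive class: sensitivity = TP/(TP+FN), specificity = TN/(TN+FP),
#' error = (FP+FN)/n. A zero denominator yields `NA` for the affected
#' metric (flagged, not an error).
#'
#' @param TP,TN,FP,FN nonnegative integer counts.
#' @return A list with `sensitivity`, `specificity`, `error` and the flag
#'   `undefined` (TRUE when any denominator was zero).
#' @export
classification_metrics <- function(TP, TN, FP, FN) {
  cnt <- c(TP, TN, FP, FN)
  if (any(!is.finite(cnt)) || any(cnt < 0) || any(cnt != round(cnt)))
    stop("counts must be nonnegative integers")
  n <- TP + TN + FP + FN
  sens <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  spec <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
  err <- if (n > 0) (FP + FN) / n else NA_real_
  list(sensitivity = unname(sens), specificity = unname(spec),
       error = unname(err),
       undefined = (TP + FN == 0) || (TN + FP == 0) || n == 0)
}

#' ROC convex hull of a classifier ensemble
#'
#' Upper convex hull of the ensemble's (1 - specificity, sensitivity)
#' points, anchored at (0, 0) and (1, 1): the ROC curve attainable by the
#' ensemble of classifiers. The area under it (trapezoidal integration
#' over the hull vertices) summarizes the best achievable ensemble
#' performance; with no informative points it degenerates to the chance
#' diagonal with AUROC 0.5.
#'
#' @param points a two-column matrix/data.frame of
#'   (1 - specificity, sensitivity) pairs in the unit square; may be
#'   empty.
#' @return A list with `hull` (matrix of hull vertices, anchors
#'   included) and `auroc`.
#' @export
roc_hull <- function(points = NULL) {
  pts <- rbind(c(0, 0), c(1, 1))
  if (!is.null(points) && NROW(points) > 0) {
    m <- as.matrix(points)
    if (ncol(m) != 2 || any(!is.finite(m)) || any(m < -1e-9) ||
        any(m > 1 + 1e-9))
      stop("points must lie in the unit square")
    pts <- rbind(pts, m)
  }
  pts <- unique(pts[order(pts[, 1], -pts[, 2]), , drop = FALSE])
  # Andrew monotone chain, upper hull from (0,0) to (1,1)
  hull <- list()
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    while (length(hull) >= 2) {
      a <- hull[[length(hull) - 1L]]; b <- hull[[length(hull)]]
      cross <- (b[1] - a[1]) * (p[2] - a[2]) -
        (b[2] - a[2]) * (p[1] - a[1])
      if (cross >= 0) hull[[length(hull)]] <- NULL else break
    }
    hull[[length(hull) + 1L]] <- p
  }
  h <- do.call(rbind, hull)
  # keep only the part at or above the chance diagonal
  h <- h[h[, 2] >= h[, 1] - 1e-12, , drop = FALSE]
  if (!any(h[, 1] == 0 & h[, 2] == 0)) h <- rbind(c(0, 0), h)
  if (!any(h[, 1] == 1 & h[, 2] == 1)) h <- rbind(h, c(1, 1))
  colnames(h) <- c("fpr", "sensitivity")
  auroc <- sum(diff(h[, 1]) * (utils::head(h[, 2], -1) +
                                 utils::tail(h[, 2], -1)) / 2)
  list(hull = h, auroc = auroc)
}

#' Probability-ranking AUROC
#'
#' Area under the ROC curve of a continuous score (Mann-Whitney
#' statistic with tie correction): the probability that a random MI
#' subject scores higher than a random healthy subject.
#'
#' @param prob numeric scores (e.g. predicted MI probabilities).
#' @param label labels, `"mi"` positive.
#' @return AUROC in `[0, 1]`.
#' @export
auroc_score <- function(prob, label) {
  pos <- label == "mi"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(prob)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cumulative factor-importance ranks
#'
#' Fuses per-method importance scores into a single relevance ranking:
#' within each method the features are ranked in ascending order of
#' importance with ranks 0 to p-1 (ties broken by stable input order),
#' and ranks are accumulated across methods. Higher accumulated rank =
#' more important factor.
#'
#' @param importance_list named list; each element a named numeric vector
#'   of importance scores over the same feature set.
#' @return An object of class `importance_table`: per-method rank matrix
#'   and the accumulated rank per feature.
#' @export
cumulative_rank <- function(importance_list) {
  if (!length(importance_list)) stop("importance_list is empty")
  feats <- names(importance_list[[1]])
  for (im in importance_list)
    if (!identical(sort(names(im)), sort(feats)))
      stop("all methods must cover the same feature set")
  ranks <- vapply(importance_list, function(im)
    rank(im[feats], ties.method = "first") - 1, numeric(length(feats)))
  ranks <- matrix(ranks, nrow = length(feats),
                  dimnames = list(feats, names(importance_list)))
  structure(list(ranks = ranks, accumulated = rowSums(ranks),
                 p = length(feats), n_methods = length(importance_list)),
            class = "importance_table")
}

#' @export
print.importance_table <- function(x, ...) {
  cat("Accumulated importance ranks (", x$n_methods, " methods, ranks 0..",
      x$p - 1, "):\n", sep = "")
  print(sort(x$accumulated, decreasing = TRUE))
  invisible(x)
}

#' Run the multi-dataset classification study
#'
#' Applies the full classifier portfolio to one or more feature tables
#' (typically the datasets D1, D2, D3 over the same subjects) with
#' nested LOOCV, and assembles: the per-method metrics table, the
#' ensemble ROC convex hull and its AUROC per dataset (univariate
#' logistic regression contributes one point per feature), the method
#' ranking by summed misclassification error across datasets, and the
#' fused factor-importance ranks per dataset.
#'
#' @param tables named list of feature tables (see [nested_loocv()]).
#' @param specs list of [classifier_spec()]s; defaults to the
#'   eight-method portfolio.
#' @param seed master seed.
#' @return An object of class `lv_study`.
#' @export
run_study <- function(tables, specs = default_classifier_specs(),
                      seed = 1) {
  stopifnot(is.list(tables), length(tables) > 0)
  if (is.null(names(tables)))
    names(tables) <- paste0("D", seq_along(tables))
  metrics <- list(); hulls <- list(); importance <- list()
  roc_points <- list()
  for (ds in names(tables)) {
    tab <- tables[[ds]]
    evs <- lapply(specs, nested_loocv, table = tab, seed = seed)
    names(evs) <- vapply(specs, `[[`, "", "method")
    met <- do.call(rbind, lapply(evs, function(e)
      data.frame(dataset = ds, method = e$method, TP = e$TP, TN = e$TN,
                 FP = e$FP, FN = e$FN, sensitivity = e$sensitivity,
                 specificity = e$specificity, error = e$error)))
    pts <- data.frame(method = met$method,
                      fpr = 1 - met$specificity,
                      sensitivity = met$sensitivity)
    # univariate LR: one operating point per single feature
    if ("univariate_LR" %in% names(evs)) {
      feats <- setdiff(names(tab), c("subject_id", "label"))
      for (f in feats) {
        ev <- nested_loocv(classifier_spec("univariate_LR", grid = f),
                           tab[, c("label", f)], seed = seed)
        pts <- rbind(pts, data.frame(method = paste0("univariate_", f),
                                     fpr = 1 - ev$specificity,
                                     sensitivity = ev$sensitivity))
      }
    }
    metrics[[ds]] <- met
    roc_points[[ds]] <- pts
    hulls[[ds]] <- roc_hull(pts[, c("fpr", "sensitivity")])
    imps <- lapply(evs[!vapply(evs, function(e)
      is.null(e$importance), logical(1))], classifier_importance)
    importance[[ds]] <- if (length(imps)) cumulative_rank(imps) else NULL
  }
  met_all <- do.call(rbind, metrics)
  rownames(met_all) <- NULL
  err_sum <- tapply(met_all$error, met_all$method, sum)
  ranking <- data.frame(method = names(sort(err_sum)),
                        error_sum = as.numeric(sort(err_sum)))
  structure(list(metrics = met_all, roc_points = roc_points,
                 hulls = hulls,
                 auroc = vapply(hulls, `[[`, numeric(1), "auroc"),
                 importance = importance, ranking = ranking,
                 seed = seed),
            class = "lv_study")
}

#' @export
print.lv_study <- function(x, ...) {
  cat("Classification study over", length(x$hulls), "dataset(s)\n")
  cat("Hull AUROC:", paste(names(x$auroc), round(x$auroc, 3),
                           sep = " = ", collapse = ", "), "\n")
  cat("Method ranking (by summed error):",
      paste(x$ranking$method, collapse = " > "), "\n")
  invisible(x)
}

#' Permutation-null AUROC of held-out logistic-regression probabilities
#'
#' Estimates the chance-level AUROC: class labels are permuted uniformly
#' at random, a multivariate logistic regression is evaluated by k-fold
#' cross-validation, and the AUROC of the held-out probabilities is
#' averaged over permutations. Converges to 0.5 for any feature table.
#'
#' @param table a labelled feature table.
#' @param n_perm number of permutations.
#' @param k_folds folds of the cross-validation.
#' @param seed master seed.
#' @return A list with `mean_auroc` and the per-permutation values.
#' @export
permutation_null_auroc <- function(table, n_perm = 200, k_folds = 5,
                                   seed = 1) {
  dat <- .as_class_data(table)
  X <- dat$X
  n <- nrow(X)
  set.seed(seed)
  vals <- vapply(seq_len(n_perm), function(b) {
    y <- sample(dat$y01)
    fold <- sample(rep_len(seq_len(k_folds), n))
    prob <- numeric(n)
    for (k in seq_len(k_folds)) {
      te <- fold == k
      if (length(unique(y[!te])) < 2) { prob[te] <- 0.5; next }
      s <- .standardize(X[!te, , drop = FALSE], X[te, , drop = FALSE])
      beta <- .fit_logistic(s$tr, y[!te])
      prob[te] <- .predict_logistic(beta, s$te)
    }
    auroc_score(prob, ifelse(y == 1, "mi", "healthy"))
  }, numeric(1))
  list(mean_auroc = mean(vals), auroc = vals)
}

#' Replicated ensemble hull AUROC on calibrated synthetic cohorts
#'
#' For each replicate: draw a cohort from the calibrated feature
#' generator, run the full classifier portfolio with nested LOOCV on the
#' requested dataset, and record the ROC convex-hull AUROC. Reports the
#' per-replicate values and their mean.
#'
#' @param cfg a [cohort_config()].
#' @param n_rep number of replicates.
#' @param dataset feature set (`"D1"`, `"D2"`, `"D3"`).
#' @param n_healthy,n_mi cohort sizes per replicate.
#' @param specs classifier portfolio.
#' @param seed master seed (replicate r uses `seed + r`).
#' @return A list with `mean_auroc` and per-replicate `auroc`.
#' @export
hull_auroc_replicates <- function(cfg = cohort_config(), n_rep = 20,
                                  dataset = "D1",
                                  n_healthy = cfg$n_healthy,
                                  n_mi = cfg$n_mi,
                                  specs = default_classifier_specs(),
                                  seed = 1) {
  vals <- vapply(seq_len(n_rep), function(r) {
    tab <- generate_feature_table(cfg, n_healthy, n_mi,
                                  dataset = dataset, seed = seed + r)
    st <- run_study(list(tab), specs = specs, seed = seed + r)
    unname(st$auroc[1])
  }, numeric(1))
  list(mean_auroc = mean(vals), auroc = vals)
}
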