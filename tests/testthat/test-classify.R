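# Classification machinery: fold enumeration, metrics identities, ROC
# hull, leakage protection, importance measures and rank fusion.

test_that("nested LOOCV fold enumeration matches the worked four-point
           scheme", {
  outer <- loocv_folds(4)
  got <- lapply(outer, function(f) sort(f$train))
  expect_setequal(
    lapply(outer, function(f) paste(sort(f$train), collapse = ",")),
    list("1,2,3", "1,2,4", "1,3,4", "2,3,4"))
  expect_setequal(vapply(outer, `[[`, 1L, "eval"), 1:4)
  # inner folds of the training set {1, 2, 3}
  inner <- loocv_folds(3)
  expect_setequal(
    lapply(inner, function(f) paste(sort(f$train), collapse = ",")),
    list("1,2", "1,3", "2,3"))
  expect_error(loocv_folds(1), "at least 2")
})

test_that("metrics identities hold on arbitrary integer counts", {
  set.seed(14)
  for (rep in 1:50) {
    cnt <- stats::rpois(4, 8)
    if (cnt[1] + cnt[4] == 0 || cnt[2] + cnt[3] == 0) next
    m <- classification_metrics(cnt[1], cnt[2], cnt[3], cnt[4])
    expect_equal(m$sensitivity, cnt[1] / (cnt[1] + cnt[4]))
    expect_equal(m$specificity, cnt[2] / (cnt[2] + cnt[3]))
    expect_equal(m$error, (cnt[3] + cnt[4]) / sum(cnt))
    expect_false(m$undefined)
  }
  # a published-style triple: 7/4/27/0 of 38
  m <- classification_metrics(TP = 7, TN = 27, FP = 0, FN = 4)
  expect_equal(round(m$sensitivity, 2), 0.64)
  expect_equal(round(m$specificity, 2), 1.00)
  expect_equal(round(m$error, 2), 0.11)
  # all correct / all wrong
  expect_equal(classification_metrics(10, 20, 0, 0)$error, 0)
  m_wrong <- classification_metrics(0, 0, 20, 10)
  expect_equal(m_wrong$sensitivity, 0)
  expect_equal(m_wrong$specificity, 0)
  expect_equal(m_wrong$error, 1)
  # always-predict-healthy: zero sensitivity, perfect specificity
  m_null <- classification_metrics(0, 27, 0, 11)
  expect_equal(m_null$sensitivity, 0)
  expect_equal(m_null$specificity, 1)
  # undefined metric flagged, not an error
  expect_true(classification_metrics(0, 5, 2, 0)$undefined)
  expect_error(classification_metrics(-1, 2, 3, 4), "nonnegative")
})

test_that("ROC hull handles anchors, dominating points and the hand
           example", {
  expect_equal(roc_hull()$auroc, 0.5)
  expect_equal(roc_hull(matrix(c(0, 1), 1))$auroc, 1.0)
  h <- roc_hull(rbind(c(0.2, 0.8), c(0.5, 0.6)))
  expect_equal(h$auroc, 0.80)
  expect_equal(nrow(h$hull), 3)
  expect_true(any(h$hull[, 1] == 0.2 & h$hull[, 2] == 0.8))
  expect_error(roc_hull(rbind(c(1.5, 0.2))), "unit square")
})

test_that("hull AUROC dominates every single-point trapezoid", {
  set.seed(31)
  for (rep in 1:20) {
    pts <- cbind(stats::runif(6), stats::runif(6))
    hull_auc <- roc_hull(pts)$auroc
    single <- apply(pts, 1, function(p)
      roc_hull(matrix(p, 1))$auroc)
    expect_gte(hull_auc, max(single) - 1e-12)
  }
})

test_that("every portfolio method separates well-separated classes
           perfectly", {
  tab <- fx_separable_table()
  for (m in c("univariate_LR", "multivariate_LR", "KNN", "LDA",
              "lasso_LR", "boosted_entropy_tree", "random_forest",
              "gp_ard")) {
    ev <- nested_loocv(classifier_spec(m), tab, seed = 2)
    expect_equal(ev$error, 0, info = m)
  }
})

test_that("held-out predictions are invariant to the held-out subject's
           label (no leakage)", {
  tab <- generate_feature_table(n_healthy = 14, n_mi = 8,
                                dataset = "D1", seed = 17)
  base <- nested_loocv(classifier_spec("multivariate_LR"), tab,
                       seed = 3)
  for (i in c(2, 17)) {
    mut <- tab
    mut$label[i] <- if (mut$label[i] == "mi") "healthy" else "mi"
    ev <- nested_loocv(classifier_spec("multivariate_LR"), mut,
                       seed = 3)
    expect_equal(ev$prob[i], base$prob[i], tolerance = 1e-10)
  }
})

test_that("degenerate tables are rejected", {
  tab <- fx_separable_table(n_per = 4)
  tab_one <- tab; tab_one$label <- "healthy"
  expect_error(nested_loocv(classifier_spec("LDA"), tab_one),
               "both classes")
  expect_error(nested_loocv(classifier_spec("LDA"), tab[1:2, ]),
               "at least 3")
  expect_error(classifier_spec("boosting_trees"), "arg")
})

test_that("heavy lasso penalty zeroes coefficients and their importance", {
  tab <- fx_separable_table(n_per = 8)
  ev <- nested_loocv(classifier_spec("lasso_LR", grid = 50), tab,
                     seed = 5)
  imp <- classifier_importance(ev)
  expect_equal(unname(imp), c(0, 0))
  expect_error(classifier_importance(
    nested_loocv(classifier_spec("LDA"), tab, seed = 5)),
    "no importance")
})

test_that("GP-ARD assigns near-zero relevance to a pure-noise feature", {
  set.seed(41)
  n <- 40
  tab <- data.frame(
    label = rep(c("healthy", "mi"), each = n / 2),
    signal = c(stats::rnorm(n / 2, 0), stats::rnorm(n / 2, 3)),
    noise = stats::rnorm(n))
  ev <- nested_loocv(classifier_spec("gp_ard"), tab, seed = 6)
  imp <- classifier_importance(ev)
  expect_lt(imp[["noise"]], 0.3 * imp[["signal"]])
})

test_that("an exact duplicate splits random-forest importance", {
  set.seed(43)
  n <- 60
  base <- data.frame(
    label = rep(c("healthy", "mi"), each = n / 2),
    signal = c(stats::rnorm(n / 2, 0), stats::rnorm(n / 2, 2.5)),
    other = stats::rnorm(n))
  solo <- classifier_importance(
    nested_loocv(classifier_spec("random_forest"), base, seed = 8))
  dup <- base
  dup$signal_copy <- dup$signal
  split <- classifier_importance(
    nested_loocv(classifier_spec("random_forest"), dup, seed = 8))
  expect_lt(split[["signal"]], solo[["signal"]] * 1.0 + 1e-9)
  expect_gt(split[["signal_copy"]], 0.2)  # the copy absorbs relevance
})

test_that("rank fusion produces permutations and respects symmetry", {
  one <- cumulative_rank(list(m1 = c(a = 0.1, b = 0.9)))
  expect_equal(unname(one$accumulated), c(0, 1))
  two <- cumulative_rank(list(m1 = c(a = 0.1, b = 0.9),
                              m2 = c(a = 0.9, b = 0.1)))
  expect_equal(unname(two$accumulated), c(1, 1))
  set.seed(51)
  many <- cumulative_rank(list(
    m1 = stats::setNames(stats::runif(5), letters[1:5]),
    m2 = stats::setNames(stats::runif(5), letters[1:5]),
    m3 = stats::setNames(stats::runif(5), letters[1:5])))
  for (j in seq_len(ncol(many$ranks)))
    expect_setequal(many$ranks[, j], 0:4)
  expect_true(all(many$accumulated <= 3 * 4))
  expect_error(cumulative_rank(list(m1 = c(a = 1), m2 = c(b = 1))),
               "same feature set")
})

test_that("permutation-null AUROC sits at chance level", {
  # cross-validated predictions under a permutation null carry a small
  # pessimistic bias of order 1/n, so the band is 0.05 at this size
  tab <- generate_feature_table(n_healthy = 600, n_mi = 400,
                                dataset = "D1", seed = 23)
  nullres <- permutation_null_auroc(tab, n_perm = 30, seed = 29)
  expect_lt(abs(nullres$mean_auroc - 0.5), 0.05)
})

test_that("the study driver assembles metrics, hulls and fused ranks", {
  tab <- generate_feature_table(n_healthy = 20, n_mi = 10,
                                dataset = "D3", seed = 33)
  specs <- list(classifier_spec("multivariate_LR"),
                classifier_spec("LDA"),
                classifier_spec("random_forest"),
                classifier_spec("univariate_LR"))
  st <- run_study(list(D3 = tab), specs = specs, seed = 3)
  expect_equal(nrow(st$metrics), 4)
  expect_true(st$auroc["D3"] >= 0.5 && st$auroc["D3"] <= 1)
  expect_equal(st$ranking$error_sum, sort(st$ranking$error_sum))
  expect_s3_class(st$importance$D3, "importance_table")
  # univariate per-feature operating points feed the hull
  expect_gt(nrow(st$roc_points$D3), 4)
})
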