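# Eight-method classification study machinery: classifier registry,
# nested leave-one-out cross-validation (outer loop for evaluation,
# inner loop on each outer training set for hyperparameter tuning),
# confusion counts and metrics. Positive labels are MI hearts.

.CLASSIFIER_METHODS <- c("univariate_LR", "multivariate_LR", "KNN",
                         "LDA", "lasso_LR", "boosted_entropy_tree",
                         "random_forest", "gp_ard")

#' Classifier specification
#'
#' Describes one classification method and its hyperparameter grid. When
#' the grid has more than one entry, [nested_loocv()] selects the value by
#' inner leave-one-out cross-validation on each outer training set
#' (`gp_ard` instead tunes by marginal-likelihood maximization). Default
#' grids: `KNN` over k = 1, 3, 5, 7 (low k wins on narrow decision
#' boundaries); `lasso_LR` over a fixed 20-point log-spaced penalty grid;
#' `univariate_LR` treats the predictor choice as its tuned parameter;
#' the tree ensembles use fixed settings (10 boosting rounds;
#' square-root-of-p feature subsampling with 200 trees).
#'
#' @param method one of `r paste0('"', .CLASSIFIER_METHODS, '"', collapse = ", ")`.
#' @param grid optional hyperparameter grid (vector/list); `NULL` uses
#'   the method default.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(method, grid = NULL) {
  method <- match.arg(method, .CLASSIFIER_METHODS)
  if (is.null(grid)) {
    grid <- switch(method,
      KNN = c(1, 3, 5, 7),
      lasso_LR = exp(seq(log(0.5), log(1e-3), length.out = 20)),
      univariate_LR = NA,  # resolved to feature names at fit time
      list(NULL))
  }
  if (length(grid) == 0) stop("hyperparameter grid must be non-empty")
  structure(list(method = method, grid = grid),
            class = "classifier_spec")
}

#' Default specifications for the eight-method portfolio
#'
#' @return A named list of [classifier_spec()] objects.
#' @export
default_classifier_specs <- function() {
  sapply(.CLASSIFIER_METHODS, classifier_spec, simplify = FALSE)
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat("Classifier:", x$method, "(grid size",
      if (identical(x$grid, NA)) "p" else length(x$grid), ")\n")
  invisible(x)
}

#' Leave-one-out fold enumeration
#'
#' Enumerates the leave-one-out folds over `n` observations: fold `i`
#' trains on all observations except `i` and evaluates on `i`.
#'
#' @param n number of observations (`>= 2`).
#' @return A list of lists with elements `train` and `eval`.
#' @export
loocv_folds <- function(n) {
  if (n < 2) stop("need at least 2 observations")
  lapply(seq_len(n), function(i)
    list(train = setdiff(seq_len(n), i), eval = i))
}

# --- internal fit/predict registry ---------------------------------------

.standardize <- function(Xtr, Xte) {
  mu <- colMeans(Xtr)
  sd <- apply(Xtr, 2, stats::sd)
  sd[!is.finite(sd) | sd < 1e-12] <- 1
  list(tr = sweep(sweep(Xtr, 2, mu, "-"), 2, sd, "/"),
       te = sweep(sweep(Xte, 2, mu, "-"), 2, sd, "/"))
}

.fit_logistic <- function(X, y01) {
  suppressWarnings(stats::glm.fit(cbind(1, X), y01,
                                  family = stats::binomial()))$coefficients
}

# Small dense Newton logistic fit (intercept + columns of X); much less
# call overhead than glm.fit for the inner tuning loops.
.fast_logistic <- function(X, y01, maxit = 25) {
  A <- cbind(1, X)
  beta <- numeric(ncol(A))
  for (it in seq_len(maxit)) {
    eta <- pmin(pmax(as.numeric(A %*% beta), -30), 30)
    p <- 1 / (1 + exp(-eta))
    W <- pmax(p * (1 - p), 1e-10)
    g <- crossprod(A, y01 - p)
    H <- crossprod(A * W, A) + diag(1e-8, ncol(A))
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta + step
    if (max(abs(step)) < 1e-8) break
  }
  beta
}

# LOOCV misclassification error of k-nearest-neighbours for every k in
# `ks`, from one standardized distance matrix (majority vote among the
# k nearest excluding the held-out point).
.knn_loocv_errors <- function(X, y01, ks) {
  s <- .standardize(X, X)$tr
  n <- nrow(s)
  D <- as.matrix(stats::dist(s))
  diag(D) <- Inf
  errs <- numeric(length(ks))
  ord <- apply(D, 1, order)     # n-1 usable neighbours per column
  for (ki in seq_along(ks)) {
    k <- min(ks[ki], n - 1)
    wrong <- 0L
    for (j in seq_len(n)) {
      vote <- mean(y01[ord[seq_len(k), j]])
      wrong <- wrong + as.integer((vote >= 0.5) != (y01[j] == 1))
    }
    errs[ki] <- wrong / n
  }
  errs
}

# Inner-LOOCV misclassification error per lambda for the lasso path:
# one path fit per inner fold, all penalties evaluated at once.
.lasso_inner_errors <- function(X, y01, lambdas) {
  n <- nrow(X)
  lam <- sort(lambdas, decreasing = TRUE)
  wrong <- numeric(length(lam))
  for (j in seq_len(n)) {
    tr <- setdiff(seq_len(n), j)
    if (length(unique(y01[tr])) < 2) next
    s <- .standardize(X[tr, , drop = FALSE], X[j, , drop = FALSE])
    fit <- suppressWarnings(
      glmnet::glmnet(s$tr, y01[tr], family = "binomial",
                     lambda = lam, standardize = FALSE))
    p <- as.numeric(stats::predict(fit, newx = s$te, s = lam,
                                   type = "response"))
    wrong <- wrong + as.integer((p >= 0.5) != (y01[j] == 1))
  }
  stats::setNames(wrong / n, lam)
}

# LOOCV error of a single-predictor logistic regression (fast path for
# the univariate inner selection).
.uni_logistic_loocv_error <- function(x, y01) {
  n <- length(x)
  wrong <- 0L
  for (j in seq_len(n)) {
    tr <- setdiff(seq_len(n), j)
    xm <- mean(x[tr]); xs <- stats::sd(x[tr])
    if (!is.finite(xs) || xs < 1e-12) xs <- 1
    beta <- .fast_logistic(matrix((x[tr] - xm) / xs), y01[tr])
    eta <- beta[1] + beta[2] * (x[j] - xm) / xs
    wrong <- wrong + as.integer((eta >= 0) != (y01[j] == 1))
  }
  wrong / n
}

.predict_logistic <- function(beta, X) {
  beta[!is.finite(beta)] <- 0
  as.numeric(stats::plogis(cbind(1, X) %*% beta))
}

# AdaBoost.M1 over entropy-split trees; usage metric = fraction of
# rounds in which a feature appears in any split.
.fit_boost <- function(X, y01, rounds = 10, maxdepth = 3) {
  df <- data.frame(.y = factor(y01, levels = c(0, 1)), X,
                   check.names = FALSE)
  n <- nrow(df)
  w <- rep(1 / n, n)
  fits <- list(); alphas <- numeric(0)
  usage <- matrix(0, rounds, ncol(X),
                  dimnames = list(NULL, colnames(X)))
  for (m in seq_len(rounds)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w,
                        method = "class",
                        parms = list(split = "information"),
                        control = rpart::rpart.control(
                          maxdepth = maxdepth, cp = 0.01,
                          minsplit = 5, xval = 0, maxcompete = 0,
                          maxsurrogate = 0))
    pred <- stats::predict(fit, df, type = "class")
    err <- sum(w[pred != df$.y]) / sum(w)
    err <- min(max(err, 1e-6), 1 - 1e-6)
    alpha <- 0.5 * log((1 - err) / err)
    w <- w * exp(alpha * (pred != df$.y))
    w <- w / sum(w)
    fits[[m]] <- fit
    alphas[m] <- alpha
    used <- setdiff(unique(as.character(fit$frame$var)), "<leaf>")
    usage[m, colnames(X) %in% used] <- 1
  }
  list(fits = fits, alphas = pmax(alphas, 0),
       usage = colMeans(usage))
}

.predict_boost <- function(model, Xnew) {
  df <- data.frame(Xnew, check.names = FALSE)
  votes <- vapply(seq_along(model$fits), function(m) {
    as.numeric(stats::predict(model$fits[[m]], df,
                              type = "class") == "1")
  }, numeric(nrow(df)))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = nrow(df))
  asum <- sum(model$alphas)
  if (asum <= 0) return(rep(0.5, nrow(df)))
  as.numeric(votes %*% model$alphas / asum)
}

# Fit `method` on (X, y01) with hyperparameter `hp`; return an object
# with enough to predict MI probabilities and extract importance.
.fit_method <- function(method, X, y01, hp, seed = 1, warm = NULL) {
  switch(method,
    univariate_LR = {
      x <- X[, hp, drop = FALSE]
      s <- .standardize(x, x)
      list(beta = .fit_logistic(s$tr, y01), feature = hp,
           mu = colMeans(x), sd = apply(x, 2, stats::sd),
           univariate = TRUE)
    },
    multivariate_LR = {
      s <- .standardize(X, X)
      list(beta = .fit_logistic(s$tr, y01), mu = colMeans(X),
           sd = apply(X, 2, stats::sd))
    },
    KNN = list(X = X, y01 = y01, k = hp,
               mu = colMeans(X), sd = apply(X, 2, stats::sd)),
    LDA = MASS::lda(X, grouping = factor(y01, levels = c(0, 1))),
    lasso_LR = {
      s <- .standardize(X, X)
      list(fit = suppressWarnings(
             glmnet::glmnet(s$tr, y01, family = "binomial",
                            lambda = sort(unique(c(hp,
                              classifier_spec("lasso_LR")$grid)),
                              decreasing = TRUE),
                            standardize = FALSE)),
           lambda = hp, mu = colMeans(X), sd = apply(X, 2, stats::sd))
    },
    boosted_entropy_tree = .fit_boost(X, y01),
    random_forest = {
      set.seed(seed)
      randomForest::randomForest(
        X, factor(y01, levels = c(0, 1)),
        ntree = 200, importance = TRUE)
    },
    gp_ard = {
      s <- .standardize(X, X)
      # warm-started folds need far fewer marginal-likelihood steps
      fit <- .gp_ard_fit(s$tr, y01, init = warm,
                         maxit = if (is.null(warm)) 80 else 30)
      fit$mu <- colMeans(X); fit$sd <- apply(X, 2, stats::sd)
      fit
    },
    stop("unknown method ", method))
}

.predict_method <- function(method, model, Xnew) {
  std <- function(mu, sd) {
    sd[!is.finite(sd) | sd < 1e-12] <- 1
    sweep(sweep(Xnew, 2, mu, "-"), 2, sd, "/")
  }
  switch(method,
    univariate_LR = {
      xn <- Xnew[, model$feature, drop = FALSE]
      sd <- model$sd; sd[!is.finite(sd) | sd < 1e-12] <- 1
      .predict_logistic(model$beta,
                        sweep(sweep(xn, 2, model$mu, "-"), 2, sd, "/"))
    },
    multivariate_LR = .predict_logistic(model$beta,
                                        std(model$mu, model$sd)),
    KNN = {
      s <- .standardize(model$X, Xnew)
      pr <- class::knn(s$tr, s$te,
                       cl = factor(model$y01, levels = c(0, 1)),
                       k = model$k, prob = TRUE)
      p_win <- attr(pr, "prob")
      ifelse(pr == "1", p_win, 1 - p_win)
    },
    LDA = as.numeric(stats::predict(model, Xnew)$posterior[, "1"]),
    lasso_LR = as.numeric(stats::predict(
      model$fit, newx = std(model$mu, model$sd), s = model$lambda,
      type = "response")),
    boosted_entropy_tree = .predict_boost(model, Xnew),
    random_forest = as.numeric(stats::predict(model, Xnew,
                                              type = "prob")[, "1"]),
    gp_ard = .gp_ard_predict(model, std(model$mu, model$sd)),
    stop("unknown method ", method))
}

.needs_inner_cv <- function(spec) {
  !spec$method %in% c("multivariate_LR", "LDA", "gp_ard") &&
    (identical(spec$grid, NA) || length(spec$grid) > 1)
}

# inner LOOCV error of hyperparameter hp on (X, y01)
.inner_cv_error <- function(method, X, y01, hp, seed) {
  n <- nrow(X)
  wrong <- 0L
  for (j in seq_len(n)) {
    tr <- setdiff(seq_len(n), j)
    if (length(unique(y01[tr])) < 2) next
    model <- .fit_method(method, X[tr, , drop = FALSE], y01[tr], hp,
                         seed = seed)
    p <- .predict_method(method, model, X[j, , drop = FALSE])
    wrong <- wrong + as.integer((p >= 0.5) != (y01[j] == 1))
  }
  wrong / n
}

#' Nested leave-one-out cross-validated evaluation
#'
#' Evaluates a classifier with two nested LOOCV schemes: the outer loop
#' provides out-of-sample predictions for evaluation; for methods with a
#' tunable regularization parameter, an inner LOOCV on each outer
#' training set selects it (ties broken toward the first grid entry).
#' The Bayesian `gp_ard` tunes its hyperparameters by maximizing the
#' marginal likelihood of the outer training data. Out-of-sample
#' observations never influence tuning. Outer folds whose training set
#' lacks a class are skipped with a warning and recorded.
#'
#' @param spec a [classifier_spec()].
#' @param table data.frame with columns `label` (`"healthy"`/`"mi"`) and
#'   numeric features (a `subject_id` column is ignored).
#' @param seed master seed; stochastic learners are seeded per fold.
#' @return An object of class `eval_result`: confusion counts, the
#'   metrics of [classification_metrics()], per-fold probabilities,
#'   chosen hyperparameters, and per-fold importance scores (methods
#'   that define them).
#' @export
nested_loocv <- function(spec, table, seed = 1) {
  stopifnot(inherits(spec, "classifier_spec"))
  dat <- .as_class_data(table)
  X <- dat$X; y01 <- dat$y01
  n <- nrow(X)
  if (n < 3) stop("need at least 3 observations")
  if (length(unique(y01)) < 2) stop("both classes must be present")
  grid <- spec$grid
  if (identical(grid, NA)) grid <- colnames(X)
  prob <- rep(NA_real_, n)
  chosen <- vector("list", n)
  skipped <- integer(0)
  imp <- list()
  warm <- NULL
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    if (length(unique(y01[tr])) < 2) {
      warning("outer fold ", i, " skipped: a class is absent from the ",
              "training set")
      skipped <- c(skipped, i)
      next
    }
    Xtr <- X[tr, , drop = FALSE]; ytr <- y01[tr]
    hp <- if (!.needs_inner_cv(spec)) {
      if (is.list(grid)) grid[[1]] else grid[1]
    } else if (spec$method == "KNN") {
      grid[which.min(.knn_loocv_errors(Xtr, ytr, grid))]
    } else if (spec$method == "lasso_LR") {
      lam <- sort(grid, decreasing = TRUE)  # ties -> sparser model
      lam[which.min(.lasso_inner_errors(Xtr, ytr, lam))]
    } else if (spec$method == "univariate_LR") {
      errs <- vapply(grid, function(f)
        .uni_logistic_loocv_error(Xtr[, f], ytr), numeric(1))
      grid[which.min(errs)]
    } else {
      errs <- vapply(grid, function(h)
        .inner_cv_error(spec$method, Xtr, ytr, h, seed + i),
        numeric(1))
      grid[[which.min(errs)]]
    }
    set.seed(seed + i)
    model <- .fit_method(spec$method, Xtr, ytr, hp, seed = seed + i,
                         warm = warm)
    if (spec$method == "gp_ard" && !is.null(model$theta))
      warm <- model$theta
    prob[i] <- .predict_method(spec$method, model,
                               X[i, , drop = FALSE])
    chosen[[i]] <- hp
    fi <- .fold_importance(spec$method, model, colnames(X))
    if (!is.null(fi)) imp[[length(imp) + 1L]] <- fi
  }
  used <- setdiff(seq_len(n), skipped)
  pred <- prob[used] >= 0.5
  truth <- y01[used] == 1
  counts <- c(TP = sum(pred & truth), TN = sum(!pred & !truth),
              FP = sum(pred & !truth), FN = sum(!pred & truth))
  res <- c(as.list(counts), classification_metrics(counts["TP"],
             counts["TN"], counts["FP"], counts["FN"]))
  res$prob <- prob
  res$label <- dat$label
  res$chosen <- chosen
  res$skipped <- skipped
  res$method <- spec$method
  res$importance <- if (length(imp)) colMeans(do.call(rbind, imp))
                    else NULL
  class(res) <- "eval_result"
  res
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf(
    "%s: error %.3f, sensitivity %.2f, specificity %.2f (TP %d FP %d TN %d FN %d)\n",
    x$method, x$error, x$sensitivity, x$specificity, x$TP, x$FP, x$TN,
    x$FN))
  invisible(x)
}

# per-fold raw importance (NULL for methods without a measure)
.fold_importance <- function(method, model, features) {
  switch(method,
    lasso_LR = {
      beta <- as.numeric(stats::coef(model$fit, s = model$lambda))[-1]
      stats::setNames(beta, features)  # averaged then |.| downstream
    },
    gp_ard = stats::setNames(1 / model$ell, features),
    boosted_entropy_tree = stats::setNames(model$usage, features),
    random_forest = stats::setNames(
      model$importance[features, "MeanDecreaseAccuracy"], features),
    NULL)
}

#' Per-feature importance of a fitted evaluation
#'
#' Method-specific importance scores, averaged over the outer folds of a
#' [nested_loocv()] run: absolute mean standardized coefficient (lasso),
#' inverted normalized length scales (GP-ARD), split-usage fraction
#' (boosted entropy trees) and mean decrease in accuracy (random
#' forest).
#'
#' @param result an `eval_result` from [nested_loocv()].
#' @return Named numeric vector of nonnegative scores (normalized to
#'   maximum 1), or an error for methods without an importance measure.
#' @export
classifier_importance <- function(result) {
  stopifnot(inherits(result, "eval_result"))
  if (is.null(result$importance))
    stop("method '", result$method, "' has no importance measure")
  sc <- result$importance
  if (result$method == "lasso_LR") sc <- abs(sc)
  if (result$method == "gp_ard") sc <- sc / max(sc)
  if (max(sc) > 0) sc <- sc / max(sc)
  sc
}

.as_class_data <- function(table) {
  stopifnot(is.data.frame(table), "label" %in% names(table))
  lab <- as.character(table$label)
  if (!all(lab %in% c("healthy", "mi")))
    stop("label column must contain only 'healthy'/'mi'")
  feat <- setdiff(names(table), c("label", "subject_id"))
  X <- as.matrix(table[, feat, drop = FALSE])
  storage.mode(X) <- "double"
  list(X = X, y01 = as.integer(lab == "mi"), label = lab)
}
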