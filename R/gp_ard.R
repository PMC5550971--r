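# Gaussian-process binary classifier with automatic relevance
# determination: squared-exponential kernel with one length scale per
# feature, logistic likelihood, Laplace approximation for the posterior
# and the marginal likelihood, hyperparameters by maximizing the Laplace
# marginal likelihood on the training data. Per-feature relevance is the
# inverted, normalized length scale.

.gp_kernel <- function(X1, X2, ell, sf2) {
  X1s <- sweep(X1, 2, ell, "/")
  X2s <- sweep(X2, 2, ell, "/")
  d2 <- outer(rowSums(X1s^2), rowSums(X2s^2), "+") -
    2 * tcrossprod(X1s, X2s)
  sf2 * exp(-0.5 * pmax(d2, 0))
}

# Laplace mode finding (logistic likelihood, targets t in {0,1}).
# Returns the mode, the log marginal likelihood and reusable pieces.
.gp_laplace <- function(K, t, maxit = 60) {
  n <- length(t)
  f <- numeric(n)
  obj_old <- -Inf
  for (it in seq_len(maxit)) {
    pi_ <- stats::plogis(f)
    W <- pi_ * (1 - pi_)
    sW <- sqrt(W)
    B <- diag(n) + (sW %o% sW) * K
    L <- tryCatch(chol(B), error = function(e) NULL)
    if (is.null(L)) return(NULL)
    b <- W * f + (t - pi_)
    a <- b - sW * backsolve(L, forwardsolve(t(L), sW * (K %*% b)))
    f_new <- as.numeric(K %*% a)
    obj <- -0.5 * sum(a * f_new) +
      sum(stats::plogis(ifelse(t == 1, f_new, -f_new), log.p = TRUE))
    if (abs(obj - obj_old) < 1e-8) { f <- f_new; break }
    f <- f_new; obj_old <- obj
  }
  pi_ <- stats::plogis(f)
  W <- pi_ * (1 - pi_)
  sW <- sqrt(W)
  B <- diag(n) + (sW %o% sW) * K
  L <- tryCatch(chol(B), error = function(e) NULL)
  if (is.null(L)) return(NULL)
  a <- (t - pi_) + W * f -
    sW * backsolve(L, forwardsolve(t(L), sW * (K %*% (W * f + (t - pi_)))))
  lml <- -0.5 * sum(a * f) +
    sum(stats::plogis(ifelse(t == 1, f, -f), log.p = TRUE)) -
    sum(log(diag(L)))
  list(f = f, lml = lml, L = L, sW = sW, t = t, pi_ = pi_)
}

# Fit: optimize log hyperparameters (p length scales + signal sd) by
# maximizing the Laplace marginal likelihood. Deterministic.
.gp_ard_fit <- function(X, y01, init = NULL, maxit = 80) {
  p <- ncol(X)
  th0 <- if (is.null(init)) rep(0, p + 1) else init
  nll <- function(th) {
    ell <- exp(pmin(pmax(th[1:p], -4), 6))
    sf2 <- exp(2 * pmin(pmax(th[p + 1], -3), 3))
    K <- .gp_kernel(X, X, ell, sf2) + diag(1e-6, nrow(X))
    lp <- .gp_laplace(K, y01)
    if (is.null(lp)) return(1e6)
    -lp$lml
  }
  opt <- stats::optim(th0, nll, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-7))
  th <- opt$par
  ell <- exp(pmin(pmax(th[1:p], -4), 6))
  sf2 <- exp(2 * pmin(pmax(th[p + 1], -3), 3))
  K <- .gp_kernel(X, X, ell, sf2) + diag(1e-6, nrow(X))
  lp <- .gp_laplace(K, y01)
  list(X = X, y01 = y01, ell = ell, sf2 = sf2, theta = th, laplace = lp,
       lml = if (is.null(lp)) -Inf else lp$lml)
}

# Predictive MI probability at new points (probit-squashed latent,
# MacKay-style variance correction).
.gp_ard_predict <- function(fit, Xnew) {
  lp <- fit$laplace
  if (is.null(lp)) return(rep(0.5, nrow(Xnew)))
  Ks <- .gp_kernel(fit$X, Xnew, fit$ell, fit$sf2)
  mu <- as.numeric(crossprod(Ks, lp$t - lp$pi_))
  v <- forwardsolve(t(lp$L), lp$sW * Ks)
  s2 <- pmax(fit$sf2 - colSums(v^2), 1e-10)
  stats::plogis(mu / sqrt(1 + pi * s2 / 8))
}
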