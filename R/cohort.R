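# Synthetic cohort generator. Two modes: "calibrated" draws per-group
# feature vectors from truncated multivariate normals whose marginal
# means/SDs are the printed cohort statistics (group marginals of the
# case-control table and the biomechanical feature statistics), with a
# documented default inter-feature correlation matrix; "pipeline" builds
# subjects by running the forward LV model at per-subject ground truth
# and reading the measurements back, optionally with observation noise.

.COHORT_FEATURES <- c("T_req", "T_a", "SBP", "EDV", "C_s", "T_a_norm",
                      "sigma_f_norm", "ESV", "GLS", "CS")

.default_feature_stats <- function() {
  list(
    healthy = list(
      mean = c(T_req = 157, T_a = 65.07, SBP = 144.6, EDV = 127,
               C_s = 0.42, T_a_norm = 0.45, sigma_f_norm = 0.35,
               ESV = 55, GLS = -21.4, CS = -0.18),
      sd = c(T_req = 25, T_a = 13, SBP = 31.2, EDV = 21,
             C_s = 0.04, T_a_norm = 0.06, sigma_f_norm = 0.05,
             ESV = 14, GLS = 4.1, CS = 0.02)),
    mi = list(
      mean = c(T_req = 156, T_a = 65.23, SBP = 118.6, EDV = 145.5,
               C_s = 0.44, T_a_norm = 0.55, sigma_f_norm = 0.47,
               ESV = 83, GLS = -11.5, CS = -0.16),
      sd = c(T_req = 27, T_a = 15, SBP = 16.4, EDV = 28,
             C_s = 0.13, T_a_norm = 0.07, sigma_f_norm = 0.09,
             ESV = 21, GLS = 3.9, CS = 0.01))
  )
}

# Default inter-feature correlations: a weak 0.1 background plus
# structured entries for mechanically related pairs (contractility drives
# tension; the two SBP-ratios inter-correlate and anti-correlate with
# SBP; volumes co-vary). A modelling assumption, fully user-overridable;
# verified positive definite.
.default_correlation <- function() {
  p <- length(.COHORT_FEATURES)
  R <- matrix(0.1, p, p, dimnames = list(.COHORT_FEATURES,
                                         .COHORT_FEATURES))
  diag(R) <- 1
  set_r <- function(i, j, v) {
    R[i, j] <<- v; R[j, i] <<- v
  }
  set_r("T_a", "T_a_norm", 0.7)
  set_r("T_a_norm", "SBP", -0.4)
  set_r("C_s", "T_a", 0.5)
  set_r("T_req", "C_s", -0.3)
  set_r("sigma_f_norm", "T_a_norm", 0.7)
  set_r("EDV", "ESV", 0.6)
  set_r("T_a", "sigma_f_norm", 0.5)
  set_r("sigma_f_norm", "SBP", -0.4)
  set_r("C_s", "T_a_norm", 0.35)
  set_r("T_req", "T_a", 0.4)
  set_r("C_s", "sigma_f_norm", 0.3)
  set_r("T_req", "T_a_norm", 0.3)
  R
}

# physical truncation bounds (beyond the +-4 SD envelope)
.feature_bounds <- function() {
  list(lower = c(T_req = 0, T_a = 0, SBP = 60, EDV = 40, C_s = 0.02,
                 T_a_norm = 0.05, sigma_f_norm = 0.05, ESV = 15,
                 GLS = -45, CS = -0.5),
       upper = c(T_req = 400, T_a = 200, SBP = 260, EDV = 400,
                 C_s = 0.98, T_a_norm = 1.5, sigma_f_norm = 1.5,
                 ESV = 350, GLS = 0, CS = 0))
}

#' Synthetic cohort configuration
#'
#' Configuration of the synthetic cohort generator: group sizes, per-group
#' marginal means and SDs of the cohort characteristics and biomechanical
#' features, the inter-feature correlation matrix, the population-based
#' end-diastolic pressures (8 mmHg healthy, 16 mmHg MI), and the outcome
#' correlation targets (six-month LVEF change vs contractility -0.79 and
#' vs end-systolic kinetics 0.70; six-month GLS vs baseline GLS 0.73).
#' The correlation matrix is a documented modelling assumption; if edits
#' make it non-positive-semidefinite it is repaired by nearest-PSD
#' projection with a warning.
#'
#' @param n_healthy,n_mi default group sizes.
#' @param feature_stats per-group lists with `mean`/`sd` vectors over the
#'   ten generator features.
#' @param correlation inter-feature correlation matrix (shared by both
#'   groups).
#' @param edp_healthy,edp_mi assumed end-diastolic pressures (mmHg).
#' @param outcome list of outcome targets (correlations, outcome means and
#'   SDs).
#' @param infarct_size_mean,infarct_size_sd infarct core size (fraction
#'   of wall volume) distribution for MI subjects.
#' @param remote_mean,remote_sd remote-segment count distribution for MI
#'   subjects (clipped to `[6, 24]`).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_healthy = 27, n_mi = 11,
                          feature_stats = .default_feature_stats(),
                          correlation = .default_correlation(),
                          edp_healthy = 8, edp_mi = 16,
                          outcome = list(r_dlvef_treq = -0.79,
                                         r_dlvef_cs = 0.70,
                                         r_gls6_gls = 0.73,
                                         dlvef_mean = 4, dlvef_sd = 8,
                                         gls6_mean = -14, gls6_sd = 4),
                          infarct_size_mean = 0.39,
                          infarct_size_sd = 0.06,
                          remote_mean = 13, remote_sd = 3) {
  for (gr in c("healthy", "mi")) {
    st <- feature_stats[[gr]]
    if (!all(.COHORT_FEATURES %in% names(st$mean)) ||
        !all(.COHORT_FEATURES %in% names(st$sd)))
      stop("feature_stats$", gr, " must name all of: ",
           paste(.COHORT_FEATURES, collapse = ", "))
    if (any(st$sd[.COHORT_FEATURES] <= 0))
      stop("all feature SDs must be > 0")
  }
  correlation <- as.matrix(correlation)
  if (!isTRUE(all.equal(correlation, t(correlation))) ||
      any(abs(diag(correlation) - 1) > 1e-8))
    stop("correlation must be a symmetric matrix with unit diagonal")
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    warning("correlation matrix is not positive semidefinite; ",
            "repairing by nearest-PSD projection")
    correlation <- as.matrix(Matrix::nearPD(correlation,
                                            corr = TRUE)$mat)
    dimnames(correlation) <- list(.COHORT_FEATURES, .COHORT_FEATURES)
  }
  structure(list(n_healthy = n_healthy, n_mi = n_mi,
                 feature_stats = feature_stats,
                 correlation = correlation,
                 edp_healthy = edp_healthy, edp_mi = edp_mi,
                 outcome = outcome,
                 infarct_size_mean = infarct_size_mean,
                 infarct_size_sd = infarct_size_sd,
                 remote_mean = remote_mean, remote_sd = remote_sd),
            class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort config:", x$n_healthy, "healthy /", x$n_mi,
      "MI; EDP", x$edp_healthy, "/", x$edp_mi, "mmHg\n")
  invisible(x)
}

# Correlated truncated-normal sampler: rejection at +-4 SD and at the
# physical bounds; EDV - ESV >= 10 ml enforced jointly.
.sample_group <- function(n, group, cfg) {
  st <- cfg$feature_stats[[group]]
  mu <- st$mean[.COHORT_FEATURES]
  sd <- st$sd[.COHORT_FEATURES]
  b <- .feature_bounds()
  lo <- pmax(mu - 4 * sd, b$lower[.COHORT_FEATURES])
  hi <- pmin(mu + 4 * sd, b$upper[.COHORT_FEATURES])
  L <- chol(cfg$correlation)
  p <- length(mu)
  out <- matrix(NA_real_, 0, p)
  guard <- 0L
  while (nrow(out) < n && guard < 200L) {
    guard <- guard + 1L
    m <- ceiling((n - nrow(out)) * 1.6) + 8L
    Z <- matrix(stats::rnorm(m * p), m, p) %*% L
    X <- sweep(sweep(Z, 2, sd, "*"), 2, mu, "+")
    colnames(X) <- .COHORT_FEATURES
    ok <- rowSums(sweep(X, 2, lo, "<") | sweep(X, 2, hi, ">")) == 0 &
      (X[, "EDV"] - X[, "ESV"] >= 10)
    out <- rbind(out, X[ok, , drop = FALSE])
  }
  if (nrow(out) < n)
    stop("impossible truncation bounds for group ", group)
  out <- out[seq_len(n), , drop = FALSE]
  df <- as.data.frame(out)
  df$EF <- (df$EDV - df$ESV) / df$EDV        # derived, not drawn
  df$sigma_f <- df$sigma_f_norm * df$SBP     # derived, not drawn
  df
}

#' Generate a synthetic cohort table
#'
#' Draws a cohort of healthy and MI subjects with the configured marginal
#' statistics (calibrated mode). Each subject carries a ground-truth
#' contractility and passive-scale, the group end-diastolic pressure, and
#' (MI only) an infarct size and remote-segment count. Reproducible given
#' `seed`.
#'
#' @param cfg a [cohort_config()].
#' @param n_healthy,n_mi group sizes (default from `cfg`).
#' @param seed integer seed.
#' @return A data.frame, one row per subject.
#' @export
generate_cohort <- function(cfg = cohort_config(),
                            n_healthy = cfg$n_healthy, n_mi = cfg$n_mi,
                            seed = 1) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(seed)
  h <- .sample_group(n_healthy, "healthy", cfg)
  m <- .sample_group(n_mi, "mi", cfg)
  h$label <- "healthy"; m$label <- "mi"
  h$EDP <- cfg$edp_healthy; m$EDP <- cfg$edp_mi
  h$infarct_size <- 0
  m$infarct_size <- pmin(pmax(
    stats::rnorm(n_mi, cfg$infarct_size_mean, cfg$infarct_size_sd),
    0.15), 0.6)
  h$n_remote <- 24L
  m$n_remote <- as.integer(pmin(pmax(round(
    stats::rnorm(n_mi, cfg$remote_mean, cfg$remote_sd)), 6L), 24L))
  out <- rbind(h, m)
  out$subject_id <- sprintf("S%03d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("subject_id", "label", "EDP", setdiff(names(out),
          c("subject_id", "label", "EDP")))]
}

.DATASET_COLUMNS <- list(
  D1 = c("T_req", "T_a", "SBP", "EDV", "C_s", "T_a_norm"),
  D2 = c("T_req", "T_a", "SBP", "EDV"),
  D3 = c("T_a", "EDV", "C_s", "T_a_norm")
)

#' Feature table for classification
#'
#' Produces the labelled feature table used by the classification study.
#' In `calibrated` mode features are drawn directly from the group-
#' conditional truncated multivariate normals of the configuration. In
#' `pipeline` mode each subject is built by [generate_subject()] (forward
#' model at ground truth), contractility is re-estimated by
#' [fit_contractility()] and the biomarkers come from
#' [summarize_biomarkers()]; this is slow and intended for small cohorts.
#'
#' Datasets: `D1` = contractility, active tension, SBP, EDV and the two
#' ratios (end-systolic kinetics, normalized active tension); `D2` = `D1`
#' without the ratios; `D3` = the ratios plus active tension and EDV
#' (no SBP, no contractility). `full` returns every generator column.
#'
#' @param cfg a [cohort_config()].
#' @param n_healthy,n_mi group sizes.
#' @param dataset `"D1"`, `"D2"`, `"D3"` or `"full"`.
#' @param mode `"calibrated"` or `"pipeline"`.
#' @param seed integer seed.
#' @param noise pipeline-mode observation-noise level (see
#'   [generate_subject()]).
#' @param geom_args pipeline-mode arguments passed to [lv_geometry()].
#' @return A data.frame with `subject_id`, `label` and feature columns.
#' @export
generate_feature_table <- function(cfg = cohort_config(),
                                   n_healthy = cfg$n_healthy,
                                   n_mi = cfg$n_mi,
                                   dataset = "D1",
                                   mode = c("calibrated", "pipeline"),
                                   seed = 1, noise = 0,
                                   geom_args = list()) {
  mode <- match.arg(mode)
  if (!dataset %in% c(names(.DATASET_COLUMNS), "full"))
    stop("unknown dataset '", dataset, "'; use D1, D2, D3 or full")
  if (mode == "calibrated") {
    tab <- generate_cohort(cfg, n_healthy, n_mi, seed = seed)
  } else {
    tab <- .pipeline_feature_table(cfg, n_healthy, n_mi, seed, noise,
                                   geom_args)
  }
  cols <- if (dataset == "full") setdiff(names(tab),
                                         c("subject_id", "label"))
          else .DATASET_COLUMNS[[dataset]]
  tab[, c("subject_id", "label", cols)]
}

.pipeline_feature_table <- function(cfg, n_healthy, n_mi, seed, noise,
                                    geom_args) {
  draws <- generate_cohort(cfg, n_healthy, n_mi, seed = seed)
  rows <- lapply(seq_len(nrow(draws)), function(i) {
    d <- draws[i, ]
    subj <- generate_subject(group = d$label, T_req = d$T_req,
                             sbp = d$SBP, noise = noise,
                             seed = seed + 1000L + i,
                             infarct_size = if (d$label == "mi")
                               d$infarct_size else NULL,
                             geom_args = geom_args, cfg = cfg)
    fit <- fit_contractility(subj$meas, subj$geom, subj$fibers,
                             subj$infarct, subj$params,
                             subj$active_cfg)
    bm <- subj$biomarkers
    data.frame(subject_id = d$subject_id, label = d$label,
               T_req = fit$T_req, T_a = bm$T_a, SBP = subj$sbp,
               EDV = subj$meas$edv, C_s = bm$C_s,
               T_a_norm = bm$T_a_norm, sigma_f_norm = bm$sigma_f_norm,
               ESV = subj$meas$esv, T_req_true = d$T_req)
  })
  do.call(rbind, rows)
}

#' Build one synthetic subject through the forward model
#'
#' Draws (or accepts) a subject's ground truth, runs the forward LV model
#' (diastolic inflation at the group end-diastolic pressure, systolic
#' contraction at the subject's systolic pressure) and assembles the
#' "measurement" block: EDV, ESV and the 24 diastolic and systolic
#' segmental strains, with optional Gaussian observation noise.
#'
#' @param group `"healthy"` or `"mi"`.
#' @param T_req ground-truth contractility (kPa); drawn from the group
#'   statistics when `NULL`.
#' @param sbp systolic pressure (mmHg); drawn when `NULL`.
#' @param passive_scale multiplier on the group-average stress-like
#'   passive coefficients (ground truth).
#' @param noise observation-noise level: volumes get relative noise
#'   `noise`, strains absolute noise `0.16 * noise` (0.16 is a typical
#'   strain magnitude). `noise = 0` returns the forward-model output
#'   exactly.
#' @param seed integer seed (used for draws and noise).
#' @param infarct_size MI core size as wall-volume fraction (MI only).
#' @param geom_args arguments passed to [lv_geometry()].
#' @param cfg a [cohort_config()].
#' @return A list of class `synthetic_subject` with the model objects
#'   (`geom`, `fibers`, `infarct`, `params`, `active_cfg`), the states,
#'   the [measurement_set()] and the ground `truth`.
#' @export
generate_subject <- function(group = c("healthy", "mi"), T_req = NULL,
                             sbp = NULL, passive_scale = 1, noise = 0,
                             seed = 1, infarct_size = NULL,
                             geom_args = list(), cfg = cohort_config()) {
  group <- match.arg(group)
  set.seed(seed)
  st <- cfg$feature_stats[[group]]
  if (is.null(T_req)) T_req <- max(stats::rnorm(1, st$mean["T_req"],
                                                st$sd["T_req"]), 1)
  if (is.null(sbp)) sbp <- max(stats::rnorm(1, st$mean["SBP"],
                                            st$sd["SBP"]), 70)
  geom <- do.call(lv_geometry, geom_args)
  fibers <- generate_fibers(geom)
  infarct <- NULL
  if (group == "mi") {
    if (is.null(infarct_size)) infarct_size <- cfg$infarct_size_mean
    infarct <- build_infarct(geom, target_size = infarct_size)
  }
  base <- if (group == "mi") ho_params_mi_remote() else
    ho_params_healthy()
  params <- .scale_params(base, q = passive_scale)
  edp <- if (group == "mi") cfg$edp_mi else cfg$edp_healthy
  active_cfg <- active_config(T_req = T_req)
  ed <- solve_diastole(geom, fibers, infarct, params, edp = edp)
  es <- solve_systole(geom, fibers, infarct, params, active_cfg,
                      sbp = sbp, ed_state = ed)
  add_noise <- function(x, sd_abs) x + stats::rnorm(length(x), 0, sd_abs)
  edv <- ed$volume; esv <- es$volume
  sd_dia <- ed$strain; sd_sys <- es$strain
  if (noise > 0) {
    edv <- add_noise(edv, noise * edv)
    esv <- add_noise(esv, noise * esv)
    sd_dia <- add_noise(sd_dia, 0.16 * noise)
    sd_sys <- add_noise(sd_sys, 0.16 * noise)
  }
  seg_class <- if (is.null(infarct)) rep("remote", geom$n_regions) else
    infarct$region_class
  meas <- measurement_set(edv = edv, esv = max(esv, 1),
                          strain_dia = sd_dia, strain_sys = sd_sys,
                          seg_class = seg_class, edp = edp, sbp = sbp)
  structure(list(group = group, sbp = sbp, edp = edp,
                 geom = geom, fibers = fibers, infarct = infarct,
                 params = params, active_cfg = active_cfg,
                 ed_state = ed, sys_state = es, meas = meas,
                 biomarkers = summarize_biomarkers(es, sbp),
                 truth = list(T_req = T_req,
                              passive_scale = passive_scale)),
            class = "synthetic_subject")
}

#' @export
print.synthetic_subject <- function(x, ...) {
  cat("Synthetic", x$group, "subject: EDV", round(x$meas$edv, 1),
      "ml, ESV", round(x$meas$esv, 1), "ml, true T_req",
      round(x$truth$T_req, 1), "kPa\n")
  invisible(x)
}

#' Six-month outcome generator
#'
#' Attaches six-month outcomes to the MI rows of a feature table. The
#' LVEF change at six months is a linear combination of the standardized
#' contractility (negative loading) and end-systolic kinetics (positive
#' loading) plus Gaussian noise, with loadings solved so the population
#' correlations equal the configured targets (-0.79 with contractility,
#' 0.70 with kinetics). Six-month GLS is correlated with baseline GLS at
#' the configured 0.73 analogously. Standardization uses the configured
#' population moments, so the population correlations are exact.
#'
#' @param cfg a [cohort_config()].
#' @param features a feature table containing MI rows with `T_req` and
#'   `C_s` (and optionally `GLS`).
#' @param seed integer seed.
#' @return The MI rows of `features` with columns `dLVEF6` (percentage
#'   points) and, if baseline GLS is present, `GLS6` appended.
#' @export
generate_outcomes <- function(cfg = cohort_config(), features,
                              seed = 1) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (!all(c("T_req", "C_s") %in% names(features)))
    stop("features must include T_req and C_s")
  mi <- features[features$label == "mi", , drop = FALSE]
  if (nrow(mi) == 0) stop("no MI rows in features")
  oc <- cfg$outcome
  r1 <- oc$r_dlvef_treq; r2 <- oc$r_dlvef_cs
  rho <- cfg$correlation["T_req", "C_s"]
  tri <- matrix(c(1, rho, r1, rho, 1, r2, r1, r2, 1), 3, 3)
  if (min(eigen(tri, symmetric = TRUE, only.values = TRUE)$values) <
      -1e-8)
    stop("infeasible correlation triple: corr(T_req, C_s) = ", rho,
         ", corr(dLVEF6, T_req) = ", r1, ", corr(dLVEF6, C_s) = ", r2,
         " is not positive semidefinite")
  b1 <- (r1 - rho * r2) / (1 - rho^2)
  b2 <- (r2 - rho * r1) / (1 - rho^2)
  s2 <- 1 - (b1^2 + b2^2 + 2 * b1 * b2 * rho)
  if (s2 < 0) stop("infeasible correlation triple: noise variance < 0")
  st <- cfg$feature_stats$mi
  set.seed(seed)
  z1 <- (mi$T_req - st$mean["T_req"]) / st$sd["T_req"]
  z2 <- (mi$C_s - st$mean["C_s"]) / st$sd["C_s"]
  y <- b1 * z1 + b2 * z2 + sqrt(s2) * stats::rnorm(nrow(mi))
  mi$dLVEF6 <- oc$dlvef_mean + oc$dlvef_sd * y
  if ("GLS" %in% names(mi)) {
    zg <- (mi$GLS - st$mean["GLS"]) / st$sd["GLS"]
    r3 <- oc$r_gls6_gls
    yg <- r3 * zg + sqrt(1 - r3^2) * stats::rnorm(nrow(mi))
    mi$GLS6 <- oc$gls6_mean + oc$gls6_sd * yg
  }
  mi
}
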