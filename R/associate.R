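# Association analysis (baseline biomarkers vs six-month outcomes) and
# group comparisons, plus the end-to-end pipeline driver.

#' Pearson association with Fisher-z confidence interval
#'
#' Pearson correlation between a baseline variable and an outcome with
#' the 95% confidence interval and two-sided p-value from the Fisher
#' z-transform. Significance is flagged at the 0.05 level.
#'
#' @param x,y numeric vectors (`n >= 3`, finite).
#' @param conf confidence level.
#' @param names optional c(baseline, outcome) names for the row.
#' @return A one-row data.frame: `baseline`, `outcome`, `r`, `ci_lo`,
#'   `ci_hi`, `p`, `n`, `significant`.
#' @export
pearson_assoc <- function(x, y, conf = 0.95, names = c("x", "y")) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance")
  r <- stats::cor(x, y)
  z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- tanh(c(z - q * se, z + q * se))
  p <- 2 * stats::pnorm(-abs(z) / se)
  data.frame(baseline = names[1], outcome = names[2], r = r,
             ci_lo = ci[1], ci_hi = ci[2], p = p, n = n,
             significant = p <= 0.05)
}

#' Two-group comparison
#'
#' Descriptive statistics and a two-sample t-test between the healthy
#' and MI groups. The default is the pooled-variance Student's t-test;
#' `welch = TRUE` switches to the Welch variant.
#'
#' @param healthy,mi numeric vectors (`n >= 2` each).
#' @param welch use the Welch (unequal-variance) t-test.
#' @return A list with the group means and SDs, `t`, `df` and `p`.
#' @export
group_compare <- function(healthy, mi, welch = FALSE) {
  healthy <- healthy[is.finite(healthy)]; mi <- mi[is.finite(mi)]
  if (length(healthy) < 2 || length(mi) < 2)
    stop("both groups need at least 2 observations")
  if (stats::sd(healthy) == 0 && stats::sd(mi) == 0 &&
      mean(healthy) == mean(mi)) {
    tt <- list(statistic = c(t = 0), parameter = c(df =
      length(healthy) + length(mi) - 2), p.value = 1)
  } else {
    tt <- stats::t.test(healthy, mi, var.equal = !welch)
  }
  list(mean_healthy = mean(healthy), sd_healthy = stats::sd(healthy),
       mean_mi = mean(mi), sd_mi = stats::sd(mi),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Association table between baseline biomarkers and outcomes
#'
#' Builds the association table: every requested baseline variable
#' against every outcome column, one [pearson_assoc()] row each. No
#' multiple-testing adjustment is applied (noted in the table attribute).
#'
#' @param data data.frame holding baselines and outcomes (MI subjects).
#' @param baselines,outcomes column names.
#' @return A data.frame of association rows.
#' @export
association_table <- function(data,
                              baselines = c("EF", "GLS", "CS", "T_req",
                                            "T_a", "sigma_f",
                                            "sigma_f_norm", "T_a_norm",
                                            "C_s"),
                              outcomes = c("dLVEF6", "GLS6")) {
  baselines <- intersect(baselines, names(data))
  outcomes <- intersect(outcomes, names(data))
  if (!length(baselines) || !length(outcomes))
    stop("no baseline/outcome columns found")
  rows <- list()
  for (oc in outcomes) for (bl in baselines)
    rows[[length(rows) + 1L]] <- pearson_assoc(data[[bl]], data[[oc]],
                                               names = c(bl, oc))
  out <- do.call(rbind, rows)
  attr(out, "adjustment") <- "none"
  out
}

#' End-to-end synthetic study pipeline
#'
#' Runs the full desk-scale study on a synthetic cohort: feature
#' generation (calibrated or pipeline mode), six-month outcome
#' generation, the three-dataset classification study, group
#' comparisons and the association table. Writes `cohort.csv`,
#' `features_D*.csv`, `outcomes.csv`, `associations.csv`,
#' `metrics.csv` and a machine-readable `summary.json` when `out_dir`
#' is given. Fully reproducible from the configuration and seed.
#'
#' @param cfg a [cohort_config()].
#' @param mode `"calibrated"` (statistical emulator) or `"pipeline"`
#'   (forward model + inverse estimation; slow, small cohorts only).
#' @param seed master seed.
#' @param out_dir optional output directory.
#' @param noise pipeline-mode observation noise.
#' @param classify run the classification study (can be disabled for
#'   speed).
#' @param geom_args pipeline-mode geometry arguments.
#' @return An object of class `lv_pipeline` with elements `cohort`,
#'   `features` (list D1/D2/D3), `outcomes`, `study`, `comparisons`,
#'   `associations` and `summary`.
#' @export
run_pipeline <- function(cfg = cohort_config(),
                         mode = c("calibrated", "pipeline"), seed = 1,
                         out_dir = NULL, noise = 0, classify = TRUE,
                         geom_args = list()) {
  mode <- match.arg(mode)
  t0 <- Sys.time()
  cohort <- generate_cohort(cfg, seed = seed)
  full <- generate_feature_table(cfg, dataset = "full", mode = mode,
                                 seed = seed, noise = noise,
                                 geom_args = geom_args)
  features <- lapply(names(.DATASET_COLUMNS), function(ds)
    full[, c("subject_id", "label", .DATASET_COLUMNS[[ds]])])
  names(features) <- names(.DATASET_COLUMNS)
  outcomes <- generate_outcomes(cfg, full, seed = seed + 1L)
  study <- if (classify) run_study(features, seed = seed) else NULL
  comparisons <- lapply(
    stats::setNames(nm = intersect(c("T_req", "T_a", "T_a_norm",
                                     "sigma_f_norm", "C_s"),
                                   names(full))),
    function(v) group_compare(full[[v]][full$label == "healthy"],
                              full[[v]][full$label == "mi"]))
  oc_data <- outcomes
  if ("EF" %in% names(full))
    oc_data$EF <- full$EF[match(oc_data$subject_id, full$subject_id)]
  assoc <- association_table(oc_data)
  summary <- list(
    seed = seed, mode = mode,
    n_healthy = sum(full$label == "healthy"),
    n_mi = sum(full$label == "mi"),
    auroc = if (!is.null(study)) as.list(study$auroc) else NULL,
    method_ranking = if (!is.null(study)) study$ranking$method else
      NULL,
    group_p = lapply(comparisons, `[[`, "p"),
    associations = stats::setNames(assoc$r, paste(assoc$baseline,
                                                  assoc$outcome,
                                                  sep = "_vs_")),
    elapsed_s = as.numeric(Sys.time() - t0, units = "secs"))
  res <- structure(list(cohort = cohort, features = features,
                        outcomes = outcomes, study = study,
                        comparisons = comparisons,
                        associations = assoc, summary = summary),
                   class = "lv_pipeline")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(cohort, file.path(out_dir, "cohort.csv"),
                     row.names = FALSE)
    for (ds in names(features))
      utils::write.csv(features[[ds]],
                       file.path(out_dir, paste0("features_", ds,
                                                 ".csv")),
                       row.names = FALSE)
    utils::write.csv(outcomes, file.path(out_dir, "outcomes.csv"),
                     row.names = FALSE)
    utils::write.csv(assoc, file.path(out_dir, "associations.csv"),
                     row.names = FALSE)
    if (!is.null(study))
      utils::write.csv(study$metrics, file.path(out_dir, "metrics.csv"),
                       row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}

#' @export
print.lv_pipeline <- function(x, ...) {
  cat("Synthetic study pipeline (", x$summary$mode, " mode, seed ",
      x$summary$seed, "): ", x$summary$n_healthy, " healthy / ",
      x$summary$n_mi, " MI\n", sep = "")
  if (!is.null(x$study))
    cat("Hull AUROC:", paste(names(x$study$auroc),
                             round(x$study$auroc, 3), sep = " = ",
                             collapse = ", "), "\n")
  cat("corr(T_req, dLVEF6) =",
      round(x$associations$r[x$associations$baseline == "T_req" &
                               x$associations$outcome == "dLVEF6"], 3),
      "; corr(C_s, dLVEF6) =",
      round(x$associations$r[x$associations$baseline == "C_s" &
                               x$associations$outcome == "dLVEF6"], 3),
      "\n")
  invisible(x)
}
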