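# Synthetic cohort generator: marginal calibration, dataset layouts,
# seeded determinism, outcome wiring and pipeline-mode consistency.

test_that("group marginals reproduce the configured statistics", {
  tab <- generate_cohort(n_healthy = 10000, n_mi = 10000, seed = 4)
  h <- tab[tab$label == "healthy", ]
  m <- tab[tab$label == "mi", ]
  expect_lt(abs(mean(h$SBP) - 144.6), 1)
  expect_lt(abs(mean(m$SBP) - 118.6), 1)
  # a few more marginals within 3 standard errors (plus truncation slack)
  for (v in c("T_req", "EDV", "C_s")) {
    st <- cohort_config()$feature_stats
    for (gr in c("healthy", "mi")) {
      x <- tab[tab$label == gr, v]
      se <- st[[gr]]$sd[v] / sqrt(length(x))
      expect_lt(abs(mean(x) - st[[gr]]$mean[v]), 3 * se + 0.02 *
                  st[[gr]]$sd[v])
      expect_lt(abs(stats::sd(x) / st[[gr]]$sd[v] - 1), 0.05)
    }
  }
  # derived ejection fraction lands on the printed group means
  expect_lt(abs(mean(h$EF) - 0.57), 0.01)
  expect_lt(abs(mean(m$EF) - 0.43), 0.01)
})

test_that("same seed gives byte-identical cohorts, different seeds do
           not", {
  a <- generate_cohort(n_healthy = 40, n_mi = 15, seed = 9)
  b <- generate_cohort(n_healthy = 40, n_mi = 15, seed = 9)
  c <- generate_cohort(n_healthy = 40, n_mi = 15, seed = 10)
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("dataset layouts match the study definitions", {
  t1 <- generate_feature_table(n_healthy = 10, n_mi = 5, dataset = "D1",
                               seed = 2)
  t2 <- generate_feature_table(n_healthy = 10, n_mi = 5, dataset = "D2",
                               seed = 2)
  t3 <- generate_feature_table(n_healthy = 10, n_mi = 5, dataset = "D3",
                               seed = 2)
  expect_setequal(setdiff(names(t1), c("subject_id", "label")),
                  c("T_req", "T_a", "SBP", "EDV", "C_s", "T_a_norm"))
  # D2 lacks the two ratio features
  d2 <- setdiff(names(t2), c("subject_id", "label"))
  expect_length(d2, 4)
  expect_false(any(c("C_s", "T_a_norm") %in% d2))
  expect_setequal(setdiff(names(t3), c("subject_id", "label")),
                  c("T_a", "EDV", "C_s", "T_a_norm"))
  expect_error(generate_feature_table(dataset = "D9"), "unknown")
})

test_that("outcome generator hits the configured population
           correlations", {
  tab <- generate_feature_table(n_healthy = 10, n_mi = 100000,
                                dataset = "full", seed = 6)
  oc <- generate_outcomes(features = tab, seed = 8)
  expect_lt(abs(stats::cor(oc$T_req, oc$dLVEF6) - (-0.79)), 0.01)
  expect_lt(abs(stats::cor(oc$C_s, oc$dLVEF6) - 0.70), 0.01)
  expect_lt(abs(stats::cor(oc$GLS, oc$GLS6) - 0.73), 0.01)
  # joint permutation of subjects leaves correlations unchanged
  idx <- sample(nrow(oc))
  expect_equal(stats::cor(oc$T_req[idx], oc$dLVEF6[idx]),
               stats::cor(oc$T_req, oc$dLVEF6))
})

test_that("an infeasible outcome correlation triple is rejected by
           name", {
  R <- lvbiomech:::.default_correlation()
  R["T_req", "C_s"] <- R["C_s", "T_req"] <- 0.2
  cfg <- suppressWarnings(cohort_config(correlation = R))
  tab <- generate_feature_table(cfg, n_healthy = 5, n_mi = 30,
                                dataset = "full", seed = 3)
  expect_error(generate_outcomes(cfg, tab), "T_req")
})

test_that("editing the correlation matrix into non-PSD triggers the
           repair warning", {
  R <- lvbiomech:::.default_correlation()
  R["SBP", "EDV"] <- R["EDV", "SBP"] <- -0.95
  R["SBP", "ESV"] <- R["ESV", "SBP"] <- 0.95
  expect_warning(cohort_config(correlation = R), "nearest-PSD")
})

test_that("remote-segment counts and infarct sizes stay in range", {
  tab <- generate_cohort(n_healthy = 5, n_mi = 400, seed = 12)
  m <- tab[tab$label == "mi", ]
  expect_true(all(m$n_remote >= 6 & m$n_remote <= 24))
  expect_lt(abs(mean(m$n_remote) - 13), 1)
  expect_true(all(m$infarct_size > 0.1 & m$infarct_size < 0.65))
  expect_true(all(tab$EDP %in% c(8, 16)))
  expect_true(all(tab$EDP[tab$label == "mi"] == 16))
})

test_that("noise-free pipeline subject reproduces its forward model
           exactly and its contractility is recoverable", {
  subj <- generate_subject("healthy", T_req = 157, sbp = 144.6,
                           noise = 0, seed = 5,
                           geom_args = list(n_layers = 3, n_theta = 6,
                                            n_mu = 12))
  expect_equal(subj$meas$edv, subj$ed_state$volume)
  expect_equal(subj$meas$esv, subj$sys_state$volume)
  expect_equal(subj$meas$strain_sys, subj$sys_state$strain)
  fit <- fit_contractility(subj$meas, subj$geom, subj$fibers,
                           subj$infarct, subj$params, subj$active_cfg)
  expect_lt(abs(fit$T_req - 157), 1)
})
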