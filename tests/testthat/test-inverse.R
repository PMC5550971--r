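# Inverse problems: objective arithmetic and restriction rules,
# contractility recovery, passive-scale recovery.

test_that("objective is zero at a perfect match and scales mismatches by
           the documented weights", {
  s <- rep(-0.15, 24)
  expect_equal(fit_objective(s, 120, s, 120), 0)
  s2 <- s; s2[5] <- s2[5] + 0.01
  # one strain off by 0.01 -> (0.01 / 0.05)^2 = 1e-4 * 400
  expect_equal(fit_objective(s, 120, s2, 120), 1e-4 * (1 / 0.05^2))
  expect_equal(fit_objective(s, 120, s, 125), (5 / 10)^2)
})

test_that("MI-mode objective uses remote segments only", {
  cls <- rep(c("remote", "infarct", "transition"), each = 8)
  s_meas <- rep(-0.15, 24)
  s_mod <- s_meas
  s_mod[cls != "remote"] <- 99  # garbage outside remote segments
  expect_equal(fit_objective(s_meas, 120, s_mod, 120, mode = "mi",
                             seg_class = cls), 0)
  expect_equal(sum(cls == "remote"), 8)
  expect_error(fit_objective(s_meas, 120, s_mod, 120, mode = "mi",
                             seg_class = rep("infarct", 24)),
               "remote")
  expect_error(fit_objective(s_meas, 120, s_mod, 120, mode = "mi"),
               "seg_class")
})

test_that("contractility is recovered from noise-free healthy
           measurements", {
  run <- fx_healthy_run()
  meas <- measurement_set(edv = run$ed$volume, esv = run$es$volume,
                          strain_dia = run$ed$strain,
                          strain_sys = run$es$strain,
                          edp = run$edp, sbp = run$sbp)
  fit <- fit_contractility(meas, run$geom, run$fibers, NULL,
                           run$params, run$cfg)
  expect_true(fit$converged)
  expect_lt(abs(fit$T_req - 157), 1)
  # the objective trace has its minimum at the recovered value
  tr <- fit$trace
  expect_equal(unname(tr[which.min(tr[, "objective"]), "T_req"]),
               fit$T_req, tolerance = 1e-6)
})

test_that("zero-contractility measurements recover zero", {
  run <- fx_healthy_run()
  cfg0 <- active_config(T_req = 0)
  es0 <- solve_systole(run$geom, run$fibers, NULL, run$params, cfg0,
                       sbp = run$sbp, ed_state = run$ed)
  # without contraction the pressurized chamber does not eject, so the
  # "measurements" describe a non-contracting ventricle (warned about)
  expect_warning(
    meas <- measurement_set(edv = run$ed$volume,
                            esv = es0$volume,
                            strain_dia = run$ed$strain,
                            strain_sys = es0$strain,
                            edp = run$edp, sbp = run$sbp),
    "not a contracting")
  fit <- fit_contractility(meas, run$geom, run$fibers, NULL,
                           run$params, run$cfg, bounds = c(0, 400))
  expect_lt(fit$T_req, 1)
})

test_that("passive fit started at the truth converges immediately with
           near-zero objective", {
  run <- fx_healthy_run()
  meas <- measurement_set(edv = run$ed$volume, esv = run$es$volume,
                          strain_dia = run$ed$strain,
                          strain_sys = run$es$strain,
                          edp = run$edp, sbp = run$sbp)
  fit <- fit_passive(meas, run$geom, run$fibers, NULL,
                     init = run$params)
  expect_true(fit$converged)
  expect_lt(fit$objective, 1e-4)
  expect_equal(unname(fit$scales), c(1, 1), tolerance = 0.02)
})

test_that("passive fit recovers the myofiber-direction stiffness from
           scaled-truth measurements", {
  run <- fx_healthy_run()
  truth <- lvbiomech:::.scale_params(ho_params_healthy(), q = 1.3)
  ed <- solve_diastole(run$geom, run$fibers, NULL, truth, edp = 8)
  meas <- measurement_set(edv = ed$volume, esv = ed$volume * 0.5,
                          strain_dia = ed$strain,
                          strain_sys = rep(-0.1, 24),
                          edp = 8, sbp = 144.6)
  fit <- fit_passive(meas, run$geom, run$fibers, NULL,
                     init = ho_params_healthy())
  stiff <- function(p) {
    d <- deformation(diag(c(1.1, 1 / sqrt(1.1), 1 / sqrt(1.1))))
    fiber_stress(passive_cauchy_stress(p, d), d)
  }
  expect_lt(abs(stiff(fit$params) / stiff(truth) - 1), 0.05)
})

test_that("passive fit responds monotonically to the filling pressure
           used to generate the data", {
  run <- fx_healthy_run()
  fit_scale_at <- function(edp) {
    ed <- solve_diastole(run$geom, run$fibers, NULL,
                         ho_params_healthy(), edp = edp)
    meas <- measurement_set(edv = ed$volume, esv = ed$volume * 0.5,
                            strain_dia = ed$strain,
                            strain_sys = rep(-0.1, 24),
                            edp = 8, sbp = 144.6)
    # data generated at higher pressure but fitted assuming 8 mmHg:
    # the apparent stiffness scale must drop below 1
    fit_passive(meas, run$geom, run$fibers, NULL,
                init = ho_params_healthy())$scales[["global"]]
  }
  expect_lt(fit_scale_at(16), 1)
})

test_that("contractility recovery tolerates small observation noise", {
  run <- fx_healthy_run()
  set.seed(21)
  errs <- vapply(1:4, function(r) {
    truth <- stats::runif(1, 100, 220)
    cfgr <- active_config(T_req = truth)
    es <- solve_systole(run$geom, run$fibers, NULL, run$params, cfgr,
                        sbp = run$sbp, ed_state = run$ed)
    meas <- measurement_set(
      edv = run$ed$volume * (1 + stats::rnorm(1, 0, 0.01)),
      esv = es$volume * (1 + stats::rnorm(1, 0, 0.01)),
      strain_dia = run$ed$strain + stats::rnorm(24, 0, 0.0016),
      strain_sys = es$strain + stats::rnorm(24, 0, 0.0016),
      edp = run$edp, sbp = run$sbp)
    fit <- fit_contractility(meas, run$geom, run$fibers, NULL,
                             run$params, run$cfg, tol = 0.2)
    abs(fit$T_req - truth)
  }, numeric(1))
  expect_lt(stats::median(errs), 5)
})
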