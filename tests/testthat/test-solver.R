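# Reduced equilibrium solver: loading monotonicity, incompressibility,
# resolution convergence, infarct mechanics and the biomarker summary.

test_that("zero end-diastolic pressure leaves the reference state", {
  run <- fx_healthy_run()
  st <- solve_diastole(run$geom, run$fibers, NULL, run$params, edp = 0)
  expect_equal(st$volume, run$geom$cavity_volume_ref)
  expect_equal(max(abs(st$strain)), 0)
})

test_that("cavity volume increases monotonically with filling pressure", {
  run <- fx_healthy_run()
  v4 <- solve_diastole(run$geom, run$fibers, NULL, run$params,
                       edp = 4)$volume
  v8 <- run$ed$volume
  expect_gt(v4, run$geom$cavity_volume_ref)
  expect_gt(v8, v4)
})

test_that("converged states are incompressible to solver tolerance", {
  run <- fx_healthy_run()
  mi <- fx_mi_run()
  expect_lt(max(abs(run$ed$J - 1)), 1e-3)
  expect_lt(max(abs(run$es$J - 1)), 1e-3)
  expect_lt(max(abs(mi$es$J - 1)), 1e-3)
})

test_that("default-resolution volumes agree with a doubled-resolution
           solve to within 1%", {
  run <- fx_healthy_run()
  g1 <- lv_geometry()
  f1 <- generate_fibers(g1)
  ed1 <- solve_diastole(g1, f1, NULL, run$params, edp = 8)
  es1 <- solve_systole(g1, f1, NULL, run$params, run$cfg,
                       sbp = run$sbp, ed_state = ed1)
  g2 <- lv_geometry(n_layers = 8, n_theta = 24, n_mu = 28)
  f2 <- generate_fibers(g2)
  ed2 <- solve_diastole(g2, f2, NULL, run$params, edp = 8)
  es2 <- solve_systole(g2, f2, NULL, run$params, run$cfg,
                       sbp = run$sbp, ed_state = ed2)
  expect_lt(abs(ed1$volume / ed2$volume - 1), 0.01)
  expect_lt(abs(es1$volume / es2$volume - 1), 0.01)
})

test_that("end-systolic volume decreases monotonically in
           contractility", {
  run <- fx_healthy_run()
  esv <- vapply(c(60, 157, 280), function(Tr) {
    cfg <- active_config(T_req = Tr)
    solve_systole(run$geom, run$fibers, NULL, run$params, cfg,
                  sbp = run$sbp, ed_state = run$ed)$volume
  }, numeric(1))
  expect_true(all(diff(esv) < 0))
  expect_lt(esv[2], run$ed$volume)  # the heart actually ejects
})

test_that("no systolic load leaves the end-diastolic configuration", {
  run <- fx_healthy_run()
  cfg0 <- active_config(T_req = 0)
  st <- solve_systole(run$geom, run$fibers, NULL, run$params, cfg0,
                      sbp = 0, ed_state = run$ed)
  expect_equal(st$volume, run$ed$volume)
  expect_equal(max(abs(st$strain)), 0)
})

test_that("without contraction the pressurized wall does not shorten", {
  run <- fx_healthy_run()
  cfg0 <- active_config(T_req = 0)
  st <- solve_systole(run$geom, run$fibers, NULL, run$params, cfg0,
                      sbp = run$sbp, ed_state = run$ed)
  expect_gte(mean(st$lambda_f - run$ed$lambda_f), 0)
})

test_that("the non-contracting infarct shortens less than remote
           myocardium", {
  mi <- fx_mi_run()
  cls <- mi$infarct$region_class
  expect_gt(mean(mi$es$strain[cls == "infarct"]),
            mean(mi$es$strain[cls == "remote"]))
  # remote myocardium shortens (negative circumferential strain)
  expect_lt(mean(mi$es$strain[cls == "remote"]), -0.05)
})

test_that("a large infarct reduces systolic twist", {
  run <- fx_healthy_run()
  mi <- fx_mi_run()
  expect_gt(max(abs(run$es$twist_deg)), max(abs(mi$es$twist_deg)))
})

test_that("biomarker summary averages functional myocardium and obeys
           the stress decomposition", {
  run <- fx_healthy_run()
  bm <- summarize_biomarkers(run$es, run$sbp)
  expect_gt(bm$T_a, 0)
  expect_equal(bm$T_a_norm, bm$T_a / run$sbp)
  expect_equal(bm$sigma_f_norm, bm$sigma_f / run$sbp)
  # zero active state reports zero tension
  cfg0 <- active_config(T_req = 0)
  st0 <- solve_systole(run$geom, run$fibers, NULL, run$params, cfg0,
                       sbp = 0, ed_state = run$ed)
  bm0 <- summarize_biomarkers(st0, run$sbp)
  expect_equal(bm0$T_a, 0)
  expect_equal(bm0$T_a_norm, 0)
})

test_that("solver fiber-stress field matches the constitutive module at
           sampled points (dual route)", {
  run <- fx_healthy_run()
  es <- run$es
  ctx <- lvbiomech:::.solver_context(run$geom, run$fibers, NULL,
                                     run$params)
  kin <- lvbiomech:::.kinematics(ctx, es$dofs)
  set.seed(3)
  for (i in sample(ctx$n, 8)) {
    F <- matrix(c(kin$F11[i], 0, 0,
                  kin$F12[i], kin$F22[i], 0,
                  kin$F13[i], kin$F23[i], kin$F33[i]), 3, 3)
    d <- deformation(F, ctx$f0[i, ], ctx$s0[i, ])
    sig_f <- fiber_stress(passive_cauchy_stress(run$params, d,
                                                M = ctx$M[i]), d)
    expect_equal(es$sigma_f[i] - es$T_a[i], sig_f, tolerance = 1e-6)
  }
})
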