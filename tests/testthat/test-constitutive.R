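# Passive law: energy/stress consistency, tension-only anisotropy,
# infarct stiffening, objectivity; active stress construction and the
# SBP normalization.

test_that("undeformed reference state carries zero energy and stress", {
  p <- ho_params_healthy()
  d <- deformation(diag(3))
  expect_equal(passive_energy(p, d, M = 0), 0)
  expect_equal(passive_cauchy_stress(p, d, M = 0),
               matrix(0, 3, 3), tolerance = 1e-12)
})

test_that("fully infarcted scar is exactly 50 times stiffer", {
  p <- ho_params_healthy()
  d <- fx_fs_shear(0.2)
  e0 <- passive_energy(p, d, M = 0)
  e1 <- passive_energy(p, d, M = 1)
  expect_gt(e0, 0)
  expect_equal(e1 / e0, 50, tolerance = 1e-12)
  # linear in M in between (isochoric deformation)
  for (M in c(0.1, 0.25, 0.5, 0.9))
    expect_equal(passive_energy(p, d, M = M) / e0, 1 + 49 * M,
                 tolerance = 1e-12)
})

test_that("energy at uniaxial fiber stretch matches an independent
           term-by-term oracle", {
  p <- ho_params_healthy()
  lam <- 1.1
  F <- diag(c(lam, 1 / sqrt(lam), 1 / sqrt(lam)))
  d <- deformation(F)
  # independent evaluation from the invariant definitions
  I1 <- lam^2 + 2 / lam
  I4f <- lam^2
  I4s <- 1 / lam      # compressed: sheet term off
  I8 <- 0
  oracle <- p$a / (2 * p$b) * (exp(p$b * (I1 - 3)) - 1) +
    p$a_f / (2 * p$b_f) * (exp(p$b_f * (I4f - 1)^2) - 1)
  expect_equal(passive_energy(p, d), oracle, tolerance = 1e-12)
})

test_that("Cauchy stress equals the finite-difference derivative of the
           energy over random admissible deformations", {
  set.seed(42)
  p <- ho_params_healthy()
  h <- 1e-6
  for (rep in 1:100) {
    d <- fx_random_deformation()
    M <- stats::runif(1)
    sig <- passive_cauchy_stress(p, d, M = M)
    expect_equal(sig, t(sig), tolerance = 1e-10)
    # first Piola-Kirchhoff by central differences, pushed forward
    P <- matrix(0, 3, 3)
    for (i in 1:3) for (j in 1:3) {
      Fp <- d$F; Fp[i, j] <- Fp[i, j] + h
      Fm <- d$F; Fm[i, j] <- Fm[i, j] - h
      P[i, j] <- (passive_energy(p, deformation(Fp), M = M) -
                    passive_energy(p, deformation(Fm), M = M)) / (2 * h)
    }
    sig_fd <- P %*% t(d$F) / d$J
    sig_fd <- (sig_fd + t(sig_fd)) / 2
    expect_equal(sig, sig_fd, tolerance = 1e-4)
  }
})

test_that("anisotropic terms only bear load when taut", {
  p <- ho_params_healthy()
  p_stiff_f <- ho_params(p$a, p$b, 1000, p$b_f, p$a_s, p$b_s, p$a_fs,
                         p$b_fs)
  lam <- 0.95  # fiber compressed
  F <- diag(c(lam, 1 / sqrt(lam), 1 / sqrt(lam)))
  d <- deformation(F)
  expect_equal(passive_energy(p, d), passive_energy(p_stiff_f, d))
  expect_equal(passive_cauchy_stress(p, d),
               passive_cauchy_stress(p_stiff_f, d))
})

test_that("energy is objective under superposed rotations", {
  set.seed(7)
  p <- ho_params_mi_remote()
  for (rep in 1:20) {
    d <- fx_random_deformation()
    Q <- fx_random_rotation()
    d_rot <- deformation(Q %*% d$F, d$f0, d$s0)
    expect_equal(passive_energy(p, d_rot), passive_energy(p, d),
                 tolerance = 1e-10)
  }
})

test_that("invalid deformations and parameters are rejected", {
  p <- ho_params_healthy()
  expect_error(deformation(matrix(0, 3, 3)), "det")
  expect_error(deformation(diag(3) * NA), "finite")
  expect_error(deformation(diag(3), f0 = c(2, 0, 0)), "unit")
  expect_error(deformation(diag(3), f0 = c(1, 0, 0), s0 = c(1, 0, 0)),
               "orthogonal")
  expect_error(ho_params(0, 1, 1, 1, 1, 1, 1, 1), "positive")
})

test_that("active stress is rank-one along the current fiber direction", {
  d <- deformation(diag(3))
  expect_equal(active_cauchy_stress(0, d), matrix(0, 3, 3))
  s10 <- active_cauchy_stress(10, d)
  expect_equal(s10[1, 1], 10)
  expect_equal(sum(abs(s10)) - abs(s10[1, 1]), 0)
  # projection identity over random deformations
  set.seed(11)
  for (rep in 1:25) {
    d <- fx_random_deformation()
    T_a <- stats::runif(1, 0, 100)
    expect_equal(fiber_stress(active_cauchy_stress(T_a, d), d), T_a,
                 tolerance = 1e-10)
  }
})

test_that("fiber stress projects isotropic tensors and sums linearly", {
  d <- fx_random_deformation()
  expect_equal(fiber_stress(3.7 * diag(3), d), 3.7)
  p <- ho_params_healthy()
  sig_p <- passive_cauchy_stress(p, d)
  sig_a <- active_cauchy_stress(25, d)
  expect_equal(fiber_stress(sig_p + sig_a, d),
               fiber_stress(sig_p, d) + fiber_stress(sig_a, d),
               tolerance = 1e-10)
})

test_that("SBP normalization is plain division in kPa/mmHg", {
  expect_equal(normalize_by_sbp(0, 120), 0)
  expect_equal(normalize_by_sbp(65.07, 144.6), 0.45, tolerance = 0.001)
  expect_equal(normalize_by_sbp(65.23, 118.6), 0.55, tolerance = 0.001)
  expect_error(normalize_by_sbp(10, 0), "positive")
  expect_error(normalize_by_sbp(10, -5), "positive")
})

test_that("parameter YAML round-trips and defaults load", {
  p <- ho_params_mi_remote()
  f <- tempfile(fileext = ".yaml")
  write_ho_params(p, f)
  expect_equal(unclass(read_ho_params(f)), unclass(p))
  expect_equal(ho_params_healthy()$a_f, 3.34)
})
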