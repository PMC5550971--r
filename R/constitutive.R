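# Passive myocardial constitutive model: invariant-based Holzapfel-Ogden
# hyperelasticity with fiber/sheet anisotropy, tension-only anisotropic
# terms, a volumetric penalty, and linear infarct stiffening (scar = 50x).
#
# Units: stresses and energy densities in kPa; pressures handed to the
# solver in mmHg and converted internally.

#' Conversion factor from mmHg to kPa
#'
#' Single place where the pressure unit conversion lives (1 mmHg =
#' 0.133322 kPa).
#' @export
MMHG_TO_KPA <- 0.133322

#' Bulk modulus of the volumetric penalty (kPa)
#'
#' Penalty stiffness `beta_s` = 1.0e5 Pa = 100 kPa used by
#' [passive_energy()] and [passive_cauchy_stress()] to penalize volume
#' change. In the reduced LV model the kinematic ansatz is exactly
#' isochoric, so the penalty contributes nothing at converged states; it is
#' kept so that free-standing evaluations of the law at non-isochoric
#' deformations are penalized consistently.
#' @export
BULK_MODULUS_KPA <- 100

#' Passive Holzapfel-Ogden material parameters
#'
#' Container for the eight coefficients of the invariant-based
#' Holzapfel-Ogden myocardial strain-energy function: isotropic pair
#' `(a, b)`, fiber pair `(a_f, b_f)`, sheet pair `(a_s, b_s)` and
#' fiber-sheet coupling `(a_fs, b_fs)`. The `a`-type coefficients are
#' stress-like (kPa), the `b`-type are dimensionless exponents.
#'
#' @param a,b,a_f,b_f,a_s,b_s,a_fs,b_fs strictly positive scalars.
#' @return An object of class `ho_params`.
#' @seealso [ho_params_healthy()], [ho_params_mi_remote()]
#' @export
ho_params <- function(a, b, a_f, b_f, a_s, b_s, a_fs, b_fs) {
  p <- list(a = a, b = b, a_f = a_f, b_f = b_f,
            a_s = a_s, b_s = b_s, a_fs = a_fs, b_fs = b_fs)
  vals <- unlist(p)
  if (length(vals) != 8L || !all(is.finite(vals)) || any(vals <= 0))
    stop("all eight Holzapfel-Ogden parameters must be positive and finite")
  structure(p, class = "ho_params")
}

#' @export
print.ho_params <- function(x, ...) {
  cat("Holzapfel-Ogden passive parameters (a-type in kPa):\n")
  print(round(unlist(x), 4))
  invisible(x)
}

.ho_from_yaml <- function(file) {
  y <- yaml::read_yaml(file)
  do.call(ho_params, y[c("a", "b", "a_f", "b_f", "a_s", "b_s",
                         "a_fs", "b_fs")])
}

#' Cohort-average passive parameters
#'
#' Average passive parameters of the healthy control group
#' (`ho_params_healthy`) and of the remote myocardium of the MI group
#' (`ho_params_mi_remote`), read from the YAML files shipped in
#' `inst/extdata`.
#' @return An `ho_params` object.
#' @export
ho_params_healthy <- function() {
  .ho_from_yaml(system.file("extdata", "healthy.yaml",
                            package = "lvbiomech", mustWork = TRUE))
}

#' @rdname ho_params_healthy
#' @export
ho_params_mi_remote <- function() {
  .ho_from_yaml(system.file("extdata", "mi_remote.yaml",
                            package = "lvbiomech", mustWork = TRUE))
}

#' Write/read passive parameters as YAML
#'
#' @param params an `ho_params` object.
#' @param file path of the YAML file.
#' @return `write_ho_params` returns `file` invisibly; `read_ho_params`
#'   returns an `ho_params` object.
#' @export
write_ho_params <- function(params, file) {
  stopifnot(inherits(params, "ho_params"))
  yaml::write_yaml(lapply(unclass(params), as.numeric), file)
  invisible(file)
}

#' @rdname write_ho_params
#' @export
read_ho_params <- function(file) .ho_from_yaml(file)

#' Pointwise deformation state
#'
#' Bundles a deformation gradient with the initial (reference) fiber and
#' sheet directions. `f0` and `s0` must be unit length and mutually
#' orthogonal; `F` must have positive determinant.
#'
#' @param F 3x3 deformation gradient.
#' @param f0 unit reference fiber direction (length-3).
#' @param s0 unit reference sheet direction (length-3), orthogonal to `f0`.
#' @param tol tolerance for the unit-norm / orthogonality checks.
#' @return An object of class `deformation` with elements `F`, `f0`, `s0`,
#'   `J` (det F) and `C` (right Cauchy-Green tensor).
#' @export
deformation <- function(F, f0 = c(1, 0, 0), s0 = c(0, 1, 0), tol = 1e-8) {
  F <- as.matrix(F)
  if (!all(dim(F) == c(3L, 3L)) || !all(is.finite(F)))
    stop("invalid deformation: F must be a finite 3x3 matrix")
  J <- det(F)
  if (!is.finite(J) || J <= 0)
    stop("invalid deformation: det(F) must be > 0")
  f0 <- as.numeric(f0); s0 <- as.numeric(s0)
  if (abs(sum(f0^2) - 1) > tol || abs(sum(s0^2) - 1) > tol)
    stop("f0 and s0 must be unit vectors")
  if (abs(sum(f0 * s0)) > 1e-6)
    stop("f0 and s0 must be orthogonal")
  structure(list(F = F, f0 = f0, s0 = s0, J = J, C = crossprod(F)),
            class = "deformation")
}

.as_infarct_extent <- function(M) {
  M <- as.numeric(M)
  if (length(M) != 1L || !is.finite(M) || M < 0 || M > 1)
    stop("infarct extent M must be a scalar in [0, 1]")
  M
}

# Distortional part of the energy (the eight-coefficient terms), kPa.
# Anisotropic fiber/sheet terms engage only under tension (I4 > 1): taut
# myofibers bear load, compressed ones do not.
.ho_energy_core <- function(params, C, f0, s0, J = sqrt(det(C))) {
  # isochoric first invariant: keeps the reference state stress-free in
  # the penalty (compressible) setting; identical to I1 when J = 1
  I1b <- J^(-2 / 3) * sum(diag(C))
  Cf <- as.numeric(C %*% f0)
  Cs <- as.numeric(C %*% s0)
  I4f <- sum(f0 * Cf)
  I4s <- sum(s0 * Cs)
  I8 <- sum(f0 * Cs)
  W <- params$a / (2 * params$b) * (exp(params$b * (I1b - 3)) - 1)
  if (I4f > 1)
    W <- W + params$a_f / (2 * params$b_f) *
      (exp(params$b_f * (I4f - 1)^2) - 1)
  if (I4s > 1)
    W <- W + params$a_s / (2 * params$b_s) *
      (exp(params$b_s * (I4s - 1)^2) - 1)
  W + params$a_fs / (2 * params$b_fs) * (exp(params$b_fs * I8^2) - 1)
}

#' Passive strain-energy density
#'
#' Holzapfel-Ogden strain-energy density at one material point, scaled by
#' the infarct-extent field: the whole elastic energy is multiplied by
#' `(1 + 49 M)`, so fully infarcted scar (`M = 1`) is exactly 50 times
#' stiffer than remote myocardium (`M = 0`), linearly in between. A
#' volumetric penalty `beta_s log(J)^2` enforces near-incompressibility for
#' free-standing evaluations; it is a numerical constraint term and is not
#' scaled by the scar stiffening.
#'
#' @param params an [ho_params()] object.
#' @param deform a [deformation()] object.
#' @param M scalar infarct extent in `[0, 1]`.
#' @param beta_s volumetric penalty stiffness (kPa).
#' @return Energy density in kPa (= kJ/m^3).
#' @export
passive_energy <- function(params, deform, M = 0,
                           beta_s = BULK_MODULUS_KPA) {
  stopifnot(inherits(params, "ho_params"), inherits(deform, "deformation"))
  M <- .as_infarct_extent(M)
  W <- .ho_energy_core(params, deform$C, deform$f0, deform$s0)
  (1 + 49 * M) * W + beta_s * log(deform$J)^2
}

#' Passive Cauchy stress
#'
#' Elastic Cauchy stress derived from the Holzapfel-Ogden energy (push
#' forward of dW/dF), including the volumetric penalty contribution
#' `(beta_s / J) log(J^2) I`. The Eulerian fluid pressure and viscous terms
#' of the parent fluid-structure formulation are not part of this model.
#'
#' @inheritParams passive_energy
#' @return Symmetric 3x3 Cauchy stress tensor (kPa).
#' @export
passive_cauchy_stress <- function(params, deform, M = 0,
                                  beta_s = BULK_MODULUS_KPA) {
  stopifnot(inherits(params, "ho_params"), inherits(deform, "deformation"))
  M <- .as_infarct_extent(M)
  F <- deform$F; J <- deform$J
  C <- deform$C
  f0 <- deform$f0; s0 <- deform$s0
  f <- as.numeric(F %*% f0)
  s <- as.numeric(F %*% s0)
  I1 <- sum(diag(C))
  I1b <- J^(-2 / 3) * I1
  I4f <- sum(f * f)
  I4s <- sum(s * s)
  I8 <- sum(f * s)
  B <- tcrossprod(F)
  # deviatoric isotropic term (isochoric invariant)
  sig <- params$a * exp(params$b * (I1b - 3)) * J^(-2 / 3) *
    (B - I1 / 3 * diag(3))
  if (I4f > 1)
    sig <- sig + 2 * params$a_f * (I4f - 1) *
      exp(params$b_f * (I4f - 1)^2) * tcrossprod(f)
  if (I4s > 1)
    sig <- sig + 2 * params$a_s * (I4s - 1) *
      exp(params$b_s * (I4s - 1)^2) * tcrossprod(s)
  sig <- sig + params$a_fs * I8 * exp(params$b_fs * I8^2) *
    (tcrossprod(f, s) + tcrossprod(s, f))
  sig <- (1 + 49 * M) * sig / J
  sig + (beta_s / J) * log(J^2) * diag(3)
}

#' Normalize a stress or tension by systolic blood pressure
#'
#' Divides a stress-like quantity (kPa) by the systolic blood pressure
#' (mmHg), yielding the normalized biomarkers (kPa per mmHg) used to
#' compare subjects with different afterloads.
#'
#' @param x stress or tension in kPa (vectorized).
#' @param sbp systolic blood pressure in mmHg, must be > 0.
#' @return `x / sbp` in kPa/mmHg.
#' @export
normalize_by_sbp <- function(x, sbp) {
  if (!is.numeric(sbp) || length(sbp) != 1L || !is.finite(sbp) || sbp <= 0)
    stop("sbp must be a positive scalar (mmHg)")
  x / sbp
}

#' Active Cauchy stress tensor
#'
#' Rank-one active stress `T_a f_hat (x) f_hat` along the normalized
#' current fiber direction, so that the fiber projection of the active
#' stress equals the active tension exactly.
#'
#' @param T_a active tension (kPa), `>= 0`.
#' @param deform a [deformation()] object.
#' @return Symmetric 3x3 Cauchy stress tensor (kPa).
#' @export
active_cauchy_stress <- function(T_a, deform) {
  stopifnot(inherits(deform, "deformation"))
  if (!is.finite(T_a) || T_a < 0) stop("T_a must be finite and >= 0")
  f <- as.numeric(deform$F %*% deform$f0)
  nf <- sqrt(sum(f^2))
  if (nf < 1e-12) stop("degenerate deformed fiber direction")
  fhat <- f / nf
  T_a * tcrossprod(fhat)
}

#' Myofiber stress
#'
#' Projection of a (total) Cauchy stress tensor onto the normalized current
#' fiber direction: `sigma_f = f_hat . sigma . f_hat`.
#'
#' @param sigma symmetric 3x3 Cauchy stress tensor (kPa).
#' @param deform a [deformation()] object.
#' @return Scalar fiber stress (kPa).
#' @export
fiber_stress <- function(sigma, deform) {
  stopifnot(inherits(deform, "deformation"))
  sigma <- as.matrix(sigma)
  if (max(abs(sigma - t(sigma))) > 1e-8 * max(1, max(abs(sigma))))
    stop("sigma must be symmetric")
  f <- as.numeric(deform$F %*% deform$f0)
  nf <- sqrt(sum(f^2))
  if (nf < 1e-12) stop("degenerate deformed fiber direction")
  fhat <- f / nf
  as.numeric(fhat %*% sigma %*% fhat)
}
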