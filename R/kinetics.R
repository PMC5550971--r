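# Active contraction model: available actin binding-site fraction z driven
# by a prescribed calcium transient, fading-memory variables Q_i driven by
# the fiber stretch rate, and the dimensionless tension scaling C(lambda_f,
# z) that multiplies the reference contractility T_req. All kinetics
# constants live in inst/extdata/active_default.yaml and are model inputs.

#' Active tension model configuration
#'
#' Builds the configuration of the active contraction model: the reference
#' contractility `T_req` (the active tension generated at unit fiber
#' stretch under peak activation), the myofilament kinetics constants and
#' the prescribed calcium transient. Defaults are read from the versioned
#' constants file shipped with the package; any value can be overridden by
#' name.
#'
#' The tension scaling is normalized so that `C = 1` at `lambda_f = 1`,
#' peak activation and zero stretch-rate history, which makes `T_req`
#' literally the active tension generated when `lambda_f = 1`. The
#' normalization constant `z_ref` (peak binding-site fraction reached at
#' `lambda_f = 1` under the default transient) is computed once at
#' construction.
#'
#' @param T_req reference active tension in kPa (`>= 0`).
#' @param ... named overrides of the constants in
#'   `inst/extdata/active_default.yaml`.
#' @return An object of class `active_config`.
#' @export
active_config <- function(T_req = NULL, ...) {
  cfg <- yaml::read_yaml(system.file("extdata", "active_default.yaml",
                                     package = "lvbiomech",
                                     mustWork = TRUE))
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown active-model constants: ",
                        paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  if (!is.null(T_req)) cfg$T_req <- T_req
  if (!is.finite(cfg$T_req) || cfg$T_req < 0)
    stop("T_req must be finite and >= 0")
  cfg$A <- as.numeric(cfg$A)
  cfg$alpha_Q <- as.numeric(cfg$alpha_Q)
  class(cfg) <- "active_config"
  cfg$z_ref <- .kinetics_z_ref(cfg)
  cfg
}

#' @export
print.active_config <- function(x, ...) {
  cat("Active tension model: T_req =", x$T_req, "kPa;",
    "end-systole at", x$t_end_systole, "ms; z_ref =",
    signif(x$z_ref, 4), "\n")
  invisible(x)
}

#' Prescribed intracellular calcium transient
#'
#' Spatially homogeneous analytic transient `ca_amp * (t/ca_tau) *
#' exp(1 - t/ca_tau)` that triggers contraction simultaneously everywhere;
#' peak `ca_amp` at `t = ca_tau`.
#'
#' @param t time in ms (vectorized).
#' @param cfg an [active_config()] object.
#' @return Calcium concentration in transient units.
#' @export
ca_transient <- function(t, cfg) {
  ifelse(t <= 0, 0, cfg$ca_amp * (t / cfg$ca_tau) * exp(1 - t / cfg$ca_tau))
}

# Calcium half-activation with length-dependent sensitivity.
.ca50 <- function(lambda_f, cfg) {
  pmax(cfg$ca50_ref / pmax(1 + cfg$beta1 * (lambda_f - 1), 0.2), 1e-6)
}

# Hill-saturated calcium drive in [0, 1).
.ca_drive <- function(ca, lambda_f, cfg) {
  r <- (pmax(ca, 0) / .ca50(lambda_f, cfg))^cfg$n_hill
  r / (1 + r)
}

# dz/dt: first-order binding toward saturation minus linear and nonlinear
# relaxation.
.dzdt <- function(z, ca, lambda_f, cfg) {
  cfg$alpha0 * .ca_drive(ca, lambda_f, cfg) * (1 - z) -
    cfg$alpha_r1 * z -
    cfg$alpha_r2 * z^cfg$n_rel / (z^cfg$n_rel + cfg$K_z^cfg$n_rel)
}

#' Myofilament kinetics state
#'
#' State of the active model at one time instant: binding-site fraction
#' `z`, the three fading-memory variables `Q` and the current fiber stretch
#' `lambda_f`. All fields may be vectors (one entry per material point).
#'
#' @param z available actin binding-site fraction, in `[0, 1]`.
#' @param Q fading-memory variables; a length-3 vector or an `n x 3`
#'   matrix.
#' @param lambda_f fiber stretch.
#' @param t time (ms).
#' @return An object of class `kinetics_state`.
#' @export
kinetics_state <- function(z = 0, Q = c(0, 0, 0), lambda_f = 1, t = 0) {
  if (is.null(dim(Q))) Q <- matrix(Q, nrow = max(length(z), 1L), ncol = 3,
                                   byrow = TRUE)
  n <- max(length(z), nrow(Q), length(lambda_f))
  z <- rep_len(z, n); lambda_f <- rep_len(lambda_f, n)
  if (nrow(Q) != n) Q <- Q[rep_len(seq_len(nrow(Q)), n), , drop = FALSE]
  if (any(!is.finite(z)) || any(z < 0) || any(z > 1))
    stop("z must lie in [0, 1]")
  if (any(!is.finite(Q))) stop("Q must be finite")
  structure(list(z = z, Q = Q, lambda_f = lambda_f, t = t),
            class = "kinetics_state")
}

#' @export
print.kinetics_state <- function(x, ...) {
  cat("kinetics state at t =", x$t, "ms:", length(x$z), "point(s); mean z =",
      signif(mean(x$z), 4), "\n")
  invisible(x)
}

#' Advance the myofilament kinetics by one explicit step
#'
#' Fourth-order Runge-Kutta step of the `z` and `Q_i` dynamics under a
#' prescribed calcium transient and fiber stretch rate. Deterministic given
#' its inputs; `dt` must be positive and below the stability bound
#' `dt_max` declared in the configuration.
#'
#' @param state a [kinetics_state()] object.
#' @param cfg an [active_config()] object.
#' @param ca calcium input: either a function of time (ms) or a single
#'   value held constant over the step.
#' @param dlambda_dt fiber stretch rate (1/ms), scalar or per-point.
#' @param dt time step (ms).
#' @return The advanced `kinetics_state`.
#' @export
step_kinetics <- function(state, cfg, ca, dlambda_dt = 0, dt = cfg$dt) {
  stopifnot(inherits(state, "kinetics_state"),
            inherits(cfg, "active_config"))
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  if (dt > cfg$dt_max)
    stop("dt exceeds the declared stability bound dt_max = ", cfg$dt_max)
  ca_fun <- if (is.function(ca)) ca else function(t) ca
  t0 <- state$t
  lam0 <- state$lambda_f
  f_z <- function(z, h, lam) .dzdt(z, ca_fun(t0 + h), lam, cfg)
  # z: RK4 with lambda advected linearly within the step
  k1 <- f_z(state$z, 0, lam0)
  k2 <- f_z(state$z + dt / 2 * k1, dt / 2, lam0 + dlambda_dt * dt / 2)
  k3 <- f_z(state$z + dt / 2 * k2, dt / 2, lam0 + dlambda_dt * dt / 2)
  k4 <- f_z(state$z + dt * k3, dt, lam0 + dlambda_dt * dt)
  z1 <- state$z + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  z1 <- pmin(pmax(z1, 0), 1)
  # Q_i: linear ODE dQ/dt = A_i dlambda/dt - alpha_i Q, exact over the step
  Q1 <- state$Q
  for (i in 1:3) {
    ai <- cfg$alpha_Q[i]
    drive <- cfg$A[i] * dlambda_dt / ai
    Q1[, i] <- drive + (state$Q[, i] - drive) * exp(-ai * dt)
  }
  kinetics_state(z = z1, Q = Q1, lambda_f = lam0 + dlambda_dt * dt,
                 t = t0 + dt)
}

#' Integrate the kinetics over a systolic interval
#'
#' Integrates the active model from rest (`z = 0`, `Q = 0`) at activation
#' onset to `t_end`, under the configured calcium transient and a
#' prescribed fiber stretch history.
#'
#' @param cfg an [active_config()] object.
#' @param lambda_fun function of time (ms) returning the fiber stretch,
#'   scalar or one value per material point.
#' @param t_end end time (ms); defaults to the configured end-systolic
#'   time.
#' @param dt step size (ms).
#' @param keep_trajectory if `TRUE`, also return the time course of `z`.
#' @return The final [kinetics_state()]; with `keep_trajectory = TRUE` a
#'   list with elements `state`, `time` and `z` (matrix, time x point).
#' @export
simulate_kinetics <- function(cfg, lambda_fun = function(t) 1,
                              t_end = cfg$t_end_systole, dt = cfg$dt,
                              keep_trajectory = FALSE) {
  stopifnot(inherits(cfg, "active_config"))
  n_steps <- max(1L, ceiling(t_end / dt))
  dt <- t_end / n_steps
  lam0 <- lambda_fun(0)
  state <- kinetics_state(z = rep(0, length(lam0)), lambda_f = lam0, t = 0)
  traj <- if (keep_trajectory)
    matrix(NA_real_, n_steps + 1L, length(state$z)) else NULL
  if (keep_trajectory) traj[1L, ] <- state$z
  for (k in seq_len(n_steps)) {
    t0 <- (k - 1) * dt
    dldt <- (lambda_fun(t0 + dt) - lambda_fun(t0)) / dt
    state <- step_kinetics(state, cfg, function(t) ca_transient(t, cfg),
                           dlambda_dt = dldt, dt = dt)
    if (keep_trajectory) traj[k + 1L, ] <- state$z
  }
  if (keep_trajectory)
    list(state = state, time = seq(0, t_end, by = dt), z = traj)
  else state
}

# Peak z reached at lambda_f = 1 under the default transient; used to
# normalize C so that C(1, z_ref) = 1 at zero stretch-rate history.
.kinetics_z_ref <- function(cfg) {
  cfg2 <- unclass(cfg)
  cfg2$z_ref <- 1
  class(cfg2) <- "active_config"
  tr <- simulate_kinetics(cfg2, lambda_fun = function(t) 1,
                          t_end = max(2 * cfg$t_end_systole, 600),
                          dt = min(cfg$dt, 1), keep_trajectory = TRUE)
  zmax <- max(tr$z)
  if (zmax <= 0) stop("degenerate active model: z never rises above 0")
  zmax
}

#' Maximum binding-site fraction
#'
#' Equilibrium `z` under saturating calcium drive, the upper bound of the
#' binding-site fraction dynamics.
#'
#' @param cfg an [active_config()] object.
#' @return Scalar in (0, 1).
#' @export
z_max <- function(cfg) {
  stopifnot(inherits(cfg, "active_config"))
  stats::uniroot(function(z) cfg$alpha0 * (1 - z) - cfg$alpha_r1 * z -
                   cfg$alpha_r2 * z^cfg$n_rel /
                     (z^cfg$n_rel + cfg$K_z^cfg$n_rel),
                 c(0, 1))$root
}

#' Kinetics state at peak activation
#'
#' Reference state with `z` at its normalization value `z_ref`,
#' zero fading-memory history and unit fiber stretch; by construction
#' [tension_scaling()] equals 1 there.
#'
#' @param cfg an [active_config()] object.
#' @return A [kinetics_state()].
#' @export
peak_activation_state <- function(cfg) {
  stopifnot(inherits(cfg, "active_config"))
  kinetics_state(z = cfg$z_ref, lambda_f = 1)
}

# Force-velocity factor from the summed fading-memory variables.
.fv_factor <- function(Q, cfg) {
  q <- rowSums(Q)
  out <- ifelse(q < 0,
                (1 + cfg$a_fv * q) / (1 - q),
                (1 + (2 + cfg$a_fv) * q) / (1 + q))
  pmax(out, 0)
}

#' Dimensionless tension scaling C(lambda_f, z)
#'
#' The product of the length-dependence factor `1 + beta0 (lambda_f - 1)`,
#' the normalized binding-site fraction `z / z_ref` and the fading-memory
#' force-velocity factor. Equals 1 at unit stretch, peak activation and
#' zero stretch-rate history; its value at the configured end-systolic time
#' is the biomarker `C^s`.
#'
#' @param state a [kinetics_state()] object.
#' @param cfg an [active_config()] object.
#' @return Nonnegative scaling value(s), one per material point.
#' @export
tension_scaling <- function(state, cfg) {
  stopifnot(inherits(state, "kinetics_state"),
            inherits(cfg, "active_config"))
  g <- pmax(1 + cfg$beta0 * (state$lambda_f - 1), 0)
  pmax(g * .fv_factor(state$Q, cfg) * state$z / cfg$z_ref, 0)
}

#' Active tension
#'
#' `T_a = T_req * C(lambda_f, z) * (1 - M)`: the reference contractility
#' scaled by the myofilament kinetics and switched off linearly with the
#' infarct extent (fully infarcted tissue is non-contractile).
#'
#' @param cfg an [active_config()] object.
#' @param state a [kinetics_state()] object.
#' @param M infarct extent in `[0, 1]`, scalar or per-point.
#' @return Active tension(s) in kPa, nonnegative.
#' @export
active_tension <- function(cfg, state, M = 0) {
  stopifnot(inherits(cfg, "active_config"))
  if (any(!is.finite(M)) || any(M < 0) || any(M > 1))
    stop("infarct extent M must lie in [0, 1]")
  cfg$T_req * tension_scaling(state, cfg) * (1 - M)
}
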