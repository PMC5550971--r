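# Reduced-order quasi-static equilibrium solver for the truncated-
# ellipsoid LV model. The kinematic ansatz is exactly isochoric by
# construction: an axisymmetric-with-infarct-bulge endocardial inflation
# field g(xi, theta), a global axial stretch, and piecewise-linear twist
# about the long axis; the radial motion of the outer wall follows from
# pointwise volume conservation. Equilibrium states minimize total
# potential energy (strain energy + active fiber potential - cavity
# pressure work) over the ansatz parameters.

# Build the per-solve context: every dof-independent quantity needed by
# the energy evaluation, precomputed once.
.solver_context <- function(geom, fibers, infarct, params) {
  p <- geom$pts
  n <- nrow(p)
  M <- if (is.null(infarct)) numeric(n) else infarct$M
  hZ <- 0.05  # mm, stencil for d(r)/dZ
  hT <- 5e-4  # rad, stencil for d(r)/dTheta
  zb <- geom$z_base; ce <- geom$c_endo
  xi_of_z <- function(z) (zb - z) / (zb + ce)
  Mf <- if (is.null(infarct)) function(theta, xi) rep(0, length(theta))
        else infarct$M_fun
  xi_zp <- xi_of_z(p$z + hZ); xi_zm <- xi_of_z(p$z - hZ)
  ctx <- list(
    n = n, w = p$w, R = p$rho, M = M,
    r_in = p$r_in,
    r_in_zp = .endo_radius(p$z + hZ, geom$a_endo, geom$c_endo),
    r_in_zm = .endo_radius(p$z - hZ, geom$a_endo, geom$c_endo),
    xi = pmin(pmax(p$xi, 0), 1),
    xi_zp = pmin(pmax(xi_zp, 0), 1),
    xi_zm = pmin(pmax(xi_zm, 0), 1),
    M_zp = Mf(p$theta, xi_zp), M_zm = Mf(p$theta, xi_zm),
    M_tp = Mf(p$theta + hT, p$xi), M_tm = Mf(p$theta - hT, p$xi),
    hZ = hZ, hT = hT,
    dxi_dz = -1 / (zb + ce),
    f0 = fibers$f0, s0 = fibers$s0,
    prm = params,
    region = p$region, midwall = p$midwall,
    n_regions = geom$n_regions,
    # twist interpolation: knots at xi = k / n_tw, value 0 at the base
    n_tw = geom$n_slices,
    tw_bin = pmin(pmax(ceiling(pmin(p$xi, 1) * geom$n_slices), 1L),
                  geom$n_slices),
    vol = list(r_in = geom$vol_grid$r_in, dz = geom$vol_grid$dz,
               xi = pmin(pmax(geom$vol_grid$xi, 0), 1),
               dth = geom$vol_grid$dth,
               n_th = length(geom$vol_grid$theta),
               M_endo = if (is.null(infarct))
                 matrix(0, length(geom$vol_grid$z),
                        length(geom$vol_grid$theta))
               else infarct$M_endo),
    has_mi = !is.null(infarct)
  )
  ctx
}

# dofs: c(g_b, g_a, lz, tw_1..tw_n_tw, [g_mi])
.dof_init <- function(ctx) {
  d <- c(1, 1, 1, rep(0, ctx$n_tw))
  if (ctx$has_mi) d <- c(d, 0)
  d
}

.dof_bounds <- function(ctx) {
  lo <- c(0.3, 0.3, 0.55, rep(-0.9, ctx$n_tw))
  hi <- c(3.0, 3.0, 1.8, rep(0.9, ctx$n_tw))
  if (ctx$has_mi) { lo <- c(lo, -1.5); hi <- c(hi, 1.5) }
  list(lo = lo, hi = hi)
}

.g_field <- function(g_b, g_a, g_mi, xi, M) g_b + (g_a - g_b) * xi + g_mi * M

# Deformed cavity volume (ml) under the ansatz.
.cavity_volume <- function(ctx, dofs) {
  g_b <- dofs[1]; g_a <- dofs[2]; lz <- dofs[3]
  g_mi <- if (ctx$has_mi) dofs[length(dofs)] else 0
  v <- ctx$vol
  g <- g_b + (g_a - g_b) * v$xi + g_mi * v$M_endo  # recycles column-wise
  (lz / 2 * sum(g^2 * v$r_in^2 * v$dz) * v$dth) / 1000
}

# Kinematics at every quadrature point for a dof vector. Returns the six
# nonzero deformation-gradient components in the local cylindrical frames
# plus invariants used by the energy. J = 1 identically.
.kinematics <- function(ctx, dofs) {
  g_b <- dofs[1]; g_a <- dofs[2]; lz <- dofs[3]
  tw <- dofs[3 + seq_len(ctx$n_tw)]
  g_mi <- if (ctx$has_mi) dofs[length(dofs)] else 0

  r2 <- function(g, r_in) g^2 * r_in^2 + (ctx$R^2 - r_in^2) / lz
  g0 <- .g_field(g_b, g_a, g_mi, ctx$xi, ctx$M)
  r2_0 <- r2(g0, ctx$r_in)
  if (any(r2_0 <= 1e-9)) return(NULL)  # collapsed map; reject
  r0 <- sqrt(r2_0)
  gzp <- .g_field(g_b, g_a, g_mi, ctx$xi_zp, ctx$M_zp)
  gzm <- .g_field(g_b, g_a, g_mi, ctx$xi_zm, ctx$M_zm)
  gtp <- .g_field(g_b, g_a, g_mi, ctx$xi, ctx$M_tp)
  gtm <- .g_field(g_b, g_a, g_mi, ctx$xi, ctx$M_tm)
  r_zp2 <- r2(gzp, ctx$r_in_zp); r_zm2 <- r2(gzm, ctx$r_in_zm)
  r_tp2 <- r2(gtp, ctx$r_in);    r_tm2 <- r2(gtm, ctx$r_in)
  if (any(r_zp2 <= 0) || any(r_zm2 <= 0) ||
      any(r_tp2 <= 0) || any(r_tm2 <= 0)) return(NULL)
  r_Z <- (sqrt(r_zp2) - sqrt(r_zm2)) / (2 * ctx$hZ)
  r_T <- (sqrt(r_tp2) - sqrt(r_tm2)) / (2 * ctx$hT)

  # piecewise-linear twist phi(xi), phi(0) = 0 at the base
  twc <- c(0, tw)
  k <- ctx$tw_bin
  slope <- (twc[k + 1L] - twc[k]) * ctx$n_tw          # dphi/dxi
  dphi_dz <- slope * ctx$dxi_dz

  F11 <- ctx$R / (lz * r0)
  F12 <- r_T / ctx$R
  F13 <- r_Z
  F22 <- r0 / ctx$R
  F23 <- r0 * dphi_dz
  F33 <- rep(lz, ctx$n)

  C11 <- F11^2
  C12 <- F11 * F12
  C13 <- F11 * F13
  C22 <- F12^2 + F22^2
  C23 <- F12 * F13 + F22 * F23
  C33 <- F13^2 + F23^2 + F33^2
  I1 <- C11 + C22 + C33

  f0 <- ctx$f0; s0 <- ctx$s0
  qform <- function(a, b) {
    C11 * a[, 1] * b[, 1] + C22 * a[, 2] * b[, 2] + C33 * a[, 3] * b[, 3] +
      C12 * (a[, 1] * b[, 2] + a[, 2] * b[, 1]) +
      C13 * (a[, 1] * b[, 3] + a[, 3] * b[, 1]) +
      C23 * (a[, 2] * b[, 3] + a[, 3] * b[, 2])
  }
  I4f <- qform(f0, f0)
  I4s <- qform(s0, s0)
  I8 <- qform(f0, s0)
  list(F11 = F11, F12 = F12, F13 = F13, F22 = F22, F23 = F23, F33 = F33,
       I1 = I1, I4f = I4f, I4s = I4s, I8 = I8,
       lambda_c = sqrt(C22), lambda_f = sqrt(pmax(I4f, 1e-12)),
       tw = tw)
}

# Total passive strain energy (microjoule = kPa mm^3), infarct-scaled.
.passive_energy_total <- function(ctx, kin) {
  prm <- ctx$prm
  # exponents capped at 50 so extreme trial deformations stay finite for
  # the bounded optimizer (the cap is far outside the physical range)
  ex <- function(x) exp(pmin(x, 50))
  W <- prm$a / (2 * prm$b) * (ex(prm$b * (kin$I1 - 3)) - 1)
  e4f <- pmax(kin$I4f - 1, 0)
  W <- W + prm$a_f / (2 * prm$b_f) * (ex(prm$b_f * e4f^2) - 1)
  e4s <- pmax(kin$I4s - 1, 0)
  W <- W + prm$a_s / (2 * prm$b_s) * (ex(prm$b_s * e4s^2) - 1)
  W <- W + prm$a_fs / (2 * prm$b_fs) * (ex(prm$b_fs * kin$I8^2) - 1)
  sum(ctx$w * (1 + 49 * ctx$M) * W)
}

# Active fiber potential: W_act(lambda) with lambda dW/dlambda =
# K * g(lambda), so the active Cauchy fiber stress is T_a =
# K (1 + beta0 (lambda - 1)) with the length dependence resolved inside
# the equilibrium solve. Below lambda_min (where the length factor
# reaches zero) the potential is continued as a constant: no negative
# active tension.
.active_potential <- function(lam, beta0) {
  lam_min <- max(1 - 1 / beta0, 0.05)
  l <- pmax(lam, lam_min)
  (1 - beta0) * log(l) + beta0 * (l - 1)
}

# Objective for a load state: strain energy + active fiber potential -
# cavity pressure work. `active`, when present, is list(K, beta0) with K
# the frozen per-point tension scale T_req (1 - M) fv(Q) z / z_ref.
.potential <- function(ctx, dofs, p_kpa, active = NULL) {
  kin <- .kinematics(ctx, dofs)
  if (is.null(kin)) return(1e10)
  E <- .passive_energy_total(ctx, kin)
  if (!is.null(active))
    E <- E + sum(ctx$w * active$K *
                   .active_potential(kin$lambda_f, active$beta0))
  out <- E - p_kpa * 1000 * .cavity_volume(ctx, dofs)
  if (!is.finite(out)) 1e10 else out
}

# Robust minimization: a derivative-free Nelder-Mead descent (handles the
# huge dynamic range of the potential far from equilibrium) followed by a
# bounded quasi-Newton polish in the quadratic neighbourhood of the
# optimum. Deterministic given the starting point.
.minimize_potential <- function(ctx, p_kpa, active = NULL, init = NULL,
                                maxit = 600, warm = FALSE) {
  b <- .dof_bounds(ctx)
  init <- if (is.null(init)) .dof_init(ctx) else
    pmin(pmax(init, b$lo + 1e-6), b$hi - 1e-6)
  fn <- function(d) .potential(ctx, d, p_kpa, active)
  # derivative-free descent (robust through the strongly nonlinear far
  # field), then a bounded quasi-Newton polish near the optimum; a warm
  # start just shortens the descent
  o1 <- stats::optim(init, fn, method = "Nelder-Mead",
                     control = list(maxit = if (warm) 250 else maxit,
                                    reltol = 1e-10))
  init2 <- pmin(pmax(o1$par, b$lo + 1e-6), b$hi - 1e-6)
  o2 <- stats::optim(init2, fn, method = "L-BFGS-B", lower = b$lo,
                     upper = b$hi,
                     control = list(maxit = 200, factr = 1e2,
                                    fnscale = max(1, abs(o1$value))))
  opt <- if (o2$value <= o1$value) o2 else
    list(par = init2, value = o1$value)
  if (!is.finite(opt$value) || opt$value >= 1e9)
    stop("equilibrium solver failed: no admissible deformation found")
  opt
}

# Region means of a midwall point quantity.
.region_means <- function(ctx, x) {
  idx <- ctx$midwall & !is.na(ctx$region)
  s <- tapply(x[idx] * ctx$w[idx], ctx$region[idx], sum) /
    tapply(ctx$w[idx], ctx$region[idx], sum)
  as.numeric(s[as.character(seq_len(ctx$n_regions))])
}

.make_state <- function(ctx, geom, dofs, kin, phase, volume,
                        strain, extras = list()) {
  st <- c(list(
    phase = phase, dofs = dofs, volume = volume, strain = strain,
    # det F of the (upper-triangular) local deformation gradient; the
    # ansatz is isochoric so this is 1 up to floating-point error
    J = kin$F11 * kin$F22 * kin$F33,
    lambda_f = kin$lambda_f, lambda_c = kin$lambda_c,
    twist_deg = kin$tw * 180 / pi,
    region = ctx$region, midwall = ctx$midwall, w = ctx$w, M = ctx$M,
    n_regions = ctx$n_regions
  ), extras)
  class(st) <- "lv_state"
  st
}

#' @export
print.lv_state <- function(x, ...) {
  cat("LV", x$phase, "state: cavity volume", round(x$volume, 1), "ml;",
      "mean |strain|", round(mean(abs(x$strain)), 3), "\n")
  if (!is.null(x$twist_deg))
    cat("  twist (base->apex knots, deg):",
        paste(round(x$twist_deg, 1), collapse = ", "), "\n")
  invisible(x)
}

#' Inflate the LV to end-diastole
#'
#' Solves the passive equilibrium of the reduced LV model under the
#' end-diastolic cavity pressure by minimizing total potential energy over
#' the isochoric kinematic ansatz. Returns the end-diastolic volume and
#' the 24 diastolic segmental circumferential strains (reference: unloaded
#' configuration).
#'
#' @param geom an [lv_geometry()] object.
#' @param fibers a [generate_fibers()] field on `geom`.
#' @param infarct an optional [build_infarct()] map (`NULL` for healthy).
#' @param params an [ho_params()] object.
#' @param edp end-diastolic pressure (mmHg, `>= 0`).
#' @param init optional dof vector used to warm-start the minimization.
#' @return An object of class `lv_state` with elements `volume` (ml),
#'   `strain` (24 circumferential strains), per-point `lambda_f`,
#'   `lambda_c`, and the converged ansatz parameters `dofs`.
#' @export
solve_diastole <- function(geom, fibers, infarct = NULL, params,
                           edp = 8, init = NULL) {
  stopifnot(inherits(geom, "lv_geometry"), inherits(fibers, "fiber_field"),
            inherits(params, "ho_params"))
  if (!is.finite(edp) || edp < 0) stop("edp must be >= 0 (mmHg)")
  ctx <- .solver_context(geom, fibers, infarct, params)
  if (edp == 0) {
    dofs <- .dof_init(ctx)
    kin <- .kinematics(ctx, dofs)
    return(.make_state(ctx, geom, dofs, kin, "diastole",
                       geom$cavity_volume_ref,
                       .region_means(ctx, kin$lambda_c - 1),
                       list(edp = 0, converged = TRUE)))
  }
  opt <- .minimize_potential(ctx, edp * MMHG_TO_KPA, init = init)
  kin <- .kinematics(ctx, opt$par)
  .make_state(ctx, geom, opt$par, kin, "diastole",
              .cavity_volume(ctx, opt$par),
              .region_means(ctx, kin$lambda_c - 1),
              list(edp = edp, converged = TRUE, energy = opt$value))
}

# Fast internal z-integration (RK4) for all points under a linear fiber
# stretch ramp lambda(t) = lam0 + v t and the configured transient.
.integrate_z <- function(cfg, lam0, v, t_end, dt) {
  n_steps <- max(1L, ceiling(t_end / dt))
  dt <- t_end / n_steps
  z <- rep(0, length(lam0))
  for (k in seq_len(n_steps)) {
    t0 <- (k - 1) * dt
    lam_mid <- lam0 + v * (t0 + dt / 2)
    ca1 <- ca_transient(t0, cfg)
    ca2 <- ca_transient(t0 + dt / 2, cfg)
    ca3 <- ca_transient(t0 + dt, cfg)
    k1 <- .dzdt(z, ca1, lam0 + v * t0, cfg)
    k2 <- .dzdt(z + dt / 2 * k1, ca2, lam_mid, cfg)
    k3 <- .dzdt(z + dt / 2 * k2, ca2, lam_mid, cfg)
    k4 <- .dzdt(z + dt * k3, ca3, lam0 + v * (t0 + dt), cfg)
    z <- pmin(pmax(z + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4), 0), 1)
  }
  z
}

# Fading-memory variables at t_end under a constant stretch rate v
# (exact solution of the linear Q dynamics from rest).
.Q_ramp <- function(cfg, v, t_end) {
  sapply(1:3, function(i) {
    cfg$A[i] * v / cfg$alpha_Q[i] * (1 - exp(-cfg$alpha_Q[i] * t_end))
  })
}

#' Contract the LV to end-systole
#'
#' Solves the end-systolic equilibrium under the systolic cavity pressure
#' and the active fiber tension produced by the myofilament kinetics at
#' the configured end-systolic time. The kinetics (integrated along each
#' material point's fiber-stretch history, shared calcium transient) and
#' the mechanical equilibrium are coupled by a damped fixed-point
#' iteration. Fully infarcted tissue carries no active tension.
#'
#' @inheritParams solve_diastole
#' @param active_cfg an [active_config()] object (contains `T_req`).
#' @param sbp systolic cavity pressure (mmHg).
#' @param ed_state the end-diastolic `lv_state` (strain reference).
#' @param max_iter,tol fixed-point iteration controls.
#' @return An `lv_state` with `volume` (ESV, ml), `strain` (24 systolic
#'   segmental strains, reference end-diastole), per-point `lambda_f`,
#'   `T_a`, `C` and `sigma_f` fields, and the twist profile.
#' @export
solve_systole <- function(geom, fibers, infarct = NULL, params, active_cfg,
                          sbp, ed_state, max_iter = 50, tol = 1e-6) {
  stopifnot(inherits(geom, "lv_geometry"), inherits(fibers, "fiber_field"),
            inherits(params, "ho_params"),
            inherits(active_cfg, "active_config"),
            inherits(ed_state, "lv_state"))
  if (!is.finite(sbp) || sbp < 0) stop("sbp must be >= 0 (mmHg)")
  ctx <- .solver_context(geom, fibers, infarct, params)
  n <- ctx$n
  lam_ed <- ed_state$lambda_f
  lam_c_ed <- ed_state$lambda_c
  t_es <- active_cfg$t_end_systole

  if (active_cfg$T_req == 0 && sbp == 0) {
    # no systolic load increment: the configuration stays end-diastolic
    kin <- .kinematics(ctx, ed_state$dofs)
    return(.make_state(ctx, geom, ed_state$dofs, kin, "systole",
                       ed_state$volume, rep(0, ctx$n_regions),
                       list(sbp = 0, T_a = rep(0, n), C = rep(0, n),
                            sigma_f = .sigma_f_passive(ctx, kin),
                            converged = TRUE, iterations = 0L,
                            ed_volume = ed_state$volume)))
  }

  p_kpa <- sbp * MMHG_TO_KPA
  lam_es <- lam_ed          # current guess of end-systolic fiber stretch
  dofs <- ed_state$dofs
  converged <- FALSE
  iter <- 0L
  res <- Inf; res_prev <- Inf
  r_prev <- NULL; x_prev <- NULL
  C_s <- rep(0, n); T_a <- rep(0, n); kin <- NULL
  # outer fixed point over the kinetics state (z, Q); the tension-length
  # dependence is resolved inside each equilibrium solve via the active
  # potential, leaving only the weak dependence of z and Q on the stretch
  # history to iterate over. The update uses Anderson(1) (secant) mixing,
  # which handles both the oscillatory and the slow near-unit modes of
  # the map, with a damped fallback when the secant step misbehaves.
  repeat {
    iter <- iter + 1L
    v <- (lam_es - lam_ed) / t_es
    z_es <- .integrate_z(active_cfg, lam_ed, v, t_es, active_cfg$dt)
    Q <- .Q_ramp(active_cfg, v, t_es)
    if (is.null(dim(Q))) Q <- matrix(Q, n, 3)
    K <- active_cfg$T_req * (1 - ctx$M) *
      .fv_factor(Q, active_cfg) * z_es / active_cfg$z_ref
    opt <- .minimize_potential(ctx, p_kpa,
                               active = list(K = K,
                                             beta0 = active_cfg$beta0),
                               init = dofs, warm = iter > 1L)
    dofs <- opt$par
    kin <- .kinematics(ctx, dofs)
    lam_new <- kin$lambda_f
    r <- lam_new - lam_es
    res <- max(abs(r))
    if (res < tol) { lam_es <- lam_new; converged <- TRUE; break }
    if (iter >= max_iter) break
    step_ok <- FALSE
    if (!is.null(r_prev) && is.finite(res_prev) && res < 4 * res_prev) {
      dr <- r - r_prev
      dx <- lam_es - x_prev
      den <- sum(dr * dr)
      if (den > 1e-24) {
        gam <- sum(r * dr) / den
        gam <- min(max(gam, -2), 2)
        cand <- lam_es + r - gam * (dx + dr)
        step_ok <- all(is.finite(cand))
      }
    }
    x_prev <- lam_es; r_prev <- r; res_prev <- res
    lam_es <- if (step_ok) cand else lam_es + 0.6 * r
    lam_es <- pmin(pmax(lam_es, 0.55), 1.6)
  }
  st <- kinetics_state(z = .integrate_z(active_cfg, lam_ed,
                                        (lam_es - lam_ed) / t_es, t_es,
                                        active_cfg$dt),
                       Q = {
                         Q <- .Q_ramp(active_cfg,
                                      (lam_es - lam_ed) / t_es, t_es)
                         if (is.null(dim(Q))) matrix(Q, n, 3) else Q
                       },
                       lambda_f = lam_es, t = t_es)
  C_s <- tension_scaling(st, active_cfg)
  T_a <- active_cfg$T_req * C_s * (1 - ctx$M)
  if (!converged && res > 1e-3)
    stop("systolic kinetics-equilibrium coupling did not converge ",
         "(residual ", signif(res, 3), ")")
  strain_sys <- .region_means(ctx, kin$lambda_c / lam_c_ed - 1)
  .make_state(ctx, geom, dofs, kin, "systole",
              .cavity_volume(ctx, dofs), strain_sys,
              list(sbp = sbp, T_a = T_a, C = C_s,
                   sigma_f = .sigma_f_passive(ctx, kin) + T_a,
                   converged = converged, iterations = iter,
                   ed_volume = ed_state$volume))
}

# Passive fiber stress (projection of the passive Cauchy stress on the
# normalized current fiber direction) at every point; J = 1.
.sigma_f_passive <- function(ctx, kin) {
  prm <- ctx$prm
  f0 <- ctx$f0; s0 <- ctx$s0
  Fdot <- function(a) cbind(
    kin$F11 * a[, 1] + kin$F12 * a[, 2] + kin$F13 * a[, 3],
    kin$F22 * a[, 2] + kin$F23 * a[, 3],
    kin$F33 * a[, 3])
  f <- Fdot(f0); s <- Fdot(s0)
  I4f <- kin$I4f; I4s <- kin$I4s; I8 <- kin$I8
  B11 <- kin$F11^2 + kin$F12^2 + kin$F13^2
  B12 <- kin$F12 * kin$F22 + kin$F13 * kin$F23
  B13 <- kin$F13 * kin$F33
  B22 <- kin$F22^2 + kin$F23^2
  B23 <- kin$F23 * kin$F33
  B33 <- kin$F33^2
  fBf <- B11 * f[, 1]^2 + B22 * f[, 2]^2 + B33 * f[, 3]^2 +
    2 * (B12 * f[, 1] * f[, 2] + B13 * f[, 1] * f[, 3] +
           B23 * f[, 2] * f[, 3])
  e4f <- pmax(I4f - 1, 0)
  e4s <- pmax(I4s - 1, 0)
  # deviatoric isotropic projection (J = 1 in the ansatz)
  sig <- prm$a * exp(prm$b * (kin$I1 - 3)) *
    (fBf / I4f - kin$I1 / 3) +
    2 * prm$a_f * e4f * exp(prm$b_f * e4f^2) * I4f +
    2 * prm$a_s * e4s * exp(prm$b_s * e4s^2) * I8^2 / I4f +
    2 * prm$a_fs * I8^2 * exp(prm$b_fs * I8^2)
  (1 + 49 * ctx$M) * sig
}

#' Wall-averaged systolic biomarkers
#'
#' Computes the biomechanical biomarkers from a converged end-systolic
#' state: wall-averaged active tension `T_a` and fiber stress `sigma_f`
#' over the functional myocardium (`M < 0.5`), their values normalized by
#' systolic blood pressure, and the end-systolic myofilament kinetics
#' value `C_s`.
#'
#' @param sys_state an end-systolic `lv_state` from [solve_systole()].
#' @param sbp systolic blood pressure (mmHg) used for normalization.
#' @return A list with `T_a`, `sigma_f` (kPa), `T_a_norm`, `sigma_f_norm`
#'   (kPa/mmHg) and `C_s` (dimensionless).
#' @export
summarize_biomarkers <- function(sys_state, sbp) {
  stopifnot(inherits(sys_state, "lv_state"))
  if (is.null(sys_state$T_a))
    stop("summarize_biomarkers needs a systolic state")
  keep <- sys_state$M < 0.5
  w <- sys_state$w[keep]
  avg <- function(x) sum(x[keep] * w) / sum(w)
  T_a <- avg(sys_state$T_a)
  sigma_f <- avg(sys_state$sigma_f)
  list(T_a = T_a, sigma_f = sigma_f,
       T_a_norm = normalize_by_sbp(T_a, sbp),
       sigma_f_norm = normalize_by_sbp(sigma_f, sbp),
       C_s = avg(sys_state$C))
}
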