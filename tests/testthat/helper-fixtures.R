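# Shared fixtures. The forward solves are the expensive part of the
# suite, so the coarse-grid model runs are built once per session and
# cached. Coarse grid: 3 transmural layers, 6 circumferential and 12
# longitudinal stations (the smallest grid that still populates all 24
# strain regions).

fx_cache <- new.env(parent = emptyenv())

fx_coarse_geom <- function() {
  if (is.null(fx_cache$geom))
    fx_cache$geom <- lv_geometry(n_layers = 3, n_theta = 6, n_mu = 12)
  fx_cache$geom
}

fx_fibers <- function() {
  if (is.null(fx_cache$fibers))
    fx_cache$fibers <- generate_fibers(fx_coarse_geom())
  fx_cache$fibers
}

fx_infarct <- function() {
  if (is.null(fx_cache$infarct))
    fx_cache$infarct <- build_infarct(fx_coarse_geom())
  fx_cache$infarct
}

# healthy forward run at the cohort-average ground truth
fx_healthy_run <- function() {
  if (is.null(fx_cache$healthy)) {
    g <- fx_coarse_geom(); fib <- fx_fibers()
    p <- ho_params_healthy()
    cfg <- active_config(T_req = 157)
    ed <- solve_diastole(g, fib, NULL, p, edp = 8)
    es <- solve_systole(g, fib, NULL, p, cfg, sbp = 144.6,
                        ed_state = ed)
    fx_cache$healthy <- list(geom = g, fibers = fib, params = p,
                             cfg = cfg, ed = ed, es = es,
                             sbp = 144.6, edp = 8)
  }
  fx_cache$healthy
}

# infarcted forward run at the MI-group ground truth
fx_mi_run <- function() {
  if (is.null(fx_cache$mi)) {
    g <- fx_coarse_geom(); fib <- fx_fibers()
    inf <- fx_infarct()
    p <- ho_params_mi_remote()
    cfg <- active_config(T_req = 156)
    ed <- solve_diastole(g, fib, inf, p, edp = 16)
    es <- solve_systole(g, fib, inf, p, cfg, sbp = 118.6,
                        ed_state = ed)
    fx_cache$mi <- list(geom = g, fibers = fib, infarct = inf,
                        params = p, cfg = cfg, ed = ed, es = es,
                        sbp = 118.6, edp = 16)
  }
  fx_cache$mi
}

# random admissible deformation: positive-definite stretch + rotation,
# moderate strains, det > 0
fx_random_deformation <- function() {
  repeat {
    F <- diag(3) + matrix(stats::rnorm(9, 0, 0.08), 3, 3)
    if (det(F) > 0.5) break
  }
  f0 <- c(1, 0, 0); s0 <- c(0, 1, 0)
  deformation(F, f0, s0)
}

fx_random_rotation <- function() {
  qr_q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(qr_q) < 0) qr_q[, 1] <- -qr_q[, 1]
  qr_q
}

# simple shear in the fiber-sheet plane: F = I + gamma f0 (x) s0
fx_fs_shear <- function(gamma = 0.2) {
  F <- diag(3); F[1, 2] <- gamma
  deformation(F)
}

# small well-separated two-class table for classifier sanity checks
fx_separable_table <- function(n_per = 10, gap = 12, seed = 99) {
  set.seed(seed)
  data.frame(
    label = rep(c("healthy", "mi"), each = n_per),
    f1 = c(stats::rnorm(n_per, 0, 1), stats::rnorm(n_per, gap, 1)),
    f2 = c(stats::rnorm(n_per, 0, 1), stats::rnorm(n_per, gap, 1)))
}
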