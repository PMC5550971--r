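# Inverse estimation of passive stiffness and contractility from
# per-subject "measurements": cavity volume plus 24 segmental
# circumferential strains. Healthy-mode objectives use all segments; MI-
# mode objectives use remote segments only (the infarct is fixed at 50x
# stiffness and zero contractility and is not estimated).

#' Per-subject measurement set
#'
#' Container for the quantities the inverse problems match: end-diastolic
#' and end-systolic cavity volumes, the 24 diastolic (reference: unloaded)
#' and systolic (reference: end-diastole) segmental circumferential
#' strains, the segment classification, and the pressures.
#'
#' @param edv,esv cavity volumes (ml).
#' @param strain_dia,strain_sys numeric vectors of segmental strains.
#' @param seg_class character vector (`"remote"`, `"transition"`,
#'   `"infarct"`) of the same length; defaults to all-remote.
#' @param edp,sbp end-diastolic and systolic pressures (mmHg).
#' @return An object of class `measurement_set`.
#' @export
measurement_set <- function(edv, esv, strain_dia, strain_sys,
                            seg_class = NULL, edp = 8, sbp = 120) {
  n <- length(strain_sys)
  if (is.null(seg_class)) seg_class <- rep("remote", n)
  if (length(strain_dia) != n || length(seg_class) != n)
    stop("strain vectors and seg_class must have equal length")
  if (!all(seg_class %in% c("remote", "transition", "infarct")))
    stop("seg_class entries must be remote/transition/infarct")
  if (!all(is.finite(c(edv, esv, strain_dia, strain_sys))))
    stop("measurements must be finite")
  if (edv <= 0 || esv <= 0) stop("volumes must be positive")
  if (edv <= esv)
    warning("EDV does not exceed ESV: not a contracting ventricle")
  structure(list(edv = edv, esv = esv, strain_dia = strain_dia,
                 strain_sys = strain_sys, seg_class = seg_class,
                 edp = edp, sbp = sbp), class = "measurement_set")
}

#' @export
print.measurement_set <- function(x, ...) {
  cat("Measurements: EDV", round(x$edv, 1), "ml, ESV", round(x$esv, 1),
      "ml;", sum(x$seg_class == "remote"), "remote of",
      length(x$seg_class), "segments\n")
  invisible(x)
}

#' Volume-and-strain mismatch objective
#'
#' Sum of squared segmental-strain mismatches plus the squared cavity
#' volume mismatch, each normalized by its typical-mismatch scale
#' (`w_strain`, dimensionless strain; `w_vol`, ml) so both contribute
#' order one at typical misfit. In `mi` mode only remote segments enter
#' the strain sum, so the non-contractile, 50-fold-stiffened infarct does
#' not bias the estimate.
#'
#' @param meas_strain,meas_vol measured segmental strains and volume.
#' @param model_strain,model_vol model-predicted counterparts.
#' @param mode `"healthy"` (all segments) or `"mi"` (remote only).
#' @param seg_class segment classification, required in `mi` mode.
#' @param w_strain,w_vol normalization scales.
#' @return Scalar objective value (dimensionless).
#' @export
fit_objective <- function(meas_strain, meas_vol, model_strain, model_vol,
                          mode = c("healthy", "mi"), seg_class = NULL,
                          w_strain = 0.05, w_vol = 10) {
  mode <- match.arg(mode)
  if (length(model_strain) != length(meas_strain))
    stop("model and measured strain vectors differ in length")
  keep <- rep(TRUE, length(meas_strain))
  if (mode == "mi") {
    if (is.null(seg_class)) stop("mi mode needs seg_class")
    keep <- seg_class == "remote"
    if (!any(keep)) stop("mi mode objective needs >= 1 remote segment")
  }
  sum(((meas_strain[keep] - model_strain[keep]) / w_strain)^2) +
    ((meas_vol - model_vol) / w_vol)^2
}

.scale_params <- function(params, q = 1, s_f = 1) {
  ho_params(a = params$a * q, b = params$b,
            a_f = params$a_f * q * s_f, b_f = params$b_f * s_f,
            a_s = params$a_s * q, b_s = params$b_s,
            a_fs = params$a_fs * q, b_fs = params$b_fs)
}

#' Multi-step passive parameter estimation
#'
#' Estimates passive stiffness from diastolic measurements with a
#' three-step scheme over two interpretable scale factors applied to the
#' initial parameter set: (1) a global stiffness scale on all stress-like
#' coefficients, fitted to EDV alone; (2) a myofiber-direction scale on
#' `(a_f, b_f)`, fitted to the diastolic segmental strains; (3) a joint
#' derivative-free polish of both scales against the full objective.
#' Deterministic given inputs; the eight parameters themselves are not
#' individually identifiable from volume plus strain, but the fiber-
#' direction stiffness is.
#'
#' @param meas a [measurement_set()].
#' @param geom,fibers,infarct model definition (see [solve_diastole()]).
#' @param init initial [ho_params()].
#' @return An object of class `fit_result` with the fitted `params`, the
#'   scale factors, the objective trace and a convergence flag.
#' @export
fit_passive <- function(meas, geom, fibers, infarct = NULL, init) {
  stopifnot(inherits(meas, "measurement_set"), inherits(init, "ho_params"))
  mode <- if (is.null(infarct)) "healthy" else "mi"
  trace <- list()
  run <- function(q, s_f) {
    prm <- .scale_params(init, q, s_f)
    st <- solve_diastole(geom, fibers, infarct, prm, edp = meas$edp)
    obj <- fit_objective(meas$strain_dia, meas$edv, st$strain, st$volume,
                         mode = mode, seg_class = meas$seg_class)
    trace[[length(trace) + 1L]] <<- c(q = q, s_f = s_f, objective = obj,
                                      volume = st$volume)
    list(obj = obj, st = st)
  }
  vol_only <- function(q) {
    prm <- .scale_params(init, q, 1)
    st <- solve_diastole(geom, fibers, infarct, prm, edp = meas$edp)
    ((st$volume - meas$edv) / 10)^2
  }
  o1 <- stats::optimize(function(lq) vol_only(exp(lq)),
                        interval = log(c(0.1, 10)), tol = 1e-3)
  q1 <- exp(o1$minimum)
  strain_only <- function(s_f) {
    prm <- .scale_params(init, q1, s_f)
    st <- solve_diastole(geom, fibers, infarct, prm, edp = meas$edp)
    keep <- if (mode == "mi") meas$seg_class == "remote" else TRUE
    sum(((meas$strain_dia[keep] - st$strain[keep]) / 0.05)^2)
  }
  o2 <- stats::optimize(function(ls) strain_only(exp(ls)),
                        interval = log(c(0.25, 4)), tol = 1e-3)
  s1 <- exp(o2$minimum)
  o3 <- stats::optim(log(c(q1, s1)),
                     function(p) run(exp(p[1]), exp(p[2]))$obj,
                     method = "Nelder-Mead",
                     control = list(maxit = 150, reltol = 1e-6))
  q_hat <- exp(o3$par[1]); s_hat <- exp(o3$par[2])
  final <- run(q_hat, s_hat)
  structure(list(params = .scale_params(init, q_hat, s_hat),
                 scales = c(global = q_hat, fiber = s_hat),
                 objective = final$obj,
                 trace = do.call(rbind, trace),
                 converged = o3$convergence == 0,
                 state = final$st),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  if (!is.null(x$T_req))
    cat("Contractility fit: T_req =", round(x$T_req, 2), "kPa; objective",
        signif(x$objective, 4), if (x$converged) "(converged)" else
          "(NOT converged)", "\n")
  else
    cat("Passive fit: scales", paste(signif(x$scales, 4), collapse = ", "),
        "; objective", signif(x$objective, 4), "\n")
  invisible(x)
}

#' Inverse estimation of contractility
#'
#' Determines the reference active tension `T_req` by matching the
#' measured end-systolic volume and systolic segmental strains: a bounded
#' one-dimensional minimization (golden-section/parabolic) of the
#' volume-and-strain objective over `T_req` in `bounds`, to an absolute
#' tolerance `tol` (kPa). In `mi` mode the strain terms are restricted to
#' remote segments. The passive parameters are held fixed.
#'
#' @param meas a [measurement_set()].
#' @param geom,fibers,infarct model definition.
#' @param params fixed passive [ho_params()].
#' @param active_cfg an [active_config()]; its `T_req` entry is the
#'   quantity being estimated and is overridden during the search.
#' @param bounds search interval for `T_req` (kPa).
#' @param tol absolute convergence tolerance (kPa).
#' @return A `fit_result` with `T_req`, the objective trace (the
#'   objective-vs-contractility curve), and a convergence flag.
#' @export
fit_contractility <- function(meas, geom, fibers, infarct = NULL, params,
                              active_cfg = active_config(),
                              bounds = c(0, 400), tol = 0.1) {
  stopifnot(inherits(meas, "measurement_set"),
            inherits(params, "ho_params"),
            inherits(active_cfg, "active_config"))
  mode <- if (is.null(infarct)) "healthy" else "mi"
  ed <- solve_diastole(geom, fibers, infarct, params, edp = meas$edp)
  trace <- list()
  fn <- function(T_req) {
    cfg <- active_cfg
    cfg$T_req <- T_req          # z_ref is independent of T_req
    st <- solve_systole(geom, fibers, infarct, params, cfg,
                        sbp = meas$sbp, ed_state = ed)
    obj <- fit_objective(meas$strain_sys, meas$esv, st$strain, st$volume,
                         mode = mode, seg_class = meas$seg_class)
    trace[[length(trace) + 1L]] <<- c(T_req = T_req, objective = obj,
                                      esv = st$volume)
    obj
  }
  opt <- stats::optimize(fn, interval = bounds, tol = tol)
  tr <- do.call(rbind, trace)
  spread <- diff(range(tr[, "objective"]))
  structure(list(T_req = opt$minimum, objective = opt$objective,
                 trace = tr,
                 converged = is.finite(opt$objective) && spread > 1e-12,
                 ed_state = ed),
            class = "fit_result")
}
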