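# Idealized left-ventricle geometry: a truncated prolate ellipsoid wall
# discretized by transmural layers, circumferential sectors and
# longitudinal stations, with region bookkeeping for the 24 segmental
# circumferential strains (4 short-axis slices x 6 sectors, basal half of
# the ventricle). Lengths in mm, volumes reported in ml.

#' Idealized left-ventricle geometry
#'
#' Builds a truncated prolate-ellipsoid LV wall. The endocardial surface is
#' the ellipsoid with short semi-axis `a_endo` and long semi-axis `c_endo`;
#' the epicardial surface is offset by `wall` in both semi-axes. The
#' ventricle is truncated at the basal plane `z = base_frac * c_endo`
#' (apex at `z = -c_endo`). Quadrature points are laid out on a
#' layers x longitudinal x circumferential grid; the basal half
#' (base to mid-ventricle) is divided into `n_slices` short-axis slices of
#' `n_sectors` sectors each, giving the 24 strain regions.
#'
#' @param a_endo endocardial short semi-axis (mm).
#' @param c_endo endocardial long semi-axis (mm).
#' @param wall wall thickness (mm), added to both semi-axes.
#' @param base_frac basal truncation height as a fraction of `c_endo`.
#' @param n_layers transmural layers.
#' @param n_theta circumferential stations.
#' @param n_mu longitudinal stations (apex to base).
#' @param n_slices,n_sectors strain-region layout (`n_slices * n_sectors`
#'   regions; defaults give 24).
#' @return An object of class `lv_geometry`.
#' @export
lv_geometry <- function(a_endo = 22, c_endo = 56, wall = 10,
                        base_frac = 0.35, n_layers = 4, n_theta = 12,
                        n_mu = 12, n_slices = 4, n_sectors = 6) {
  if (wall <= 0) stop("wall thickness must be > 0")
  if (a_endo <= 0 || c_endo <= 0) stop("semi-axes must be > 0")
  if (base_frac <= -1 || base_frac >= 1)
    stop("base_frac must lie in (-1, 1)")
  a_epi <- a_endo + wall
  c_epi <- c_endo + wall
  z_base <- base_frac * c_endo
  # endocardial parameter angle at the base plane (mu = 0 at apex)
  mu_base_en <- acos(-z_base / c_endo)
  mu_base_ep <- acos(-z_base / c_epi)

  # quadrature grid: midpoint rule in (u, mu, theta); layers blend the
  # endo (u = 0) and epi (u = 1) surfaces at matched normalized mu
  u <- (seq_len(n_layers) - 0.5) / n_layers
  th <- (seq_len(n_theta) - 0.5) / n_theta * 2 * pi
  mu_frac <- (seq_len(n_mu) - 0.5) / n_mu
  du <- 1 / n_layers
  dth <- 2 * pi / n_theta
  dmu_frac <- 1 / n_mu

  grid <- expand.grid(u = u, mu_frac = mu_frac, th = th,
                      KEEP.OUT.ATTRS = FALSE)
  A <- a_endo + (a_epi - a_endo) * grid$u
  C <- c_endo + (c_epi - c_endo) * grid$u
  mu_b <- mu_base_en + (mu_base_ep - mu_base_en) * grid$u
  mu <- grid$mu_frac * mu_b
  rho <- A * sin(mu)
  z <- -C * cos(mu)
  # volume element: rho * |d(rho, z)/d(u, mu)| du dmu dth with
  # mu = mu_frac * mu_b(u)
  dA <- a_epi - a_endo
  dC <- c_epi - c_endo
  dmu_b <- mu_base_ep - mu_base_en
  # d(rho)/du at fixed (mu_frac, th), d(z)/du likewise
  drho_du <- dA * sin(mu) + A * cos(mu) * grid$mu_frac * dmu_b
  dz_du <- -dC * cos(mu) + C * sin(mu) * grid$mu_frac * dmu_b
  drho_dm <- A * cos(mu) * mu_b
  dz_dm <- C * sin(mu) * mu_b
  jac <- abs(drho_du * dz_dm - dz_du * drho_dm)
  w <- rho * jac * du * dmu_frac * dth

  # endocardial radius at each point's height (0 beyond the endo apex)
  r_in <- .endo_radius(z, a_endo, c_endo)
  # normalized apex-ward coordinate (0 at base plane, 1 at endo apex)
  xi <- (z_base - z) / (z_base + c_endo)

  # strain regions: basal half (xi < 0.5), n_slices bands x n_sectors
  slice <- ifelse(xi < 0.5, pmin(floor(xi / (0.5 / n_slices)) + 1L,
                                 n_slices), NA_integer_)
  sector <- pmin(floor(grid$th / (2 * pi / n_sectors)) + 1L, n_sectors)
  region <- ifelse(is.na(slice), NA_integer_,
                   (slice - 1L) * n_sectors + sector)
  mid_layers <- if (n_layers >= 4) {
    lo <- floor(n_layers / 2); c(lo, lo + 1L)
  } else ceiling(n_layers / 2)
  layer_idx <- round(grid$u * n_layers + 0.5)
  midwall <- layer_idx %in% mid_layers

  # every strain region must own at least one mid-wall quadrature point
  regc <- unique(region[midwall & !is.na(region)])
  if (length(regc) < n_slices * n_sectors)
    stop("grid too coarse: ", n_slices * n_sectors - length(regc),
         " strain region(s) contain no mid-wall point; increase n_mu or ",
         "n_theta")

  # closed-form reference volumes
  ub <- base_frac
  cav_vol <- pi * a_endo^2 * c_endo *
    ((ub - ub^3 / 3) - (-1 + 1 / 3))
  ub_e <- z_base / c_epi
  epi_vol <- pi * a_epi^2 * c_epi * ((ub_e - ub_e^3 / 3) + 2 / 3)
  wall_vol <- epi_vol - cav_vol

  # fine endocardial grid for the deformed cavity-volume quadrature
  n_mu_vol <- 48L
  muv <- (seq_len(n_mu_vol) - 0.5) / n_mu_vol * mu_base_en
  dmuv <- mu_base_en / n_mu_vol
  zv <- -c_endo * cos(muv)
  r_in_v <- a_endo * sin(muv)
  dz_v <- c_endo * sin(muv) * dmuv
  xiv <- (z_base - zv) / (z_base + c_endo)

  # meridian arc length of the mid-wall surface, base to apex (for
  # infarct footprint distances)
  amid <- (a_endo + a_epi) / 2; cmid <- (c_endo + c_epi) / 2
  mus <- seq(0, (mu_base_en + mu_base_ep) / 2, length.out = 200)
  arc <- sum(sqrt((amid * cos(mus))^2 + (cmid * sin(mus))^2) *
               diff(mus)[1])

  structure(list(
    a_endo = a_endo, c_endo = c_endo, a_epi = a_epi, c_epi = c_epi,
    wall = wall, z_base = z_base, base_frac = base_frac,
    n_layers = n_layers, n_theta = n_theta, n_mu = n_mu,
    n_slices = n_slices, n_sectors = n_sectors,
    n_regions = n_slices * n_sectors,
    pts = data.frame(u = grid$u, mu = mu, theta = grid$th, rho = rho,
                     z = z, w = w, r_in = r_in, xi = xi,
                     region = region, midwall = midwall,
                     layer = layer_idx),
    cavity_volume_ref = cav_vol / 1000,  # ml
    wall_volume = wall_vol / 1000,       # ml
    vol_grid = list(z = zv, r_in = r_in_v, dz = dz_v, xi = xiv,
                    theta = th, dth = dth),
    meridian_length = arc,
    mid_radius = amid
  ), class = "lv_geometry")
}

.endo_radius <- function(z, a_endo, c_endo) {
  inside <- abs(z) < c_endo
  out <- numeric(length(z))
  out[inside] <- a_endo * sqrt(1 - (z[inside] / c_endo)^2)
  out
}

#' @export
print.lv_geometry <- function(x, ...) {
  cat("Truncated-ellipsoid LV geometry:\n")
  cat("  endo semi-axes", x$a_endo, "x", x$c_endo, "mm, wall", x$wall,
      "mm\n")
  cat("  reference cavity volume", round(x$cavity_volume_ref, 1),
      "ml, wall volume", round(x$wall_volume, 1), "ml\n")
  cat("  grid:", nrow(x$pts), "points;", x$n_regions, "strain regions\n")
  invisible(x)
}

#' Rule-based myocardial fiber and sheet field
#'
#' Assigns fiber and sheet orientations by the rule-based construction:
#' the helix angle varies linearly through the wall from `endo_angle` at
#' the endocardium to `epi_angle` at the epicardium, and the sheet angle
#' from `sheet_endo` to `sheet_epi`. Unit fiber (`f0`) and sheet (`s0`)
#' vectors are expressed in the local cylindrical frame (radial,
#' circumferential, axial) at each quadrature point and are mutually
#' orthogonal by construction.
#'
#' @param geom an [lv_geometry()] object.
#' @param endo_angle,epi_angle helix angle at endo-/epicardium (degrees).
#' @param sheet_endo,sheet_epi sheet angle at endo-/epicardium (degrees).
#' @return An object of class `fiber_field` with matrices `f0`, `s0`
#'   (n x 3, cylindrical components) and vectors `helix`, `sheet`
#'   (degrees).
#' @export
generate_fibers <- function(geom, endo_angle = -60, epi_angle = 60,
                            sheet_endo = -45, sheet_epi = 45) {
  stopifnot(inherits(geom, "lv_geometry"))
  p <- geom$pts
  helix <- endo_angle + (epi_angle - endo_angle) * p$u
  sheet <- sheet_endo + (sheet_epi - sheet_endo) * p$u
  al <- helix * pi / 180
  be <- sheet * pi / 180
  # local frame in cylindrical components (e_R, e_Theta, e_Z):
  # e_c = circumferential, e_l = meridian tangent, e_n = e_c x e_l
  A <- geom$a_endo + (geom$a_epi - geom$a_endo) * p$u
  C <- geom$c_endo + (geom$c_epi - geom$c_endo) * p$u
  lR <- A * cos(p$mu); lZ <- C * sin(p$mu)
  nl <- sqrt(lR^2 + lZ^2)
  lR <- lR / nl; lZ <- lZ / nl
  # f0 = cos(al) e_c + sin(al) e_l
  f0 <- cbind(sin(al) * lR, cos(al), sin(al) * lZ)
  # e_n = e_c x e_l = (lZ, 0, -lR)
  nR <- lZ; nZ <- -lR
  # e_n x f0 (in the same orthonormal triad)
  cR <- -nZ * f0[, 2]
  cT <- nZ * f0[, 1] - nR * f0[, 3]
  cZ <- nR * f0[, 2]
  s0 <- cbind(cos(be) * nR + sin(be) * cR,
              sin(be) * cT,
              cos(be) * nZ + sin(be) * cZ)
  structure(list(f0 = f0, s0 = s0, helix = helix, sheet = sheet,
                 endo_angle = endo_angle, epi_angle = epi_angle,
                 sheet_endo = sheet_endo, sheet_epi = sheet_epi,
                 # continuous angle rules (u = 0 endocardium, 1 epicardium)
                 helix_fun = function(u) endo_angle +
                   (epi_angle - endo_angle) * u,
                 sheet_fun = function(u) sheet_endo +
                   (sheet_epi - sheet_endo) * u),
            class = "fiber_field")
}

#' @export
print.fiber_field <- function(x, ...) {
  cat("Rule-based fiber field: helix", x$endo_angle, "to", x$epi_angle,
      "deg, sheet", x$sheet_endo, "to", x$sheet_epi, "deg\n")
  invisible(x)
}

#' Infarct-extent field
#'
#' Builds the transmural infarct-extent field `M` on the LV wall: `M = 1`
#' inside a contiguous elliptical patch (in circumferential/longitudinal
#' arc-length coordinates on the mid-wall surface), `M = 0` in the remote
#' myocardium, and `M` decreasing linearly across a transition band of
#' width `band` mm adjacent to the infarct boundary. The patch extent is
#' calibrated so that the `M = 1` core occupies `target_size` of the wall
#' volume. Strain regions are classified as `infarct`, `transition` or
#' `remote` from their mean `M`.
#'
#' @param geom an [lv_geometry()] object.
#' @param center_theta circumferential center of the patch (radians).
#' @param center_xi longitudinal center (0 = base, 1 = apex).
#' @param target_size infarct core volume fraction of the wall, in (0, 1).
#' @param aspect longitudinal-to-circumferential radius ratio of the
#'   patch.
#' @param band transition bandwidth (mm).
#' @param thresholds named vector: regions with mean `M` below
#'   `remote` are remote, above `infarct` are infarct, else transition.
#' @return An object of class `infarct_map` with per-point `M`, per-region
#'   labels, the realized `size` (volume fraction) and the remote-segment
#'   count `n_remote`.
#' @export
build_infarct <- function(geom, center_theta = pi, center_xi = 0.75,
                          target_size = 0.39, aspect = 2, band = 10,
                          thresholds = c(remote = 0.05, infarct = 0.5)) {
  stopifnot(inherits(geom, "lv_geometry"))
  if (target_size <= 0 || target_size >= 1)
    stop("target_size (infarct volume fraction) must lie in (0, 1)")
  if (band <= 0) stop("transition band must be > 0 mm")

  core_frac <- function(scale) {
    M <- .infarct_M(geom$pts$theta, geom$pts$xi, geom, center_theta,
                    center_xi, scale, aspect, band)
    sum(geom$pts$w[M >= 1]) / sum(geom$pts$w)
  }
  sc <- tryCatch(
    stats::uniroot(function(s) core_frac(s) - target_size,
                   interval = c(1, 60), extendInt = "upX")$root,
    error = function(e) stop("could not calibrate infarct extent: ",
                             conditionMessage(e)))
  M <- .infarct_M(geom$pts$theta, geom$pts$xi, geom, center_theta,
                  center_xi, sc, aspect, band)
  M_endo <- outer(seq_along(geom$vol_grid$z), seq_along(geom$vol_grid$theta),
                  function(i, j) .infarct_M(geom$vol_grid$theta[j],
                                            geom$vol_grid$xi[i], geom,
                                            center_theta, center_xi, sc,
                                            aspect, band))
  size <- sum(geom$pts$w[M >= 1]) / sum(geom$pts$w)
  if (size <= 0 || size >= 1)
    stop("degenerate infarct: core covers ", round(100 * size), "% of wall")

  reg_M <- tapply(M * geom$pts$w, geom$pts$region, sum) /
    tapply(geom$pts$w, geom$pts$region, sum)
  reg_M <- reg_M[as.character(seq_len(geom$n_regions))]
  labels <- ifelse(reg_M < thresholds[["remote"]], "remote",
                   ifelse(reg_M > thresholds[["infarct"]], "infarct",
                          "transition"))
  structure(list(
    M = M, M_endo = M_endo, size = size,
    region_M = as.numeric(reg_M), region_class = as.character(labels),
    n_remote = sum(labels == "remote"),
    center_theta = center_theta, center_xi = center_xi, scale = sc,
    aspect = aspect, band = band,
    M_fun = function(theta, xi) .infarct_M(theta, xi, geom, center_theta,
                                           center_xi, sc, aspect, band)
  ), class = "infarct_map")
}

# M(theta, xi): elliptical core with a linear transition band measured as
# arc-length distance (mm) from the core boundary along the ray from the
# patch center.
.infarct_M <- function(theta, xi, geom, center_theta, center_xi, scale,
                       aspect, band) {
  r_c <- scale
  r_l <- scale * aspect
  dth <- atan2(sin(theta - center_theta), cos(theta - center_theta))
  d_c <- abs(dth) * geom$mid_radius * 0.85  # mid-wall equatorial-ish arc
  d_l <- abs(xi - center_xi) * geom$meridian_length
  q <- sqrt((d_c / r_c)^2 + (d_l / r_l)^2)
  dist_mm <- sqrt(d_c^2 + d_l^2) * pmax(1 - 1 / pmax(q, 1e-12), 0)
  ifelse(q <= 1, 1, pmax(1 - dist_mm / band, 0))
}

#' @export
print.infarct_map <- function(x, ...) {
  cat("Infarct-extent field: core", round(100 * x$size, 1),
      "% of wall volume;", x$n_remote, "remote segments;",
      sum(x$region_class == "infarct"), "infarct,",
      sum(x$region_class == "transition"), "transition\n")
  invisible(x)
}
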