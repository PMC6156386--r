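#' Synthetic biventricular phantom specification
#'
#' Parameterizes a deforming two-walled truncated-ellipsoid phantom: the LV
#' is a thick-walled prolate ellipsoid shell, the RV a crescent formed by a
#' second, offset, thinner-walled ellipsoid shell clipped against the LV
#' epicardium, both truncated by a flat base plane normal to the long axis.
#' An analytic, exactly invertible motion (longitudinal base-toward-apex
#' excursion scaled by MAPSE, circumferential shortening with the
#' incompressible radial thickening it implies, apex-to-base twist, and an
#' optional extra wall-volume gain) drives both the rendered cine images
#' and the ground-truth strain oracle.
#'
#' The cycle phase is `sin^2(pi * t / n_frames)` for the default mid-cycle
#' end-systole, so the motion is the identity at the end-diastolic frame 0
#' and peaks at `es_frame`.
#'
#' @param lv_endo_radii LV endocardial semi-axes (x, y, long-axis) in mm.
#' @param lv_wall_thickness LV wall thickness (mm), added to all semi-axes.
#' @param rv_offset centre offset of the RV ellipsoid from the LV centre (mm).
#' @param rv_radii RV endocardial semi-axes (mm).
#' @param rv_wall_thickness RV free wall thickness (mm).
#' @param base_truncation_height base plane height above the epicardial
#'   apex (mm); also the apex-to-base length used by the motion model.
#' @param grid_dim,grid_spacing rendered image grid (voxels, mm); the slice
#'   spacing is deliberately coarse, as in short-axis cine acquisitions.
#' @param n_frames frames per cardiac cycle.
#' @param es_frame end-systolic frame index (0-based; frame 0 is ED).
#' @param thickening_amplitude fractional wall-volume gain at ES beyond the
#'   volume-preserving response (0 = exactly volume-preserving wall motion
#'   when `mapse = 0`).
#' @param circumferential_shortening_amplitude fractional circumferential
#'   shortening at the LV endocardial equator at ES.
#' @param mapse basal longitudinal excursion (mm).
#' @param twist_deg apex-to-base twist at ES (degrees).
#' @param noise_sd additive Gaussian image noise SD on \[0,1\] intensities.
#' @param seed RNG seed used by the renderer.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(lv_endo_radii = c(20, 20, 45),
                         lv_wall_thickness = 10,
                         rv_offset = c(26, 0, 5),
                         rv_radii = c(26, 22, 35),
                         rv_wall_thickness = 5,
                         base_truncation_height = 75,
                         grid_dim = c(96L, 96L, 16L),
                         grid_spacing = c(1.5, 1.5, 8),
                         n_frames = 30L,
                         es_frame = 15L,
                         thickening_amplitude = 0,
                         circumferential_shortening_amplitude = 0.15,
                         mapse = 12,
                         twist_deg = 8,
                         noise_sd = 0.05,
                         seed = 1L) {
  spec <- list(lv_endo_radii = as.numeric(lv_endo_radii),
               lv_wall_thickness = as.numeric(lv_wall_thickness),
               rv_offset = as.numeric(rv_offset),
               rv_radii = as.numeric(rv_radii),
               rv_wall_thickness = as.numeric(rv_wall_thickness),
               base_truncation_height = as.numeric(base_truncation_height),
               grid_dim = as.integer(grid_dim),
               grid_spacing = as.numeric(grid_spacing),
               n_frames = as.integer(n_frames),
               es_frame = as.integer(es_frame),
               thickening_amplitude = as.numeric(thickening_amplitude),
               circumferential_shortening_amplitude =
                 as.numeric(circumferential_shortening_amplitude),
               mapse = as.numeric(mapse),
               twist_deg = as.numeric(twist_deg),
               noise_sd = as.numeric(noise_sd),
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  ws_ph_validate(spec)
  spec
}

#' @method print phantom_spec
#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(paste0("phantom_spec: LV endo (%g, %g, %g) mm + %g mm wall, ",
                     "RV wall %g mm\n  grid %dx%dx%d @ (%g, %g, %g) mm, ",
                     "%d frames (ES = %d), MAPSE %g mm, noise %g, seed %d\n"),
              x$lv_endo_radii[1], x$lv_endo_radii[2], x$lv_endo_radii[3],
              x$lv_wall_thickness, x$rv_wall_thickness,
              x$grid_dim[1], x$grid_dim[2], x$grid_dim[3],
              x$grid_spacing[1], x$grid_spacing[2], x$grid_spacing[3],
              x$n_frames, x$es_frame, x$mapse, x$noise_sd, x$seed))
  invisible(x)
}

ws_ph_validate <- function(spec) {
  chk <- function(ok, fmt, ...) if (!ok) ws_stopf(fmt, ...)
  chk(all(spec$lv_endo_radii > 0), "lv_endo_radii must be positive")
  chk(all(spec$rv_radii > 0), "rv_radii must be positive")
  chk(spec$lv_wall_thickness > 0, "lv_wall_thickness must be positive")
  chk(spec$rv_wall_thickness > 0, "rv_wall_thickness must be positive")
  chk(spec$base_truncation_height > 0, "base_truncation_height must be positive")
  chk(all(spec$grid_spacing > 0), "grid_spacing must be positive on all axes")
  chk(all(spec$grid_dim >= 4), "grid_dim too small")
  chk(spec$n_frames >= 2, "n_frames must be at least 2")
  chk(spec$es_frame > 0 && spec$es_frame < spec$n_frames,
      "es_frame must satisfy 0 < es_frame < n_frames")
  chk(spec$noise_sd >= 0, "noise_sd must be nonnegative")
  chk(spec$mapse >= 0, "mapse must be nonnegative")
  chk(spec$mapse < spec$base_truncation_height,
      "mapse must be smaller than base_truncation_height")
  s <- spec$circumferential_shortening_amplitude
  chk(s >= 0 && s < 1, "circumferential_shortening_amplitude must be in [0, 1)")
  chk(spec$thickening_amplitude > -1, "thickening_amplitude must exceed -1")
  # bijectivity of both radial maps at peak contraction
  mp <- ws_ph_motion_pars(spec, spec$es_frame)
  rv_slope <- 1 - mp$rv$Delta * 1.5 / (mp$rv$ub - mp$rv$ua)
  if (2 * mp$lv$Delta >= mp$lv$uc || rv_slope <= 0.1)
    ws_stopf(paste0("radial motion is not invertible near a contraction ",
                    "axis: reduce circumferential_shortening_amplitude (%g), ",
                    "mapse (%g) or thickening_amplitude (%g)"),
             s, spec$mapse, spec$thickening_amplitude)
  invisible(TRUE)
}

# geometry constants derived from a spec (ED configuration, apex at z = 0)
ws_ph_geom <- function(spec) {
  zc <- spec$lv_wall_thickness + spec$lv_endo_radii[3]
  lv_c <- c(0, 0, zc)
  list(lv_center = lv_c,
       lv_endo = spec$lv_endo_radii,
       lv_epi = spec$lv_endo_radii + spec$lv_wall_thickness,
       rv_center = lv_c + spec$rv_offset,
       rv_endo = spec$rv_radii,
       rv_epi = spec$rv_radii + spec$rv_wall_thickness,
       z_base = spec$base_truncation_height)
}

ws_ellipsoid_q <- function(pts, center, semi) {
  ((pts[, 1] - center[1]) / semi[1])^2 +
  ((pts[, 2] - center[2]) / semi[2])^2 +
  ((pts[, 3] - center[3]) / semi[3])^2
}

# wall indicator in the ED (reference) configuration
ws_ph_inside_ed <- function(spec, pts) {
  g <- ws_ph_geom(spec)
  q_lvi <- ws_ellipsoid_q(pts, g$lv_center, g$lv_endo)
  q_lvo <- ws_ellipsoid_q(pts, g$lv_center, g$lv_epi)
  q_rvi <- ws_ellipsoid_q(pts, g$rv_center, g$rv_endo)
  q_rvo <- ws_ellipsoid_q(pts, g$rv_center, g$rv_epi)
  rv_cavity <- q_rvi < 1 & q_lvo >= 1
  (q_lvo < 1 | q_rvo < 1) & q_lvi >= 1 & !rv_cavity & pts[, 3] <= g$z_base
}

# --- analytic motion -------------------------------------------------------
# Composition of two cylindrical maps, each of the form (about a vertical
# axis through (cx, cy)):
#   z' = lambda_z z,  theta' = theta + tau z,  r'^2 = v(r^2, z)
# with v piecewise in u = r^2: a regularized quadratic core below u_c, an
# area-redistributing zone (u - Delta q(z))/sigma across the wall up to
# u_m, a C^1 blend back to unit slope by u_m2, and unit slope beyond, so
# circumferential shortening persists at all radii while the wall thickens.
# q(z) is a smoothstep ramp that switches the radial squeeze off toward the
# apex (avoiding crowding at the axis).  The primary map acts about the LV
# long axis and carries the longitudinal excursion, twist and wall-volume
# modulation; a secondary, weaker, purely radial squeeze about the RV
# centre gives the RV free wall its own tangential shortening and radial
# thickening.  All pieces, their gradients and the inverse are closed-form.
ws_ph_motion_pars <- function(spec, frame) {
  p <- cycle_phase(frame, spec$n_frames, 0, spec$es_frame)
  L <- spec$base_truncation_height
  lam_z <- 1 - spec$mapse * p / L
  mu <- 1 / (1 + spec$thickening_amplitude * p)
  sigma <- sqrt(lam_z) * mu
  r_s <- mean(spec$lv_endo_radii[1:2])
  s <- spec$circumferential_shortening_amplitude
  lv <- list(cx = 0, cy = 0, lam_z = lam_z,
             tau = spec$twist_deg * pi / 180 * p / L,
             sigma = sigma,
             Delta = r_s^2 * (1 - sigma * (1 - s * p)^2),
             uc = (0.9 * r_s)^2,
             um = (r_s + spec$lv_wall_thickness)^2,
             um2 = (r_s + spec$lv_wall_thickness + 8)^2,
             # the squeeze switches on only above the height where the
             # endocardium clears the regularized core radius, so no wall
             # tissue ever sits in the (compressive) core of the map
             qz0 = 0.47 * L, qz1 = 0.67 * L)
  lv$type <- "core"
  # RV squeeze about the cavity centroid: the area deficit ramps up INSIDE
  # the blood pool (no tissue there), so both the RV free wall and the
  # septum sit in the outer slope-1 zone, which shortens them tangentially
  # and thickens them radially while preserving volume exactly
  r_rv <- mean(spec$rv_radii[1:2])
  s_rv <- 0.4 * s
  rv <- list(cx = spec$rv_offset[1] + 0.45 * spec$rv_radii[1],
             cy = spec$rv_offset[2], lam_z = 1,
             tau = 0, sigma = 1, type = "ramp",
             Delta = (0.67 * r_rv)^2 * (1 - (1 - s_rv * p)^2),
             ua = (0.25 * r_rv)^2, ub = (0.5 * r_rv)^2,
             qz0 = 0.47 * L, qz1 = 0.67 * L)
  list(p = p, L = L, lam_z = lam_z, mu = mu, lv = lv, rv = rv)
}

# v(u, z), dv/du and dv/dz for the radial profile of one map component
ws_ph_v <- function(u, z, mp) {
  if (identical(mp$type, "ramp")) return(ws_ph_v_ramp(u, z, mp))
  ws_ph_v_core(u, z, mp)
}

# "ramp" profile: v = u - Delta q(z) rho(u), rho a smoothstep from 0 below
# u_a to 1 above u_b (identity core, full annulus-area deficit outside)
ws_ph_v_ramp <- function(u, z, mp) {
  q <- ws_smoothstep(z, mp$qz0, mp$qz1)
  qd <- ws_smoothstep_deriv(z, mp$qz0, mp$qz1)
  rho <- ws_smoothstep(u, mp$ua, mp$ub)
  rhod <- ws_smoothstep_deriv(u, mp$ua, mp$ub)
  Dq <- mp$Delta * q
  list(v = u - Dq * rho,
       v_u = 1 - Dq * rhod,
       v_z = -mp$Delta * qd * rho)
}

ws_ph_v_core <- function(u, z, mp) {
  q <- ws_smoothstep(z, mp$qz0, mp$qz1)
  qd <- ws_smoothstep_deriv(z, mp$qz0, mp$qz1)
  Dq <- mp$Delta * q
  sg <- mp$sigma
  a <- (1 - 2 * Dq / mp$uc) / sg
  b <- Dq / (sg * mp$uc^2)
  Du <- mp$um2 - mp$um
  c2 <- (1 - 1 / sg) / (2 * Du)
  vm <- (mp$um - Dq) / sg
  vm2 <- vm + Du * (1 / sg + 1) / 2
  v <- v_u <- v_z <- numeric(length(u))
  z1 <- u < mp$uc
  z2 <- !z1 & u < mp$um
  z3 <- u >= mp$um & u < mp$um2
  z4 <- u >= mp$um2
  if (any(z1)) {
    v[z1] <- a[z1] * u[z1] + b[z1] * u[z1]^2
    v_u[z1] <- a[z1] + 2 * b[z1] * u[z1]
    v_z[z1] <- (mp$Delta * qd[z1] / sg) *
      (-2 * u[z1] / mp$uc + (u[z1] / mp$uc)^2)
  }
  if (any(z2)) {
    v[z2] <- (u[z2] - Dq[z2]) / sg
    v_u[z2] <- 1 / sg
    v_z[z2] <- -mp$Delta * qd[z2] / sg
  }
  if (any(z3)) {
    s3 <- u[z3] - mp$um
    v[z3] <- vm[z3] + s3 / sg + c2 * s3^2
    v_u[z3] <- 1 / sg + 2 * c2 * s3
    v_z[z3] <- -mp$Delta * qd[z3] / sg
  }
  if (any(z4)) {
    v[z4] <- vm2[z4] + (u[z4] - mp$um2)
    v_u[z4] <- 1
    v_z[z4] <- -mp$Delta * qd[z4] / sg
  }
  list(v = v, v_u = v_u, v_z = v_z)
}

#' Analytic phantom motion at a frame
#'
#' Returns the prescribed phantom motion evaluated at one frame: the
#' deformation map relative to end-diastole, its exact deformation
#' gradient, and the closed-form inverse map.  The map is the identity at
#' the end-diastolic frame 0 and its gradient has positive determinant
#' everywhere.
#'
#' @param spec a [phantom_spec()].
#' @param frame frame index (0-based).
#' @return an object of class `analytic_motion` with elements `frame`,
#'   `phase`, and vectorized functions `map(X)`, `gradient(X)` (n x 9
#'   row-major tensors) and `inverse(x)`.
#' @export
analytic_motion <- function(spec, frame) {
  if (frame < 0 || frame >= spec$n_frames)
    ws_stopf("frame index out of range [0, %d)", spec$n_frames)
  mp <- ws_ph_motion_pars(spec, frame)
  structure(list(frame = frame, phase = mp$p,
                 map = function(X) ws_ph_map(spec, frame, X),
                 gradient = function(X) ws_ph_grad(spec, frame, X),
                 inverse = function(x) ws_ph_inverse(spec, frame, x)),
            class = "analytic_motion")
}

# forward map of one cylindrical component
ws_ph_map1 <- function(X, mc) {
  dx <- X[, 1] - mc$cx
  dy <- X[, 2] - mc$cy
  u <- dx^2 + dy^2
  vv <- ws_ph_v(u, X[, 3], mc)
  rp <- sqrt(vv$v)
  thp <- atan2(dy, dx) + mc$tau * X[, 3]
  cbind(mc$cx + rp * cos(thp), mc$cy + rp * sin(thp), mc$lam_z * X[, 3])
}

# exact deformation gradient of one cylindrical component (n x 9 row-major)
ws_ph_grad1 <- function(X, mc) {
  dx <- X[, 1] - mc$cx
  dy <- X[, 2] - mc$cy
  r <- sqrt(dx^2 + dy^2)
  u <- r^2
  z <- X[, 3]
  vv <- ws_ph_v(u, z, mc)
  rp <- sqrt(vv$v)
  th <- atan2(dy, dx)
  thp <- th + mc$tau * z
  cr <- cos(th); sr <- sin(th); cp <- cos(thp); sp <- sin(thp)
  eps <- 1e-9
  onaxis <- r < eps | rp < eps
  drp_dr <- ifelse(onaxis, sqrt(pmax(vv$v_u, 0)), r * vv$v_u / pmax(rp, eps))
  rp_r <- ifelse(onaxis, sqrt(pmax(vv$v_u, 0)), rp / pmax(r, eps))
  drp_dz <- ifelse(rp < eps, 0, vv$v_z / (2 * pmax(rp, eps)))
  F <- matrix(0, nrow(X), 9)
  F[, 1] <- drp_dr * cp * cr + rp_r * sp * sr     # F11
  F[, 2] <- drp_dr * cp * sr - rp_r * sp * cr     # F12
  F[, 3] <- drp_dz * cp - rp * mc$tau * sp        # F13
  F[, 4] <- drp_dr * sp * cr - rp_r * cp * sr     # F21
  F[, 5] <- drp_dr * sp * sr + rp_r * cp * cr     # F22
  F[, 6] <- drp_dz * sp + rp * mc$tau * cp        # F23
  F[, 9] <- mc$lam_z                              # F33
  F
}

# inverse of one cylindrical component (closed form for the "core"
# profile; monotone Newton for the "ramp" profile, whose v_u >= 0.5)
ws_ph_inverse1 <- function(x, mc) {
  if (identical(mc$type, "ramp")) {
    z <- x[, 3] / mc$lam_z
    dx <- x[, 1] - mc$cx
    dy <- x[, 2] - mc$cy
    vv <- dx^2 + dy^2
    u <- vv + mc$Delta * ws_smoothstep(z, mc$qz0, mc$qz1)  # upper start
    for (it in 1:40) {
      f <- ws_ph_v_ramp(u, z, mc)
      step <- (f$v - vv) / f$v_u
      u <- pmax(u - step, 0)
      if (max(abs(step)) < 1e-12) break
    }
    th <- atan2(dy, dx) - mc$tau * z
    r <- sqrt(pmax(u, 0))
    return(cbind(mc$cx + r * cos(th), mc$cy + r * sin(th), z))
  }
  z <- x[, 3] / mc$lam_z
  q <- ws_smoothstep(z, mc$qz0, mc$qz1)
  Dq <- mc$Delta * q
  sg <- mc$sigma
  a <- (1 - 2 * Dq / mc$uc) / sg
  b <- Dq / (sg * mc$uc^2)
  Du <- mc$um2 - mc$um
  c2 <- (1 - 1 / sg) / (2 * Du)
  vm <- (mc$um - Dq) / sg
  vm2 <- vm + Du * (1 / sg + 1) / 2
  vc <- (mc$uc - Dq) / sg
  dx <- x[, 1] - mc$cx
  dy <- x[, 2] - mc$cy
  vv <- dx^2 + dy^2
  u <- numeric(length(vv))
  i4 <- vv >= vm2
  i3 <- !i4 & vv >= vm
  i2 <- !i4 & !i3 & vv >= vc
  i1 <- !(i4 | i3 | i2)
  u[i4] <- mc$um2 + vv[i4] - vm2[i4]
  if (any(i3)) {
    d <- vv[i3] - vm[i3]
    disc <- pmax(1 / sg^2 + 4 * c2 * d, 0)
    u[i3] <- mc$um + 2 * d / (1 / sg + sqrt(disc))
  }
  u[i2] <- sg * vv[i2] + Dq[i2]
  if (any(i1)) {
    disc <- pmax(a[i1]^2 + 4 * b[i1] * vv[i1], 0)
    u[i1] <- 2 * vv[i1] / (a[i1] + sqrt(disc))
  }
  th <- atan2(dy, dx) - mc$tau * z
  r <- sqrt(pmax(u, 0))
  cbind(mc$cx + r * cos(th), mc$cy + r * sin(th), z)
}

# composed phantom motion: RV squeeze first, then the LV-axis map
ws_ph_map <- function(spec, frame, X) {
  mp <- ws_ph_motion_pars(spec, frame)
  ws_ph_map1(ws_ph_map1(X, mp$rv), mp$lv)
}

ws_ph_grad <- function(spec, frame, X) {
  mp <- ws_ph_motion_pars(spec, frame)
  Y <- ws_ph_map1(X, mp$rv)
  ws_mat3_mul(ws_ph_grad1(Y, mp$lv), ws_ph_grad1(X, mp$rv))
}

ws_ph_inverse <- function(spec, frame, x) {
  mp <- ws_ph_motion_pars(spec, frame)
  ws_ph_inverse1(ws_ph_inverse1(x, mp$lv), mp$rv)
}

# --- mesh -------------------------------------------------------------------

#' Tetrahedral mesh of the phantom at end-systole
#'
#' Meshes the end-systolic wall (the tracking reference configuration) with
#' the conforming lattice mesher, tags the boundary facets (LV endocardium,
#' RV endocardium, epicardium, base plane), and partitions the cells into
#' the three wall regions.
#'
#' @param spec a [phantom_spec()].
#' @param mesh_size lattice spacing / characteristic cell size (mm).
#' @return a [biv_mesh()] with regions assigned.
#' @export
make_phantom_mesh <- function(spec, mesh_size = 3.5) {
  g <- ws_ph_geom(spec)
  es <- spec$es_frame
  inv <- function(x) ws_ph_inverse(spec, es, x)
  inside <- function(pts) ws_ph_inside_ed(spec, inv(pts))
  lo <- c(min(-g$lv_epi[1], g$rv_center[1] - g$rv_epi[1]) - 1,
          min(-g$lv_epi[2], g$rv_center[2] - g$rv_epi[2]) - 1,
          -1)
  hi <- c(max(g$lv_epi[1], g$rv_center[1] + g$rv_epi[1]) + 1,
          max(g$lv_epi[2], g$rv_center[2] + g$rv_epi[2]) + 1,
          g$z_base + 1)
  # classify boundary facets by the region just OUTSIDE them: a probe point
  # a fraction of a lattice cell along the outward normal is pulled back to
  # the reference configuration and tested against LV cavity, RV cavity,
  # the base cut, or the exterior.  (Tagging by nearest analytic surface
  # would mislabel the septal endocardium, which geometrically lies on the
  # LV epicardial ellipsoid but faces the RV blood pool.)
  classify <- function(centroid, normal) {
    tag <- rep(NA_character_, nrow(centroid))
    todo <- rep(TRUE, nrow(centroid))
    for (delta in c(0.5, 1.0, 0.25) * mesh_size) {
      if (!any(todo)) break
      probe <- centroid[todo, , drop = FALSE] +
        delta * normal[todo, , drop = FALSE]
      Xp <- inv(probe)
      in_wall <- ws_ph_inside_ed(spec, Xp)
      q_lvi <- ws_ellipsoid_q(Xp, g$lv_center, g$lv_endo)
      q_lvo <- ws_ellipsoid_q(Xp, g$lv_center, g$lv_epi)
      q_rvi <- ws_ellipsoid_q(Xp, g$rv_center, g$rv_endo)
      t <- ifelse(Xp[, 3] > g$z_base, "BASE",
           ifelse(q_lvi < 1, "LV_ENDO",
           ifelse(q_rvi < 1 & q_lvo >= 1, "RV_ENDO", "EPI")))
      t[in_wall] <- NA_character_  # probe aliased into the wall: retry
      tag[todo] <- t
      todo[todo] <- is.na(t)
    }
    # lateral staircase facets whose probes stay inside the wall inherit
    # the tag of the nearest resolved facet (same staircase surface)
    if (any(is.na(tag)) && any(!is.na(tag))) {
      miss <- which(is.na(tag))
      have <- which(!is.na(tag))
      for (i in miss) {
        d2 <- (centroid[have, 1] - centroid[i, 1])^2 +
              (centroid[have, 2] - centroid[i, 2])^2 +
              (centroid[have, 3] - centroid[i, 3])^2
        tag[i] <- tag[have[which.min(d2)]]
      }
    }
    tag[is.na(tag)] <- "EPI"
    tag
  }
  mesh <- lattice_tet_mesh(inside, rbind(lo, hi), mesh_size,
                           classify = classify, long_axis = c(0, 0, 1),
                           require_tags = TRUE)
  mesh$regions <- partition_regions(mesh)
  attr(mesh, "phantom_spec") <- spec
  attr(mesh, "mesh_size") <- mesh_size
  mesh
}

# --- rendering --------------------------------------------------------------

#' Render the phantom cine image series
#'
#' One volume per frame: voxels inside the deformed wall are bright (1.0),
#' background dark (0.0).  Partial volume is modelled by 2x supersampling
#' per axis; Gaussian noise of `noise_sd` is then added with the spec's
#' seed and intensities are clipped to \[0, 1\].
#'
#' @param spec a [phantom_spec()].
#' @return an [image_series()] of `n_frames` volumes.
#' @export
render_image_series <- function(spec) {
  g <- ws_ph_geom(spec)
  dm <- spec$grid_dim
  sp <- spec$grid_spacing
  center <- c((min(-g$lv_epi[1], g$rv_center[1] - g$rv_epi[1]) +
               max(g$lv_epi[1], g$rv_center[1] + g$rv_epi[1])) / 2,
              0, g$z_base * 0.47)
  origin <- center - (dm - 1) / 2 * sp
  affine <- diag(4)
  affine[1:3, 1:3] <- diag(sp)
  affine[1:3, 4] <- origin
  xs <- origin[1] + (0:(dm[1] - 1)) * sp[1]
  ys <- origin[2] + (0:(dm[2] - 1)) * sp[2]
  zs <- origin[3] + (0:(dm[3] - 1)) * sp[3]
  base_pts <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  # 2x supersampling in-plane; 4x through-plane, where the voxel is several
  # times coarser and edge coverage would otherwise be strongly quantized
  offs <- as.matrix(expand.grid(dx = c(-0.25, 0.25) * sp[1],
                                dy = c(-0.25, 0.25) * sp[2],
                                dz = c(-0.375, -0.125, 0.125, 0.375) * sp[3]))
  frames <- vector("list", spec$n_frames)
  if (spec$noise_sd > 0) {
    if (exists(".Random.seed", envir = .GlobalEnv)) {
      old_seed <- get(".Random.seed", envir = .GlobalEnv)
      on.exit(assign(".Random.seed", old_seed, envir = .GlobalEnv), add = TRUE)
    }
    set.seed(spec$seed)
  }
  for (f in seq_len(spec$n_frames)) {
    acc <- numeric(nrow(base_pts))
    for (o in seq_len(nrow(offs))) {
      pts <- base_pts + rep(offs[o, ], each = nrow(base_pts))
      Xr <- ws_ph_inverse(spec, f - 1, pts)
      acc <- acc + ws_ph_inside_ed(spec, Xr)
    }
    img <- acc / nrow(offs)
    if (spec$noise_sd > 0)
      img <- img + stats::rnorm(length(img), 0, spec$noise_sd)
    frames[[f]] <- array(pmin(pmax(img, 0), 1), dim = dm)
  }
  image_series(frames, affine = affine,
               frame_times = (0:(spec$n_frames - 1)) / spec$n_frames,
               es_index = spec$es_frame, ed_index = 0L,
               normalized = TRUE)
}

# --- ground truth -----------------------------------------------------------

#' Ground-truth strain curves of the phantom
#'
#' Evaluates the analytic deformation gradient at the cell centroids of the
#' end-systolic phantom mesh for every frame and pushes it through the same
#' end-diastolic remapping, triad projection and region-averaging code path
#' as the tracked pipeline, yielding exact reference strain-time curves.
#'
#' @param spec a [phantom_spec()].
#' @param mesh optional precomputed phantom mesh (built if `NULL`).
#' @param dirs optional precomputed [build_directions()] field.
#' @param mesh_size forwarded to [make_phantom_mesh()] when `mesh` is `NULL`.
#' @param weighted volume-weighted region averaging (default unweighted).
#' @return a `strain_curves` object (see [compute_strain_curves()]).
#' @export
ground_truth_strains <- function(spec, mesh = NULL, dirs = NULL,
                                 mesh_size = 3.5, weighted = FALSE) {
  if (is.null(mesh)) mesh <- make_phantom_mesh(spec, mesh_size)
  if (is.null(dirs)) dirs <- build_directions(mesh)
  es <- spec$es_frame
  xc <- ws_cell_centroids(mesh)
  X0 <- ws_ph_inverse(spec, es, xc)
  Fes_inv <- ws_mat3_inv(ws_ph_grad(spec, es, X0))
  # per-frame gradient relative to the ES configuration (shared code path
  # with the tracked solution, which also references ES)
  F_frames <- lapply(0:(spec$n_frames - 1), function(f)
    ws_mat3_mul(ws_ph_grad(spec, f, X0), Fes_inv))
  compute_strain_curves(F_frames, mesh, dirs,
                        frame_times = (0:(spec$n_frames - 1)) / spec$n_frames,
                        ed_index = 0L, es_index = es, weighted = weighted)
}
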