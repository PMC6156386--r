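#' Registration configuration
#'
#' Parameters of the hyperelastic warping energy and its minimization.
#' `gamma` is the intensity-mismatch penalty factor (0.005 by default, the
#' value used for all cases in the source framework's regime of raw scanner
#' intensities is retained on normalized intensities with a correspondingly
#' softer material).  `C1` is the Neo-Hookean modulus of the regularizer;
#' the default is set by a force-balance argument (see the methods
#' vignette) so that typical image forces exceed elastic restoring forces
#' by roughly an order of magnitude at physiological strain.  `kappa`
#' penalizes volume change, stabilizing the registration against element
#' inversion.
#'
#' @param C1 Neo-Hookean modulus (dimensionless on \[0,1\] intensities).
#' @param kappa volumetric penalty modulus.
#' @param gamma intensity-mismatch penalty factor.
#' @param mapse basal longitudinal excursion amplitude (mm).
#' @param bc_profile named phase profile for the basal boundary condition;
#'   only `"sin2"` (the [cycle_phase()] profile) is provided.
#' @param tol relative energy-decrease convergence tolerance per frame.
#' @param maxit maximum optimizer iterations per frame.
#' @param smooth_sd Gaussian presmoothing SD of the image term, in voxels
#'   per axis; the default smooths less through-plane, where clinical
#'   short-axis voxels are already several times coarser.
#' @return an object of class `warp_config`.
#' @export
warp_config <- function(C1 = 2e-5, kappa = 5e-5, gamma = 0.005,
                        mapse = 0, bc_profile = "sin2",
                        tol = 1e-6, maxit = 300L, smooth_sd = c(1, 1, 0.5)) {
  if (C1 <= 0) ws_stopf("C1 must be positive")
  if (gamma <= 0) ws_stopf("gamma must be positive")
  if (kappa < 0) ws_stopf("kappa must be nonnegative")
  if (tol <= 0) ws_stopf("tol must be positive")
  if (maxit < 1) ws_stopf("maxit must be at least 1")
  if (mapse < 0) ws_stopf("mapse must be nonnegative")
  if (!identical(bc_profile, "sin2"))
    ws_stopf("unknown bc_profile: %s", bc_profile)
  structure(list(C1 = C1, kappa = kappa, gamma = gamma, mapse = mapse,
                 bc_profile = bc_profile, tol = tol,
                 maxit = as.integer(maxit), smooth_sd = smooth_sd),
            class = "warp_config")
}

#' Neo-Hookean strain energy density
#'
#' The material model of the warping regularizer in its classical printed
#' form `W = C1 (I1 - 3)`, with `I1 = tr C` the first invariant of the
#' right Cauchy-Green tensor `C = F^T F`.  (The assembled registration
#' energy uses the stress-free isochoric/volumetric split of the same
#' material so that the undeformed state carries no stress; both coincide
#' on isochoric deformations.  See the methods vignette.)
#'
#' @param C symmetric positive-definite 3 x 3 right Cauchy-Green tensor.
#' @param C1 material constant.
#' @return energy density `W`.
#' @export
neo_hookean_energy_density <- function(C, C1 = 1) {
  C <- as.matrix(C)
  if (!identical(dim(C), c(3L, 3L)) || max(abs(C - t(C))) > 1e-8)
    ws_stopf("C must be a symmetric 3 x 3 tensor")
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    ws_stopf("C must be positive-definite (min eigenvalue %g)", min(ev))
  C1 * (sum(diag(C)) - 3)
}

#' Image similarity penalty
#'
#' Pointwise energy `U = gamma/2 (r - t)^2` coupling the template intensity
#' (`R(X)`, argument `r`) to the target intensity (`T(phi(X))`, argument
#' `t`).
#'
#' @param r template intensity (vectorized).
#' @param t target intensity.
#' @param gamma penalty factor.
#' @return penalty density values.
#' @export
similarity_penalty <- function(r, t, gamma = 0.005) {
  gamma / 2 * (r - t)^2
}

#' Prescribed basal longitudinal displacement
#'
#' Longitudinal displacement applied to the base nodes, expressed relative
#' to the end-systolic configuration used as tracking origin:
#' `d(t) = mapse * (1 - phase(t))` along the apex-to-base axis, so the base
#' sits `mapse` above its contracted position at end-diastole and at 0 at
#' end-systole.  The phase profile is the [cycle_phase()] sine-squared law.
#'
#' @param frame frame index (0-based).
#' @param config a [warp_config()] carrying `mapse`.
#' @param series an [image_series()] supplying frame count and ES/ED
#'   indices.
#' @return displacement in mm along `long_axis`.
#' @export
basal_displacement <- function(frame, config, series) {
  n <- length(series$frames)
  ph <- cycle_phase(frame, n, series$ed_index, series$es_index)
  config$mapse * (1 - ph)
}

# 4-point tetrahedral quadrature (barycentric weights, equal 1/4 weights)
ws_qp4 <- function() {
  a <- (5 + 3 * sqrt(5)) / 20
  b <- (5 - sqrt(5)) / 20
  rbind(c(a, b, b, b), c(b, a, b, b), c(b, b, a, b), c(b, b, b, a))
}

# precomputed registration context: P1 geometry, quadrature, template
# intensities R sampled once at the quadrature points of the undeformed
# (end-systolic) mesh
ws_prepare_warp <- function(mesh, series, config,
                            template_frame = series$es_index) {
  geom <- ws_tet_geom(mesh)
  if (any(geom$vol <= 0)) ws_stopf("mesh has non-positive cell volumes")
  qpw <- ws_qp4()
  m <- nrow(mesh$cells)
  pts <- matrix(0, m * 4, 3)
  for (q in 1:4) {
    qp <- qpw[q, 1] * mesh$nodes[mesh$cells[, 1], , drop = FALSE] +
          qpw[q, 2] * mesh$nodes[mesh$cells[, 2], , drop = FALSE] +
          qpw[q, 3] * mesh$nodes[mesh$cells[, 3], , drop = FALSE] +
          qpw[q, 4] * mesh$nodes[mesh$cells[, 4], , drop = FALSE]
    pts[seq(q, by = 4, length.out = m), ] <- qp
  }
  fd <- ws_frame_data(series, template_frame, config$smooth_sd)
  sg <- .ws_sample_grad(fd$T, fd$gx, fd$gy, fd$gz, fd$dim, fd$w2v, pts)
  Rq <- matrix(sg$value, m, 4, byrow = TRUE)
  base_nodes <- sort(unique(as.vector(
    mesh$facets[mesh$facet_tags == "BASE", , drop = FALSE])))
  # Sobolev preconditioner (lumped mass + scaled stiffness): descent
  # directions are smoothed over ~10 cell sizes, which propagates boundary
  # data and long-range image forces through the soft elastic interior
  K <- ws_stiffness(mesh, geom)
  mass <- rowsum(rep(geom$vol / 4, 4), as.vector(mesh$cells),
                 reorder = TRUE)[, 1]
  hbar <- mean(geom$vol)^(1 / 3)
  M <- Matrix::Diagonal(x = mass)
  Pfact <- Matrix::Cholesky(Matrix::forceSymmetric(M + (10 * hbar)^2 * K))
  list(geom = geom, qpw = qpw, Rq = Rq, base_nodes = base_nodes,
       Pfact = Pfact)
}

#' Warping energy and gradient
#'
#' Evaluates `E(u) = sum W dV + sum gamma/2 (R - T(phi))^2 dV` over the
#' mesh, with the elastic term integrated at one point per tetrahedron
#' (P1 elements carry a constant deformation gradient) and the image term
#' at four points per tetrahedron.  The analytic nodal gradient is
#' assembled alongside.  Both template and target intensities are taken
#' from the same Gaussian-presmoothed copies so the analytic gradient is
#' the exact derivative of the reported energy.
#'
#' @param mesh a [biv_mesh()] built at end-systole.
#' @param u n x 3 nodal displacement matrix (mm).
#' @param series a normalized [image_series()].
#' @param target_frame frame index of the target image T (0-based).
#' @param config a [warp_config()].
#' @param template_frame frame index of the template R (default ES).
#' @param want_grad assemble the gradient (disable for energy-only audit).
#' @return list with `energy`, `elastic`, `mismatch`, `gradient` (n x 3)
#'   and `feasible` (`FALSE` when an element is inverted, energy `Inf`).
#' @export
warping_energy <- function(mesh, u, series, target_frame, config = warp_config(),
                           template_frame = series$es_index, want_grad = TRUE) {
  prep <- ws_prepare_warp(mesh, series, config, template_frame)
  fd <- ws_frame_data(series, target_frame, config$smooth_sd)
  u <- as.matrix(u)
  if (any(!is.finite(u))) ws_stopf("displacement must be finite")
  .ws_energy(mesh$nodes, mesh$cells, prep$geom$dndx, prep$geom$vol,
             prep$qpw, prep$Rq, fd$T, fd$dim, fd$w2v,
             config$C1, config$kappa, config$gamma, u,
             use_image = TRUE, want_grad = want_grad)
}

#' Register the mesh to one target frame
#'
#' Minimizes the warping energy over nodal displacements with the
#' longitudinal component of the base nodes fixed to `bc`, by projected
#' Barzilai-Borwein descent with a backtracking line search that rejects
#' any step inverting an element.  The returned energy never exceeds the
#' energy of the initial iterate.
#'
#' @param mesh a [biv_mesh()] built at end-systole.
#' @param series a normalized [image_series()].
#' @param target_frame target frame index (0-based).
#' @param config a [warp_config()].
#' @param u_init initial displacement (zero if `NULL`); must be feasible.
#' @param bc prescribed basal longitudinal displacement (mm), see
#'   [basal_displacement()].
#' @param prep precomputed context from an earlier call (internal reuse).
#' @return list with `u`, `energy`, `energies` (per accepted iterate),
#'   `iterations`, `converged`, `line_search_failed`.
#' @export
register_frame <- function(mesh, series, target_frame, config = warp_config(),
                           u_init = NULL, bc = 0, prep = NULL) {
  if (is.null(prep)) prep <- ws_prepare_warp(mesh, series, config)
  if (is.null(u_init)) u_init <- matrix(0, nrow(mesh$nodes), 3)
  fd <- ws_frame_data(series, target_frame, config$smooth_sd)
  laxis <- mesh$long_axis
  bn <- prep$base_nodes
  project_u <- function(u) {
    d <- u[bn, , drop = FALSE] %*% laxis
    u[bn, ] <- u[bn, , drop = FALSE] + (bc - as.numeric(d)) %o% laxis
    u
  }
  project_g <- function(g) {
    d <- g[bn, , drop = FALSE] %*% laxis
    g[bn, ] <- g[bn, , drop = FALSE] - as.numeric(d) %o% laxis
    g
  }
  evalE <- function(u, want_grad)
    .ws_energy(mesh$nodes, mesh$cells, prep$geom$dndx, prep$geom$vol,
               prep$qpw, prep$Rq, fd$T, fd$dim, fd$w2v,
               config$C1, config$kappa, config$gamma, u,
               use_image = TRUE, want_grad = want_grad)
  u <- as.matrix(u_init)
  # move to the new basal level by a uniform (always feasible) shift of
  # the whole mesh before pinning the base exactly; projecting only the
  # base nodes can invert base-layer elements when the prescribed level
  # changes by more than a cell size between frames
  d0 <- mean(u[bn, , drop = FALSE] %*% laxis)
  u <- u + rep(bc - d0, nrow(u)) %o% laxis
  u <- project_u(u)
  en <- evalE(u, TRUE)
  if (!en$feasible)
    ws_stopf("initial displacement is infeasible (inverted element)")
  E <- en$energy
  g <- project_g(en$gradient)
  energies <- E
  converged <- FALSE
  warn <- FALSE
  iters <- 0L
  # L-BFGS with the Sobolev operator as initial metric: curvature pairs
  # capture both the long-range (boundary-condition) and local (edge
  # alignment) modes of the energy
  mem <- 8L
  Slist <- list(); Ylist <- list(); PYlist <- list()
  for (it in seq_len(config$maxit)) {
    if (max(abs(g)) < 1e-12) { converged <- TRUE; break }
    k <- length(Slist)
    q <- g
    avec <- numeric(k)
    if (k > 0) {
      for (i in k:1) {
        rho <- 1 / sum(Slist[[i]] * Ylist[[i]])
        avec[i] <- rho * sum(Slist[[i]] * q)
        q <- q - avec[i] * Ylist[[i]]
      }
    }
    r <- as.matrix(Matrix::solve(prep$Pfact, q))
    if (k > 0) {
      theta <- sum(Slist[[k]] * Ylist[[k]]) / sum(Ylist[[k]] * PYlist[[k]])
      r <- theta * r
      for (i in 1:k) {
        rho <- 1 / sum(Slist[[i]] * Ylist[[i]])
        b <- rho * sum(Ylist[[i]] * r)
        r <- r + Slist[[i]] * (avec[i] - b)
      }
    }
    d <- project_g(r)
    gd <- sum(g * d)
    if (gd <= 0) {  # not a descent direction: reset to the Sobolev step
      Slist <- list(); Ylist <- list(); PYlist <- list()
      d <- project_g(as.matrix(Matrix::solve(prep$Pfact, g)))
      gd <- sum(g * d)
      if (gd <= 0) { converged <- TRUE; break }
    }
    a <- if (length(Slist) > 0) 1 else 0.5 / max(abs(d))
    accepted <- FALSE
    for (bt in 1:40) {
      utry <- u - a * d
      et <- evalE(utry, FALSE)
      if (et$feasible && et$energy <= E - 1e-4 * a * gd) {
        accepted <- TRUE
        break
      }
      a <- a / 2
    }
    if (!accepted) { warn <- TRUE; break }
    dec <- E - et$energy
    en <- evalE(utry, TRUE)
    gnew <- project_g(en$gradient)
    svec <- utry - u
    yvec <- gnew - g
    if (sum(svec * yvec) > 1e-14) {
      Slist <- c(Slist, list(svec))
      Ylist <- c(Ylist, list(yvec))
      PYlist <- c(PYlist, list(as.matrix(Matrix::solve(prep$Pfact, yvec))))
      if (length(Slist) > mem) {
        Slist <- Slist[-1]; Ylist <- Ylist[-1]; PYlist <- PYlist[-1]
      }
    }
    u <- utry
    g <- gnew
    E <- en$energy
    energies <- c(energies, E)
    iters <- it
    if (dec < config$tol * max(abs(energies[length(energies) - 1]), 1e-12)) {
      converged <- TRUE
      break
    }
  }
  list(u = u, energy = E, energies = energies, iterations = iters,
       converged = converged, line_search_failed = warn)
}

#' Track the mesh through the cardiac cycle
#'
#' Visits the frames in temporal order starting at end-systole and wrapping
#' around the cycle, warm-starting each registration from the previous
#' frame's solution.  The template R is the end-systolic frame sampled once
#' on the undeformed mesh; displacement at ES is exactly zero.  Per-frame
#' deformation gradients, Jacobians and energy logs are returned.
#'
#' @param mesh a [biv_mesh()] built at end-systole (regions optional).
#' @param series a normalized [image_series()].
#' @param config a [warp_config()]; its `mapse` drives the basal boundary
#'   condition.
#' @return an object of class `motion_solution`: lists `u` and `F` indexed
#'   by frame + 1, per-cell Jacobians `J` (m x n matrix), per-frame
#'   iteration/energy logs, and the series bookkeeping.
#' @export
track_cycle <- function(mesh, series, config = warp_config()) {
  if (!series$normalized)
    ws_stopf("series must be normalized first (see normalize_series)")
  n <- length(series$frames)
  es <- series$es_index
  prep <- ws_prepare_warp(mesh, series, config)
  visit <- (es + 0:(n - 1)) %% n
  nn <- nrow(mesh$nodes)
  u <- vector("list", n)
  u[[es + 1]] <- matrix(0, nn, 3)
  log <- vector("list", n)
  log[[es + 1]] <- list(frame = es, iterations = 0L, energy = 0,
                        converged = TRUE, line_search_failed = FALSE)
  prev <- u[[es + 1]]
  last_good <- es
  for (f in visit[-1]) {
    bc <- basal_displacement(f, config, series)
    res <- tryCatch(
      register_frame(mesh, series, f, config, u_init = prev, bc = bc,
                     prep = prep),
      error = function(e)
        ws_stopf("tracking aborted at frame %d (last good frame %d): %s",
                 f, last_good, conditionMessage(e)))
    u[[f + 1]] <- res$u
    log[[f + 1]] <- list(frame = f, iterations = res$iterations,
                         energy = res$energy, energies = res$energies,
                         converged = res$converged,
                         line_search_failed = res$line_search_failed)
    prev <- res$u
    last_good <- f
  }
  m <- nrow(mesh$cells)
  F <- vector("list", n)
  J <- matrix(0, m, n)
  for (f in 0:(n - 1)) {
    F[[f + 1]] <- .ws_def_grads(mesh$nodes, mesh$cells, prep$geom$dndx,
                                u[[f + 1]])
    J[, f + 1] <- ws_mat3_det(F[[f + 1]])
  }
  if (any(J <= 0))
    ws_stopf("inverted element in accepted solution (should not happen)")
  # mismatch audit: final vs zero-displacement image energy per frame
  mismatch <- matrix(NA_real_, n, 2,
                     dimnames = list(NULL, c("at_zero", "final")))
  u0 <- matrix(0, nn, 3)
  for (f in 0:(n - 1)) {
    fd <- ws_frame_data(series, f, config$smooth_sd)
    e0 <- .ws_energy(mesh$nodes, mesh$cells, prep$geom$dndx, prep$geom$vol,
                     prep$qpw, prep$Rq, fd$T, fd$dim,
                     fd$w2v, config$C1, config$kappa, config$gamma, u0,
                     TRUE, FALSE)
    e1 <- .ws_energy(mesh$nodes, mesh$cells, prep$geom$dndx, prep$geom$vol,
                     prep$qpw, prep$Rq, fd$T, fd$dim,
                     fd$w2v, config$C1, config$kappa, config$gamma,
                     u[[f + 1]], TRUE, FALSE)
    mismatch[f + 1, ] <- c(e0$mismatch, e1$mismatch)
  }
  structure(list(u = u, F = F, J = J, log = log, mismatch = mismatch,
                 frame_times = series$frame_times, es_index = es,
                 ed_index = series$ed_index, visit_order = visit,
                 config = config),
            class = "motion_solution")
}

#' @method print motion_solution
#' @export
print.motion_solution <- function(x, ...) {
  n <- length(x$u)
  iters <- vapply(x$log, function(l) l$iterations, integer(1))
  cat(sprintf(paste0("motion_solution: %d frames (ES = %d, ED = %d), ",
                     "min J = %.3f, iterations %d-%d\n"),
              n, x$es_index, x$ed_index, min(x$J), min(iters), max(iters)))
  invisible(x)
}
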