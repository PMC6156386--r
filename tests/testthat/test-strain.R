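test_that("reference remapping follows the relative-deformation form", {
  F_ed <- diag(c(1.2, 0.9, 1.05))
  expect_lt(max(abs(remap_reference(F_ed, F_ed))), 1e-14)
  E <- remap_reference(diag(c(1.1, 1, 1)), diag(3))
  expect_equal(E[1, 1], (1.1^2 - 1) / 2, tolerance = 1e-12)
  expect_lt(max(abs(E - diag(c(E[1, 1], 0, 0)))), 1e-14)
  # rigid motion on top of the reference leaves zero strain
  th <- 0.5
  Q <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_lt(max(abs(remap_reference(Q %*% F_ed, F_ed))), 1e-12)
  expect_error(remap_reference(diag(3), diag(c(1, 1, 0))), "singular")
  expect_error(remap_reference(diag(c(-1, 1, 1)), diag(3)), "positive")
})

test_that("strain projection returns the triad-diagonal entries", {
  triad <- list(e_C = c(1, 0, 0), e_L = c(0, 1, 0), e_R = c(0, 0, 1))
  expect_equal(unname(project_strain(matrix(0, 3, 3), triad)), c(0, 0, 0))
  E <- diag(c(0.1, -0.05, 0.2))
  expect_equal(project_strain(E, triad),
               c(CC = 0.1, LL = -0.05, RR = 0.2))
  # rotated orthonormal triad picks out its own diagonal
  th <- 0.8
  eC <- c(cos(th), sin(th), 0)
  eL <- c(-sin(th), cos(th), 0)
  eR <- c(0, 0, 1)
  E2 <- 0.07 * outer(eC, eC) - 0.03 * outer(eL, eL) + 0.12 * outer(eR, eR)
  expect_equal(project_strain(E2, list(e_C = eC, e_L = eL, e_R = eR)),
               c(CC = 0.07, LL = -0.03, RR = 0.12), tolerance = 1e-12)
  expect_error(project_strain(E, list(e_C = c(1, 0, 0), e_L = c(1, 0, 0),
                                      e_R = c(0, 0, 1))), "orthonormal")
})

test_that("1D shortening gives the Green-Lagrange closed form -s + s^2/2", {
  for (s in c(0.05, 0.155, 0.3)) {
    F <- diag(c(1 - s, 1, 1))
    E <- remap_reference(F, diag(3))
    eps <- project_strain(E, list(e_C = c(1, 0, 0), e_L = c(0, 1, 0),
                                  e_R = c(0, 0, 1)))["CC"]
    expect_equal(unname(eps), -s + s^2 / 2, tolerance = 1e-12)
  }
})

test_that("region averaging is an element mean with optional volume weights", {
  mesh <- ws_fix("mesh_small")
  m <- nrow(mesh$cells)
  expect_equal(unname(region_average(rep(0.3, m), mesh)),
               rep(0.3, 3), tolerance = 1e-14)
  set.seed(9)
  v <- rnorm(m)
  ra <- region_average(v, mesh)
  for (r in names(ra)) {
    vals <- v[mesh$regions == r]
    expect_gte(ra[[r]], min(vals))
    expect_lte(ra[[r]], max(vals))
    expect_equal(ra[[r]], mean(vals), tolerance = 1e-14)
  }
  # volume weighting only differs on meshes with non-uniform cell volumes
  m3 <- mesh
  m3$nodes[, 3] <- m3$nodes[, 3] * (1 + 0.01 * m3$nodes[, 3])
  vols <- warpstrain:::ws_cell_volumes(m3$nodes, m3$cells)
  rw <- region_average(v, m3, weighted = TRUE)
  for (r in names(rw)) {
    sel <- m3$regions == r
    expect_equal(rw[[r]], sum(v[sel] * vols[sel]) / sum(vols[sel]),
                 tolerance = 1e-12)
  }
  expect_false(isTRUE(all.equal(unname(ra), unname(rw))))
  m2 <- mesh
  m2$regions <- NULL
  expect_error(region_average(v, m2), "region")
})

test_that("trace identity holds for orthonormal triads", {
  set.seed(5)
  for (i in 1:20) {
    F <- diag(3) + matrix(rnorm(9, 0, 0.1), 3, 3)
    E <- remap_reference(F, diag(3))
    Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    tri <- list(e_C = Q[, 1], e_L = Q[, 2], e_R = Q[, 3])
    eps <- project_strain(E, tri)
    expect_equal(sum(eps), sum(diag(E)), tolerance = 1e-12)
  }
})

test_that("strain curves vanish at ED and peaks obey sign conventions", {
  oracle <- ws_fix("oracle0")
  expect_lt(max(abs(oracle$strains[, , oracle$ed_index + 1])), 1e-12)
  pk <- oracle$peaks
  expect_true(all(pk$peak_percent[pk$component == "CC"] < 0))
  expect_true(all(pk$peak_percent[pk$component == "RR"] > 0))
  # monotone-to-ES curve peaks at ES
  expect_true(all(pk$peak_frame >= oracle$ed_index &
                  pk$peak_frame <= oracle$es_index))
  # zero curves give zero peaks
  m <- nrow(ws_fix("mesh0")$cells)
  Fz <- lapply(1:4, function(i) warpstrain:::ws_mat3_identity(m))
  cz <- compute_strain_curves(Fz, ws_fix("mesh0"), ws_fix("dirs0"),
                              ed_index = 0, es_index = 2)
  expect_true(all(cz$peaks$peak_percent == 0))
  # whole-cycle window is available
  pk2 <- peak_systolic(oracle, window = "cycle")
  expect_true(all(abs(pk2$peak_percent) >= abs(pk$peak_percent) - 1e-9))
})

test_that("a superimposed rotation changes no strain component", {
  mesh <- ws_fix("mesh0")
  dirs <- ws_fix("dirs0")
  spec <- ws_fix("spec0")
  xc <- warpstrain:::ws_cell_centroids(mesh)
  X0 <- warpstrain:::ws_ph_inverse(spec, spec$es_frame, xc)
  Fes_inv <- warpstrain:::ws_mat3_inv(
    warpstrain:::ws_ph_grad(spec, spec$es_frame, X0))
  frames <- c(0, 7, 15)
  F_list <- lapply(frames, function(f)
    warpstrain:::ws_mat3_mul(warpstrain:::ws_ph_grad(spec, f, X0), Fes_inv))
  c1 <- compute_strain_curves(F_list, mesh, dirs, ed_index = 0, es_index = 2)
  # rotating every tracked configuration (including ED) conjugates the
  # relative gradient; with the material triads carried along, strains
  # are unchanged
  th <- 0.6
  Q <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  Qm <- matrix(rep(as.numeric(t(Q)), each = nrow(xc)), nrow(xc), 9)
  F_rot <- lapply(F_list, function(F) warpstrain:::ws_mat3_mul(Qm, F))
  dirs_rot <- lapply(dirs, function(e) t(Q %*% t(e)))
  class(dirs_rot) <- class(dirs)
  c2 <- compute_strain_curves(F_rot, mesh, dirs_rot, ed_index = 0,
                              es_index = 2)
  expect_lt(max(abs(c1$strains - c2$strains)), 1e-12)
  # rotating the targets but not the ED reference also leaves strain
  # unchanged (rigid motion relative to the reference)
  F_mix <- c(F_list[1], lapply(F_list[-1], function(F)
    warpstrain:::ws_mat3_mul(Qm, F)))
  c3 <- compute_strain_curves(F_mix, mesh, dirs, ed_index = 0, es_index = 2)
  expect_lt(max(abs(c1$strains - c3$strains)), 1e-12)
})

test_that("default phantom wall volume is consistent at end-systole", {
  # mapse = 0, zero thickening: motion is exactly volume-preserving in the
  # wall, so region-averaged det F_rel at ES stays within 5% of 1
  spec <- phantom_spec(grid_dim = c(48, 48, 10), grid_spacing = c(2.5, 2.5, 8),
                       n_frames = 4, es_frame = 2, noise_sd = 0, mapse = 0,
                       thickening_amplitude = 0)
  mesh <- make_phantom_mesh(spec, 5)
  xc <- warpstrain:::ws_cell_centroids(mesh)
  X0 <- warpstrain:::ws_ph_inverse(spec, spec$es_frame, xc)
  J <- warpstrain:::ws_mat3_det(
    warpstrain:::ws_ph_grad(spec, spec$es_frame, X0))
  for (r in c("LV_FREE", "SEPTUM", "RV_FREE"))
    expect_lt(abs(mean(J[mesh$regions == r]) - 1), 0.05)
})
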