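test_that("phantom spec validation catches bad parameters", {
  expect_error(phantom_spec(lv_endo_radii = c(-1, 20, 45)), "positive")
  expect_error(phantom_spec(es_frame = 0), "es_frame")
  expect_error(phantom_spec(es_frame = 30), "es_frame")
  expect_error(phantom_spec(noise_sd = -0.1), "noise_sd")
  expect_error(phantom_spec(grid_spacing = c(1.5, 0, 8)), "spacing")
  # a shortening too violent for an invertible radial map names the knobs
  expect_error(phantom_spec(circumferential_shortening_amplitude = 0.45),
               "circumferential_shortening_amplitude")
})

test_that("analytic motion is the identity at end-diastole", {
  spec <- ws_fix("spec0")
  am <- analytic_motion(spec, 0)
  X <- cbind(runif(80, -30, 55), runif(80, -28, 28), runif(80, 1, 72))
  expect_lt(max(abs(am$map(X) - X)), 1e-12)
  F0 <- am$gradient(X)
  I9 <- matrix(rep(c(1, 0, 0, 0, 1, 0, 0, 0, 1), each = 80), 80, 9)
  expect_lt(max(abs(F0 - I9)), 1e-12)
  expect_error(analytic_motion(spec, 30), "range")
})

test_that("basal longitudinal excursion equals MAPSE at end-systole", {
  spec <- ws_fix("spec0")
  base_pt <- matrix(c(25, 0, spec$base_truncation_height), 1)
  x_es <- analytic_motion(spec, spec$es_frame)$map(base_pt)
  expect_equal(x_es[3], spec$base_truncation_height - spec$mapse,
               tolerance = 1e-12)
})

test_that("closed-form motion gradient matches central finite differences", {
  spec <- ws_fix("spec0")
  set.seed(11)
  X <- cbind(runif(60, -30, 55), runif(60, -28, 28), runif(60, 1, 72))
  for (frame in c(4, 8, 15, 22)) {
    am <- analytic_motion(spec, frame)
    Fa <- am$gradient(X)
    h <- 1e-5
    for (k in 1:3) {
      Xp <- X; Xp[, k] <- Xp[, k] + h
      Xm <- X; Xm[, k] <- Xm[, k] - h
      fd <- (am$map(Xp) - am$map(Xm)) / (2 * h)
      for (i in 1:3)
        expect_lt(max(abs(fd[, i] - Fa[, (i - 1) * 3 + k])), 1e-6)
    }
    # exact inverse and positive Jacobian
    expect_lt(max(abs(am$inverse(am$map(X)) - X)), 1e-7)
    expect_gt(min(warpstrain:::ws_mat3_det(Fa)), 0)
  }
})

test_that("rendered series has bright wall, dark background, and is seeded", {
  spec <- ws_fix("spec0")
  series <- ws_fix("series0")
  f0 <- series$frames[[1]]
  w2v <- warpstrain:::ws_world2vox(series$affine)
  vox <- function(p) {
    v <- round(w2v %*% c(p, 1)) + 1
    f0[v[1], v[2], v[3]]
  }
  expect_equal(vox(c(-25, 0, 55)), 1)   # mid LV free wall at ED
  expect_equal(vox(c(-48, -52, 10)), 0) # far background
  # determinism: same spec (same seed) gives bitwise-identical frames
  spec_n <- phantom_spec(grid_dim = c(32, 32, 6), n_frames = 3, es_frame = 1,
                         noise_sd = 0.05, seed = 7)
  expect_identical(render_image_series(spec_n)$frames,
                   render_image_series(spec_n)$frames)
})

test_that("volume-preserving motion keeps the bright-voxel volume within 5%", {
  # mapse = 0 and zero extra thickening make the wall motion exactly
  # volume-preserving
  spec <- phantom_spec(noise_sd = 0, mapse = 0, thickening_amplitude = 0)
  s <- render_image_series(spec)
  v_ed <- sum(s$frames[[1]] >= 0.5)
  v_es <- sum(s$frames[[spec$es_frame + 1]] >= 0.5)
  expect_lt(abs(v_es - v_ed) / v_ed, 0.05)
})

test_that("increasing thickening amplitude increases rendered ES wall volume", {
  vol_es <- vapply(c(0, 0.05, 0.1), function(thk) {
    sp <- phantom_spec(grid_dim = c(64, 64, 12), grid_spacing = c(2, 2, 8),
                       n_frames = 4, es_frame = 2, noise_sd = 0,
                       thickening_amplitude = thk)
    sum(render_image_series(sp)$frames[[3]] >= 0.5)
  }, numeric(1))
  expect_true(all(diff(vol_es) > 0))
})

test_that("zero-amplitude motion yields zero strain everywhere", {
  spec <- phantom_spec(grid_dim = c(48, 48, 10), grid_spacing = c(2.5, 2.5, 8),
                       n_frames = 4, es_frame = 2, noise_sd = 0,
                       mapse = 0, twist_deg = 0,
                       circumferential_shortening_amplitude = 0,
                       thickening_amplitude = 0)
  curves <- ground_truth_strains(spec, mesh_size = 5)
  expect_lt(max(abs(curves$strains)), 1e-12)
})

test_that("per-cell longitudinal stretch reproduces the closed form", {
  # F = I + (lambda - 1) e_L x e_L per cell: eps_LL = (lambda^2 - 1)/2
  # exactly, other components zero
  mesh <- ws_fix("mesh0")
  dirs <- ws_fix("dirs0")
  lambda <- 1.17
  m <- nrow(mesh$cells)
  Fm <- warpstrain:::ws_mat3_identity(m)
  for (i in 1:3) for (j in 1:3)
    Fm[, (i - 1) * 3 + j] <- Fm[, (i - 1) * 3 + j] +
      (lambda - 1) * dirs$e_L[, i] * dirs$e_L[, j]
  sc <- cell_strains(Fm, dirs)
  expect_lt(max(abs(sc[, "LL"] - (lambda^2 - 1) / 2)), 1e-10)
  expect_lt(max(abs(sc[, c("CC", "RR")])), 1e-10)
  for (r in c("LV_FREE", "SEPTUM", "RV_FREE"))
    expect_equal(unname(region_average(sc[, "LL"], mesh)[r]),
                 (lambda^2 - 1) / 2, tolerance = 1e-10)
})

test_that("default phantom oracle has physiological strain signs at ES", {
  oracle <- ws_fix("oracle0")
  es <- ws_fix("spec0")$es_frame + 1
  expect_true(all(oracle$strains[, "CC", es] < 0))
  expect_true(all(oracle$strains[, "LL", es] < 0))
  expect_true(all(oracle$strains[, "RR", es] > 0))
})

test_that("identical specs give identical meshes and oracle curves", {
  sp <- phantom_spec(grid_dim = c(48, 48, 10), grid_spacing = c(2.5, 2.5, 8),
                     n_frames = 4, es_frame = 2, noise_sd = 0)
  m1 <- make_phantom_mesh(sp, 5)
  m2 <- make_phantom_mesh(sp, 5)
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$cells, m2$cells)
  expect_identical(m1$regions, m2$regions)
  c1 <- ground_truth_strains(sp, mesh_size = 5)
  c2 <- ground_truth_strains(sp, mesh_size = 5)
  expect_identical(c1$strains, c2$strains)
})
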