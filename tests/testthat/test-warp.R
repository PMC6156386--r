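test_that("normalization maps series percentiles to [0,1] and is scale-free", {
  set.seed(1)
  frames <- lapply(1:3, function(i) array(runif(8 * 8 * 4), c(8, 8, 4)))
  aff <- diag(4)
  s1 <- normalize_series(frames, affine = aff, es_index = 1)
  s2 <- normalize_series(lapply(frames, function(f) f * 10 + 3),
                         affine = aff, es_index = 1)
  expect_equal(s1$frames, s2$frames, tolerance = 1e-12)
  expect_true(all(unlist(s1$frames) >= 0 & unlist(s1$frames) <= 1))
  expect_false(is.null(s1$normalization))
  expect_error(normalize_series(lapply(1:2, function(i) array(1, c(4, 4, 4))),
                                affine = aff, es_index = 1), "constant")
  # a single constant frame among normal frames is fine (series-wide scale)
  frames2 <- frames
  frames2[[2]] <- array(0.5, c(8, 8, 4))
  expect_s3_class(normalize_series(frames2, affine = aff, es_index = 1),
                  "image_series")
})

test_that("image sampling is exact at voxel centers and on linear ramps", {
  dm <- c(12, 10, 6)
  sp <- c(2, 2, 4)
  aff <- diag(4); aff[1:3, 1:3] <- diag(sp); aff[1:3, 4] <- c(-4, -4, 0)
  xs <- -4 + (0:(dm[1] - 1)) * 2
  ramp <- array(0, dm)
  for (i in 1:dm[1]) ramp[i, , ] <- 0.03 * xs[i] + 0.2
  series <- image_series(list(ramp, ramp), aff, es_index = 0, ed_index = 1,
                         normalized = TRUE)
  # voxel center: exact stored value
  sv <- sample_image(series, 0, matrix(c(xs[5], -4 + 3 * 2, 8), 1))
  expect_equal(sv$value, ramp[5, 4, 3], tolerance = 1e-12)
  # ramp gradient recovered away from borders, smoothing disabled
  pts <- cbind(runif(20, -2, 14), runif(20, -2, 12), runif(20, 5, 15))
  sg <- sample_image(series, 0, pts, smooth_sd = 0)
  expect_lt(max(abs(sg$gradient[, 1] - 0.03)), 1e-6)
  expect_lt(max(abs(sg$gradient[, 2:3])), 1e-6)
  # far-outside points return intensity 0 and zero gradient
  far <- sample_image(series, 0, matrix(c(500, 500, 500), 1))
  expect_identical(far$value, 0)
  expect_identical(as.numeric(far$gradient), c(0, 0, 0))
})

test_that("Neo-Hookean density follows the closed form", {
  expect_equal(neo_hookean_energy_density(diag(3)), 0)
  F <- diag(c(2, 1 / sqrt(2), 1 / sqrt(2)))
  expect_equal(neo_hookean_energy_density(t(F) %*% F, C1 = 1), 2,
               tolerance = 1e-12)
  th <- 0.7
  Q <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_equal(neo_hookean_energy_density(t(Q) %*% Q), 0, tolerance = 1e-12)
  expect_error(neo_hookean_energy_density(diag(c(1, 1, -1))), "positive-definite")
})

test_that("similarity penalty is gamma/2 (r-t)^2 and symmetric", {
  expect_equal(similarity_penalty(1, 1, 0.005), 0)
  expect_equal(similarity_penalty(1, 0, 0.005), 0.0025)
  r <- runif(10); t <- runif(10)
  expect_equal(similarity_penalty(r, t, 0.3), similarity_penalty(t, r, 0.3))
})

test_that("basal displacement is zero at ES and MAPSE at ED", {
  series <- ws_fix("series_small")
  cfg <- warp_config(mapse = 9)
  expect_equal(basal_displacement(series$es_index, cfg, series), 0)
  expect_equal(abs(basal_displacement(series$ed_index, cfg, series)), 9)
  cfg0 <- warp_config(mapse = 0)
  for (f in 0:9) expect_equal(basal_displacement(f, cfg0, series), 0)
})

test_that("warping energy vanishes for matched images at zero displacement", {
  mesh <- ws_fix("mesh_small")
  series <- ws_fix("series_small")
  cfg <- warp_config()
  u0 <- matrix(0, nrow(mesh$nodes), 3)
  en <- warping_energy(mesh, u0, series, series$es_index, cfg)
  expect_equal(en$energy, 0, tolerance = 1e-12)
  # differing target: only the mismatch term contributes
  en2 <- warping_energy(mesh, u0, series, 0, cfg)
  expect_equal(en2$elastic, 0, tolerance = 1e-12)
  expect_gt(en2$mismatch, 0)
  expect_equal(en2$energy, en2$mismatch, tolerance = 1e-12)
})

test_that("analytic energy gradient matches finite differences", {
  mesh <- ws_fix("mesh_small")
  series <- ws_fix("series_small")
  cfg <- warp_config()
  set.seed(21)
  h <- 1e-5
  for (rep in 1:4) {
    st <- draw_smooth_state(mesh, series, h)
    en <- warping_energy(mesh, st$u, series, 2, cfg)
    fd <- (warping_energy(mesh, st$u + h * st$d, series, 2, cfg,
                          want_grad = FALSE)$energy -
           warping_energy(mesh, st$u - h * st$d, series, 2, cfg,
                          want_grad = FALSE)$energy) / (2 * h)
    expect_lt(abs(fd - sum(en$gradient * st$d)) / max(abs(fd), 1e-8), 1e-5)
  }
})

test_that("registration of matched images with zero BC stays at rest", {
  mesh <- ws_fix("mesh_small")
  series <- ws_fix("series_small")
  r <- register_frame(mesh, series, series$es_index, warp_config(), bc = 0)
  expect_lt(max(abs(r$u)), 1e-6)
})

test_that("a known in-plane shift is recovered", {
  mesh <- ws_fix("mesh_small")
  series <- ws_fix("series_small")
  # target = template translated by 2 voxels (4 mm) along +x
  es_arr <- series$frames[[series$es_index + 1]]
  dm <- dim(es_arr)
  arr2 <- array(0, dm)
  arr2[3:dm[1], , ] <- es_arr[1:(dm[1] - 2), , ]
  shifted <- series
  shifted$frames[[1]] <- arr2
  r <- register_frame(mesh, shifted, 0, warp_config(maxit = 400L), bc = 0)
  expect_lt(abs(mean(r$u[, 1]) - 4) / 4, 0.1)
  expect_lt(mean(abs(r$u[, 2])), 0.5)
  # energies are non-increasing along the optimization
  expect_true(all(diff(r$energies) <= 1e-12))
})
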