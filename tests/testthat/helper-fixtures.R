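# Shared fixtures, built lazily and cached for the whole test run.  All
# fixtures are generated in code; nothing is read from disk.

ws_fix <- local({
  cache <- new.env(parent = emptyenv())
  function(name) {
    if (!is.null(cache[[name]])) return(cache[[name]])
    val <- switch(name,
      spec0 = phantom_spec(noise_sd = 0),
      mesh0 = make_phantom_mesh(ws_fix("spec0"), 3.5),
      dirs0 = build_directions(ws_fix("mesh0")),
      series0 = normalize_series(render_image_series(ws_fix("spec0"))),
      oracle0 = ground_truth_strains(ws_fix("spec0"), mesh = ws_fix("mesh0"),
                                     dirs = ws_fix("dirs0")),
      spec_small = phantom_spec(grid_dim = c(64, 64, 12),
                                grid_spacing = c(2, 2, 8),
                                n_frames = 10, es_frame = 5, noise_sd = 0),
      mesh_small = make_phantom_mesh(ws_fix("spec_small"), 4.5),
      dirs_small = build_directions(ws_fix("mesh_small")),
      series_small = normalize_series(render_image_series(ws_fix("spec_small"))),
      cylinder = make_structured_cylinder(),
      stop("unknown fixture: ", name))
    cache[[name]] <- val
    val
  }
})

# structured (non-staircase) cylinder-shell mesh: nodes on an (r, theta, z)
# grid, each index hexahedron split into six tetrahedra along a common
# diagonal; inner surface LV_ENDO, outer EPI, top BASE, bottom APEX
make_structured_cylinder <- function(r0 = 10, r1 = 15, H = 30,
                                     nr = 4, nth = 40, nz = 12) {
  id <- function(i, j, k) 1 + (i - 1) + nr * ((j - 1) %% nth + nth * (k - 1))
  rr <- seq(r0, r1, length.out = nr)
  th <- seq(0, 2 * pi, length.out = nth + 1)[1:nth]
  zz <- seq(0, H, length.out = nz)
  idx <- as.matrix(expand.grid(i = 1:nr, j = 1:nth, k = 1:nz))
  coords <- cbind(rr[idx[, 1]] * cos(th[idx[, 2]]),
                  rr[idx[, 1]] * sin(th[idx[, 2]]),
                  zz[idx[, 3]])
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  cells <- vector("list", 6 * (nr - 1) * nth * (nz - 1))
  ci <- 0
  for (i in 1:(nr - 1)) for (j in 1:nth) for (k in 1:(nz - 1)) {
    corner <- function(b) id(i + b[1], j + b[2], k + b[3])
    for (p in 1:6) {
      ax <- perms[p, ]
      b1 <- c(0, 0, 0); b1[ax[1]] <- 1
      b2 <- b1; b2[ax[2]] <- 1
      ci <- ci + 1
      cells[[ci]] <- c(corner(c(0, 0, 0)), corner(b1), corner(b2),
                       corner(c(1, 1, 1)))
    }
  }
  mesh <- biv_mesh(coords, do.call(rbind, cells), require_tags = FALSE)
  fg <- warpstrain:::ws_facet_geometry(mesh$nodes, mesh$facets)
  r <- sqrt(fg$centroid[, 1]^2 + fg$centroid[, 2]^2)
  mesh$facet_tags <- ifelse(fg$normal[, 3] > 0.9, "BASE",
                     ifelse(fg$normal[, 3] < -0.9, "APEX",
                     ifelse(r < (r0 + r1) / 2, "LV_ENDO", "EPI")))
  mesh
}

# lattice slab [0,10]x[0,10]x[0,20] with the z = 0 / z = 20 faces tagged
make_slab <- function(h = 2.5) {
  lattice_tet_mesh(function(p) rep(TRUE, nrow(p)),
                   rbind(c(0, 0, 0), c(10, 10, 20)), h,
                   classify = function(ce, no)
                     ifelse(no[, 3] < -0.9, "LV_ENDO",
                            ifelse(no[, 3] > 0.9, "EPI", "WALL")),
                   require_tags = FALSE)
}

# lattice spherical shell a < r < b with inner/outer surfaces tagged
make_shell <- function(h, a = 10, b = 20) {
  lattice_tet_mesh(function(p) {
    r <- sqrt(rowSums(p^2)); r > a & r < b
  }, rbind(rep(-b - 1, 3), rep(b + 1, 3)), h,
  classify = function(ce, no) {
    r <- sqrt(rowSums(ce^2))
    ifelse(r < (a + b) / 2, "LV_ENDO", "EPI")
  }, require_tags = FALSE)
}

# per-cell strain components of an m x 9 gradient field projected on a
# direction field (thin wrapper so tests do not repeat the algebra)
cell_strains <- function(Fm, dirs) warpstrain:::ws_projected_strains(Fm, dirs)

mat3_rows <- function(M) matrix(t(M), 1)

# Draw a random feasible displacement state and probe direction such that
# no quadrature point crosses a voxel face within the central-difference
# stencil: the trilinear image term is only piecewise smooth, so the
# analytic/finite-difference comparison is performed where the energy is
# differentiable (kink crossings are a measure-zero set).
draw_smooth_state <- function(mesh, series, h = 1e-5, sd_u = 0.12) {
  qpw <- warpstrain:::ws_qp4()
  w2v <- warpstrain:::ws_world2vox(series$affine)
  qp_vox <- function(u) {
    xd <- mesh$nodes + u
    out <- vector("list", 4)
    for (q in 1:4) {
      p <- qpw[q, 1] * xd[mesh$cells[, 1], ] + qpw[q, 2] * xd[mesh$cells[, 2], ] +
           qpw[q, 3] * xd[mesh$cells[, 3], ] + qpw[q, 4] * xd[mesh$cells[, 4], ]
      out[[q]] <- cbind(p, 1) %*% t(w2v)
    }
    do.call(rbind, out)
  }
  for (try in 1:100) {
    u <- matrix(rnorm(nrow(mesh$nodes) * 3, 0, sd_u), ncol = 3)
    d <- matrix(rnorm(length(u)), ncol = 3)
    d <- d / max(abs(d))
    v0 <- qp_vox(u)
    vp <- qp_vox(u + h * d)
    vm <- qp_vox(u - h * d)
    if (all(floor(v0) == floor(vp)) && all(floor(v0) == floor(vm)))
      return(list(u = u, d = d))
  }
  stop("could not find a kink-free probe state")
}
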