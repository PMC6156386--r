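test_that("mesh constructor validates and re-orients", {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  # inverted ordering: negative signed volume, should be auto-flipped
  m <- biv_mesh(nodes, rbind(c(1L, 3L, 2L, 4L)), require_tags = FALSE)
  expect_gt(warpstrain:::ws_cell_volumes(m$nodes, m$cells), 0)
  expect_error(biv_mesh(nodes[1:3, ], rbind(c(1L, 2L, 3L, 3L))), "4 nodes")
})

test_that("halving the lattice size increases the cell count", {
  inside <- function(p) {
    r <- sqrt(rowSums(p^2)); r < 12
  }
  bb <- rbind(rep(-13, 3), rep(13, 3))
  m1 <- lattice_tet_mesh(inside, bb, 4, require_tags = FALSE)
  m2 <- lattice_tet_mesh(inside, bb, 2, require_tags = FALSE)
  expect_gt(nrow(m2$cells), nrow(m1$cells))
})

test_that("phantom mesh at the 4 mm size matches the clinical model scale", {
  mesh <- make_phantom_mesh(ws_fix("spec0"), 4.0)
  expect_gte(nrow(mesh$nodes), 2286)
  expect_lte(nrow(mesh$nodes), 3288)
  expect_gte(nrow(mesh$cells), 7013)
  expect_lte(nrow(mesh$cells), 11985)
})

test_that("region partition is exhaustive, exclusive and contiguous", {
  mesh <- ws_fix("mesh0")
  counts <- table(factor(mesh$regions, c("LV_FREE", "SEPTUM", "RV_FREE")))
  expect_identical(sum(counts), nrow(mesh$cells))
  expect_true(all(counts > 0))
  # each region forms a single face-connected component
  adj <- warpstrain:::ws_cell_adjacency(mesh)
  for (r in names(counts)) {
    cand <- mesh$regions == r
    keep <- cand[adj[, 1]] & cand[adj[, 2]]
    a2 <- adj[keep, , drop = FALSE]
    idx <- which(cand)
    comp <- integer(nrow(mesh$cells))
    comp[idx[1]] <- 1L
    queue <- idx[1]
    nb <- split(c(a2[, 2], a2[, 1]), c(a2[, 1], a2[, 2]))
    while (length(queue) > 0) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (n2 in nb[[as.character(cur)]])
        if (comp[n2] == 0L) { comp[n2] <- 1L; queue <- c(queue, n2) }
    }
    expect_identical(sum(comp[idx]), length(idx))
  }
})

test_that("a cell touching only LV endocardium and epicardium is LV free wall", {
  mesh <- ws_fix("mesh0")
  lv_nodes <- unique(as.vector(mesh$facets[mesh$facet_tags == "LV_ENDO", ]))
  rv_nodes <- unique(as.vector(mesh$facets[mesh$facet_tags == "RV_ENDO", ]))
  epi_nodes <- unique(as.vector(mesh$facets[mesh$facet_tags == "EPI", ]))
  touches <- function(cells, set) rowSums(matrix(cells %in% set, ncol = 4)) > 0
  sel <- touches(mesh$cells, lv_nodes) & touches(mesh$cells, epi_nodes) &
         !touches(mesh$cells, rv_nodes)
  # restrict to the free wall side, far from the septal junction
  cc <- warpstrain:::ws_cell_centroids(mesh)
  sel <- sel & cc[, 1] < -5
  expect_gt(sum(sel), 0)
  expect_true(all(mesh$regions[sel] == "LV_FREE"))
})

test_that("partition is invariant under node renumbering and rigid motion", {
  mesh <- ws_fix("mesh0")
  # renumber nodes with a fixed permutation
  set.seed(4)
  perm <- sample(nrow(mesh$nodes))
  inv <- integer(length(perm))
  inv[perm] <- seq_along(perm)
  m2 <- biv_mesh(mesh$nodes[perm, ], matrix(inv[mesh$cells], ncol = 4),
                 facets = matrix(inv[mesh$facets], ncol = 3),
                 facet_tags = mesh$facet_tags, long_axis = mesh$long_axis)
  lab2 <- partition_regions(m2)
  # compare per-cell via matching centroids (cell order is preserved)
  expect_identical(lab2, partition_regions(mesh))
  # rigid transform
  th <- 0.4
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  m3 <- mesh
  m3$nodes <- t(R %*% t(mesh$nodes) + c(3, -2, 5))
  m3$long_axis <- as.numeric(R %*% mesh$long_axis)
  expect_identical(partition_regions(m3), partition_regions(mesh))
})

test_that("validate_mesh reports scale-consistent volumes and closure", {
  mesh <- ws_fix("mesh_small")
  rep1 <- validate_mesh(mesh)
  expect_identical(rep1$n_degenerate, 0L)
  expect_true(rep1$surface_closed)
  m2 <- mesh
  m2$nodes <- mesh$nodes * 2
  rep2 <- validate_mesh(m2)
  expect_equal(rep2$total_volume, 8 * rep1$total_volume, tolerance = 1e-12)
  expect_identical(sum(rep1$region_counts), rep1$n_cells)
})
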