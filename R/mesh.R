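#' Biventricular tetrahedral mesh
#'
#' Container for a linear (P1) tetrahedral mesh of the biventricular wall
#' with tagged boundary surfaces and optional wall-region labels.  Boundary
#' facets carry exactly one tag each; the canonical surface tags are
#' `LV_ENDO`, `RV_ENDO`, `EPI` and `BASE`.  Cells with negative signed
#' volume are re-oriented (two nodes swapped) on construction.
#'
#' @param nodes numeric n x 3 matrix of reference coordinates (mm).
#' @param cells integer m x 4 matrix of tetrahedra (1-based node indices).
#' @param facets integer f x 3 matrix of boundary triangles; derived from
#'   `cells` when `NULL`.
#' @param facet_tags character vector of length f labelling every boundary
#'   facet.
#' @param regions optional per-cell labels in `LV_FREE`, `SEPTUM`, `RV_FREE`.
#' @param long_axis unit vector pointing apex to base.
#' @param require_tags require all four canonical surface tags to be
#'   present (disable for single-chamber test geometries).
#' @return an object of class `biv_mesh`.
#' @export
biv_mesh <- function(nodes, cells, facets = NULL, facet_tags = NULL,
                     regions = NULL, long_axis = c(0, 0, 1),
                     require_tags = TRUE) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  cells <- as.matrix(cells)
  storage.mode(cells) <- "integer"
  if (ncol(nodes) != 3 || nrow(nodes) < 4)
    ws_stopf("mesh needs an n x 3 node matrix with at least 4 nodes")
  if (ncol(cells) != 4 || nrow(cells) < 1)
    ws_stopf("mesh needs an m x 4 cell matrix")
  if (min(cells) < 1 || max(cells) > nrow(nodes))
    ws_stopf("cell indices out of node range")

  # re-orient inverted tetrahedra so all signed volumes are positive
  v <- ws_cell_volumes(nodes, cells)
  flip <- which(v < 0)
  if (length(flip) > 0) {
    tmp <- cells[flip, 3]
    cells[flip, 3] <- cells[flip, 4]
    cells[flip, 4] <- tmp
    v[flip] <- -v[flip]
  }
  if (any(v <= 1e-12))
    ws_stopf("degenerate tetrahedra (zero volume): cells %s",
             paste(utils::head(which(v <= 1e-12), 5), collapse = ", "))

  if (is.null(facets)) {
    bf <- ws_boundary_facets(cells)
    facets <- bf$facets
  }
  facets <- as.matrix(facets)
  storage.mode(facets) <- "integer"
  if (is.null(facet_tags)) facet_tags <- rep(NA_character_, nrow(facets))
  facet_tags <- as.character(facet_tags)
  if (length(facet_tags) != nrow(facets))
    ws_stopf("facet_tags must label every boundary facet (%d facets, %d tags)",
             nrow(facets), length(facet_tags))
  if (require_tags) {
    if (anyNA(facet_tags))
      ws_stopf("%d boundary facets carry no tag", sum(is.na(facet_tags)))
    missing <- setdiff(WS_TAGS, unique(facet_tags))
    if (length(missing) > 0)
      ws_stopf("missing surface tag(s): %s", paste(missing, collapse = ", "))
  }
  if (!is.null(regions)) {
    regions <- as.character(regions)
    if (length(regions) != nrow(cells))
      ws_stopf("regions must label every cell")
    bad <- setdiff(unique(regions), WS_REGIONS)
    if (length(bad) > 0)
      ws_stopf("unknown region label(s): %s", paste(bad, collapse = ", "))
  }
  structure(list(nodes = nodes, cells = cells, facets = facets,
                 facet_tags = facet_tags, regions = regions,
                 long_axis = ws_unit(as.numeric(long_axis))),
            class = "biv_mesh")
}

#' @method print biv_mesh
#' @export
print.biv_mesh <- function(x, ...) {
  cat(sprintf("biv_mesh: %d nodes, %d cells, %d boundary facets\n",
              nrow(x$nodes), nrow(x$cells), nrow(x$facets)))
  tt <- table(x$facet_tags, useNA = "ifany")
  cat("  facet tags:", paste(sprintf("%s=%d", names(tt), tt), collapse = ", "), "\n")
  if (!is.null(x$regions)) {
    rt <- table(factor(x$regions, WS_REGIONS))
    cat("  regions:", paste(sprintf("%s=%d", names(rt), rt), collapse = ", "), "\n")
  }
  invisible(x)
}

ws_cell_volumes <- function(nodes, cells) {
  a <- nodes[cells[, 2], , drop = FALSE] - nodes[cells[, 1], , drop = FALSE]
  b <- nodes[cells[, 3], , drop = FALSE] - nodes[cells[, 1], , drop = FALSE]
  d <- nodes[cells[, 4], , drop = FALSE] - nodes[cells[, 1], , drop = FALSE]
  (a[, 1] * (b[, 2] * d[, 3] - b[, 3] * d[, 2]) -
   a[, 2] * (b[, 1] * d[, 3] - b[, 3] * d[, 1]) +
   a[, 3] * (b[, 1] * d[, 2] - b[, 2] * d[, 1])) / 6
}

# cached P1 geometry (shape-function gradients + volumes)
ws_tet_geom <- function(mesh) {
  if (!is.null(attr(mesh, "geom"))) return(attr(mesh, "geom"))
  .ws_tet_precompute(mesh$nodes, mesh$cells)
}

# boundary facets (faces appearing in exactly one cell) with owner cells
ws_boundary_facets <- function(cells) {
  m <- nrow(cells)
  faceidx <- rbind(c(2, 3, 4), c(1, 4, 3), c(1, 2, 4), c(1, 3, 2))
  faces <- matrix(0L, 4 * m, 3)
  owner <- rep(seq_len(m), each = 4)
  for (f in 1:4)
    faces[seq(f, by = 4, length.out = m), ] <- cells[, faceidx[f, ], drop = FALSE]
  skey <- cbind(pmin.int(faces[, 1], faces[, 2], faces[, 3]),
                faces[, 1] + faces[, 2] + faces[, 3] -
                  pmin.int(faces[, 1], faces[, 2], faces[, 3]) -
                  pmax.int(faces[, 1], faces[, 2], faces[, 3]),
                pmax.int(faces[, 1], faces[, 2], faces[, 3]))
  key <- paste(skey[, 1], skey[, 2], skey[, 3])
  cnt <- table(key)
  bnd <- cnt[key] == 1
  list(facets = faces[bnd, , drop = FALSE], owner = owner[bnd])
}

# outward normals and centroids of boundary facets
ws_facet_geometry <- function(nodes, facets) {
  p1 <- nodes[facets[, 1], , drop = FALSE]
  p2 <- nodes[facets[, 2], , drop = FALSE]
  p3 <- nodes[facets[, 3], , drop = FALSE]
  nrm <- ws_cross_rows(p2 - p1, p3 - p1)
  area <- sqrt(rowSums(nrm^2)) / 2
  list(centroid = (p1 + p2 + p3) / 3, normal = nrm / (2 * area), area = area)
}

ws_cell_centroids <- function(mesh) {
  (mesh$nodes[mesh$cells[, 1], , drop = FALSE] +
   mesh$nodes[mesh$cells[, 2], , drop = FALSE] +
   mesh$nodes[mesh$cells[, 3], , drop = FALSE] +
   mesh$nodes[mesh$cells[, 4], , drop = FALSE]) / 4
}

#' Conforming lattice tetrahedral mesh of an implicit solid
#'
#' Meshes the region where `inside()` is `TRUE` by keeping the cubes of a
#' regular lattice whose centers fall inside and splitting each cube into
#' six tetrahedra along a common diagonal (Kuhn subdivision), which yields a
#' watertight, conforming mesh.  Boundary facets are tagged by the supplied
#' classifier.
#'
#' @param inside vectorized predicate: n x 3 matrix of points -> logical.
#' @param bbox 2 x 3 matrix, rows = lower and upper corner (mm).
#' @param h lattice spacing = characteristic cell size (mm).
#' @param classify function(centroids, normals) -> character tags for
#'   boundary facets (may be `NULL` to leave facets untagged).
#' @param long_axis apex-to-base unit vector for the resulting mesh.
#' @param require_tags passed through to [biv_mesh()].
#' @return a [biv_mesh()].
#' @export
lattice_tet_mesh <- function(inside, bbox, h, classify = NULL,
                             long_axis = c(0, 0, 1), require_tags = FALSE) {
  if (h <= 0) ws_stopf("mesh size h must be positive")
  lo <- bbox[1, ]
  n <- pmax(ceiling((bbox[2, ] - lo) / h), 1L)
  cx <- lo[1] + (seq_len(n[1]) - 0.5) * h
  cy <- lo[2] + (seq_len(n[2]) - 0.5) * h
  cz <- lo[3] + (seq_len(n[3]) - 0.5) * h
  centers <- as.matrix(expand.grid(x = cx, y = cy, z = cz))
  keep <- which(inside(centers))
  if (length(keep) == 0)
    ws_stopf("no lattice cube center falls inside the solid; check geometry or mesh size h = %g", h)
  # integer cube coordinates of kept cubes
  kx <- (keep - 1) %% n[1]
  ky <- ((keep - 1) %/% n[1]) %% n[2]
  kz <- (keep - 1) %/% (n[1] * n[2])
  # corner nodes on the (n+1)^3 lattice
  nx1 <- n[1] + 1L; ny1 <- n[2] + 1L
  corner_key <- function(i, j, k) 1 + i + nx1 * (j + ny1 * k)
  offs <- as.matrix(expand.grid(dx = 0:1, dy = 0:1, dz = 0:1))
  ck <- matrix(0L, length(keep), 8)
  for (c8 in 1:8)
    ck[, c8] <- corner_key(kx + offs[c8, 1], ky + offs[c8, 2], kz + offs[c8, 3])
  used <- sort(unique(as.vector(ck)))
  id_of <- integer(max(used))
  id_of[used] <- seq_along(used)
  uk <- used - 1
  nodes <- cbind(lo[1] + (uk %% nx1) * h,
                 lo[2] + ((uk %/% nx1) %% ny1) * h,
                 lo[3] + (uk %/% (nx1 * ny1)) * h)
  # Kuhn subdivision: six tets sharing the 0-7 diagonal; corner c8 index is
  # 1 + dx + 2 dy + 4 dz
  perms <- rbind(c(1, 2, 4), c(1, 4, 2), c(2, 1, 4),
                 c(2, 4, 1), c(4, 1, 2), c(4, 2, 1))
  tets <- vector("list", 6)
  for (p in 1:6) {
    v0 <- 1L
    v1 <- 1L + perms[p, 1]
    v2 <- 1L + perms[p, 1] + perms[p, 2]
    v3 <- 8L
    tets[[p]] <- cbind(id_of[ck[, v0]], id_of[ck[, v1]],
                       id_of[ck[, v2]], id_of[ck[, v3]])
  }
  cells <- do.call(rbind, tets)
  # orient all tets positively BEFORE facet extraction so the boundary
  # triangles (and hence the classifier's outward normals) are consistent
  v <- ws_cell_volumes(nodes, cells)
  flip <- which(v < 0)
  if (length(flip) > 0) {
    tmp <- cells[flip, 3]
    cells[flip, 3] <- cells[flip, 4]
    cells[flip, 4] <- tmp
  }
  bf <- ws_boundary_facets(cells)
  tags <- NULL
  if (!is.null(classify)) {
    fg <- ws_facet_geometry(nodes, bf$facets)
    tags <- classify(fg$centroid, fg$normal)
  }
  biv_mesh(nodes, cells, facets = bf$facets, facet_tags = tags,
           long_axis = long_axis, require_tags = require_tags)
}

#' Mesh quality and consistency report
#'
#' @param mesh a [biv_mesh()].
#' @return a list with node/cell counts, min/max/total cell volume, the
#'   worst edge-length aspect ratio, per-region cell counts, the number of
#'   degenerate cells, and whether the boundary surface is closed (every
#'   boundary edge shared by exactly two boundary facets).
#' @export
validate_mesh <- function(mesh) {
  v <- ws_cell_volumes(mesh$nodes, mesh$cells)
  edges <- rbind(mesh$cells[, c(1, 2)], mesh$cells[, c(1, 3)],
                 mesh$cells[, c(1, 4)], mesh$cells[, c(2, 3)],
                 mesh$cells[, c(2, 4)], mesh$cells[, c(3, 4)])
  el <- sqrt(rowSums((mesh$nodes[edges[, 1], ] - mesh$nodes[edges[, 2], ])^2))
  elm <- matrix(el, nrow = nrow(mesh$cells))
  # regular tetrahedron attains edge^3 / (6 sqrt(2) V) = 1
  aspect <- apply(elm, 1, max)^3 / (6 * sqrt(2) * v)
  fe <- rbind(mesh$facets[, c(1, 2)], mesh$facets[, c(2, 3)], mesh$facets[, c(1, 3)])
  fkey <- paste(pmin.int(fe[, 1], fe[, 2]), pmax.int(fe[, 1], fe[, 2]))
  # every boundary edge on an even number of boundary facets (counts of 4
  # occur at the non-manifold pinch edges a lattice mesh can contain)
  closed <- all(table(fkey) %% 2 == 0)
  region_counts <- if (is.null(mesh$regions)) NULL else
    table(factor(mesh$regions, WS_REGIONS))
  list(n_nodes = nrow(mesh$nodes), n_cells = nrow(mesh$cells),
       n_facets = nrow(mesh$facets),
       min_volume = min(v), max_volume = max(v), total_volume = sum(v),
       max_aspect = max(aspect), n_degenerate = sum(v <= 1e-12),
       region_counts = region_counts, surface_closed = closed)
}

#' Partition the wall into LV free wall, septum and RV free wall
#'
#' Two harmonic "pool proximity" fields are solved on the mesh: `d_LV` with
#' the LV endocardium at 0 and the epicardium at 1 (RV endocardium and base
#' left as natural boundaries) and `d_RV` symmetrically.  A cell whose
#' centroid sees both fields below `threshold` lies between the two blood
#' pools and is labelled `SEPTUM`; otherwise the smaller of the two fields
#' decides between `LV_FREE` and `RV_FREE`, exact ties going to `SEPTUM`.
#'
#' @param mesh a [biv_mesh()] with tagged facets.
#' @param threshold septum detection threshold on the harmonic fields.
#' @return character vector of per-cell region labels.
#' @export
partition_regions <- function(mesh, threshold = 0.5) {
  for (tag in c("LV_ENDO", "RV_ENDO", "EPI"))
    if (!tag %in% mesh$facet_tags)
      ws_stopf("partition requires facet tag %s", tag)
  d_lv <- solve_laplace_coordinate(mesh, c(LV_ENDO = 0, EPI = 1))
  d_rv <- solve_laplace_coordinate(mesh, c(RV_ENDO = 0, EPI = 1))
  cl <- rowMeans(matrix(d_lv[mesh$cells], ncol = 4))
  cr <- rowMeans(matrix(d_rv[mesh$cells], ncol = 4))
  septum <- (cl < threshold & cr < threshold) | cl == cr
  # the septum must bridge the two blood pools: keep only septum-candidate
  # components that touch both endocardial surfaces (a thick apex can also
  # read "far from the epicardium" on both fields without lying between
  # the pools)
  touch <- function(tag) {
    nodes <- unique(as.vector(mesh$facets[mesh$facet_tags == tag, , drop = FALSE]))
    rowSums(matrix(mesh$cells %in% nodes, ncol = 4)) > 0
  }
  septum <- ws_filter_components(mesh, septum,
                                 touch("LV_ENDO"), touch("RV_ENDO"))
  lab <- ifelse(septum, "SEPTUM", ifelse(cl <= cr, "LV_FREE", "RV_FREE"))
  lab <- ws_relabel_satellites(mesh, lab)
  counts <- table(factor(lab, WS_REGIONS))
  if (any(counts == 0))
    ws_stopf("region(s) with zero cells: %s",
             paste(names(counts)[counts == 0], collapse = ", "))
  lab
}

# each region should be one face-connected patch: cells in satellite
# components (staircase slivers at junctions) are relabelled by the
# majority label of their face neighbors until stable
ws_relabel_satellites <- function(mesh, lab, max_pass = 20) {
  adj <- ws_cell_adjacency(mesh)
  for (pass in seq_len(max_pass)) {
    changed <- FALSE
    for (r in WS_REGIONS) {
      cand <- lab == r
      if (!any(cand)) next
      keep <- cand[adj[, 1]] & cand[adj[, 2]]
      a2 <- adj[keep, , drop = FALSE]
      idx <- which(cand)
      comp <- integer(length(lab))
      cid <- 0L
      nb <- split(c(a2[, 2], a2[, 1]), c(a2[, 1], a2[, 2]))
      for (seed in idx) {
        if (comp[seed] != 0L) next
        cid <- cid + 1L
        queue <- seed
        comp[seed] <- cid
        while (length(queue) > 0) {
          cur <- queue[[1]]
          queue <- queue[-1]
          for (n2 in nb[[as.character(cur)]]) {
            if (comp[n2] == 0L) {
              comp[n2] <- cid
              queue <- c(queue, n2)
            }
          }
        }
      }
      if (cid <= 1L) next
      sizes <- tabulate(comp[idx], cid)
      main <- which.max(sizes)
      sat <- idx[comp[idx] != main]
      for (i in sat) {
        nbl <- lab[c(adj[adj[, 1] == i, 2], adj[adj[, 2] == i, 1])]
        nbl <- nbl[nbl != r]
        if (length(nbl) > 0) {
          lab[i] <- names(sort(table(nbl), decreasing = TRUE))[1]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  lab
}

# keep only the connected components of `candidate` cells (face adjacency)
# that contain at least one cell flagged in both `mustA` and `mustB`
ws_filter_components <- function(mesh, candidate, mustA, mustB) {
  idx <- which(candidate)
  if (length(idx) == 0) return(candidate)
  adj <- ws_cell_adjacency(mesh)
  keep_edge <- candidate[adj[, 1]] & candidate[adj[, 2]]
  adj <- adj[keep_edge, , drop = FALSE]
  comp <- integer(nrow(mesh$cells))
  cid <- 0L
  nb <- split(c(adj[, 2], adj[, 1]), c(adj[, 1], adj[, 2]))
  for (seed in idx) {
    if (comp[seed] != 0L) next
    cid <- cid + 1L
    queue <- seed
    comp[seed] <- cid
    while (length(queue) > 0) {
      cur <- queue[[1]]
      queue <- queue[-1]
      for (n2 in nb[[as.character(cur)]]) {
        if (comp[n2] == 0L) {
          comp[n2] <- cid
          queue <- c(queue, n2)
        }
      }
    }
  }
  good <- logical(cid)
  for (k in seq_len(cid)) {
    cells_k <- comp == k
    good[k] <- any(mustA[cells_k]) && any(mustB[cells_k])
  }
  out <- candidate
  out[idx] <- good[comp[idx]]
  out
}
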