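#' Per-element circumferential / longitudinal / radial triads
#'
#' Laplace-Dirichlet rule-based construction of the local wall coordinate
#' frame with the myofiber angle fixed at zero.  A transmural harmonic
#' field (both endocardial surfaces at 0, epicardium at 1) supplies the
#' outward radial direction; an apicobasal field (base at 1, an apex node
#' patch at 0) supplies the longitudinal direction after orthogonalization
#' against the radial one; the circumferential direction completes the
#' right-handed triad as `e_C = e_L x e_R`.
#'
#' Because a single transmural field is shared by both ventricles, the
#' septal radial direction points from the LV pool toward the RV pool,
#' keeping the triad continuous across the wall.
#'
#' @param mesh a [biv_mesh()] with tagged facets.
#' @param apex_frac fraction of the apicobasal extent whose lowest nodes
#'   form the apex Dirichlet patch (no apex surface tag exists).
#' @return an object of class `direction_field`: list of m x 3 matrices
#'   `e_C`, `e_L`, `e_R` (unit rows).
#' @export
build_directions <- function(mesh, apex_frac = 0.02) {
  endo_tags <- intersect(c("LV_ENDO", "RV_ENDO"), unique(mesh$facet_tags))
  if (length(endo_tags) == 0 || !"EPI" %in% mesh$facet_tags)
    ws_stopf("direction construction requires endocardial and EPI facet tags")
  trans_bc <- stats::setNames(c(rep(0, length(endo_tags)), 1),
                              c(endo_tags, "EPI"))
  phi_t <- solve_laplace_coordinate(mesh, trans_bc)
  # transventricular field for the septal transmural direction: with both
  # endocardia held at 0 the epicardial-depth field is flat across the
  # septum (its gradient turns lateral), so the LV->RV harmonic field
  # supplies the septal wall normal and the two gradients are blended by
  # squared magnitude (the dominant field is the locally meaningful one)
  psi <- if (length(endo_tags) == 2)
    solve_laplace_coordinate(mesh, c(LV_ENDO = 0, RV_ENDO = 1))
  else NULL

  proj <- as.numeric(mesh$nodes %*% mesh$long_axis)
  apex_cut <- min(proj) + apex_frac * (max(proj) - min(proj))
  apex_idx <- which(proj <= apex_cut)
  phi_l <- solve_laplace_coordinate(mesh, c(BASE = 1),
                                    node_values = list(index = apex_idx,
                                                       value = 0))
  geom <- ws_tet_geom(mesh)
  # volume-weighted cell -> node -> cell gradient recovery: the elementwise
  # P1 gradient is noisy on staircase boundaries; patch averaging restores
  # the smooth field direction (standard gradient recovery)
  recover <- function(g) {
    idx <- as.vector(mesh$cells)
    gv <- g[rep(seq_len(nrow(g)), 4), , drop = FALSE] * geom$vol
    acc <- rowsum(gv, idx, reorder = TRUE)
    wgt <- rowsum(rep(geom$vol, 4), idx, reorder = TRUE)[, 1]
    nodal <- acc / wgt
    (nodal[mesh$cells[, 1], ] + nodal[mesh$cells[, 2], ] +
     nodal[mesh$cells[, 3], ] + nodal[mesh$cells[, 4], ]) / 4
  }
  g_t <- recover(ws_cell_gradient(mesh, phi_t, geom))
  if (!is.null(psi)) {
    g_psi <- recover(ws_cell_gradient(mesh, psi, geom))
    m <- rowSums(g_psi^2) / (rowSums(g_psi^2) + rowSums(g_t^2) + 1e-300)
    g_t <- (1 - m) * g_t + m * g_psi
  }
  g_l <- recover(ws_cell_gradient(mesh, phi_l, geom))
  # cells whose four nodes all sit on one Dirichlet surface carry a zero
  # field gradient (a lattice-mesh corner artifact): fill from face
  # neighbors before normalizing
  adj <- ws_cell_adjacency(mesh)
  g_t <- ws_fill_degenerate(g_t, adj, "transmural gradient")
  e_R <- ws_unit_rows(g_t, "transmural gradient")
  g_l_perp <- g_l - rowSums(g_l * e_R) * e_R
  g_l_perp <- ws_fill_degenerate(g_l_perp, adj,
                                 "apicobasal gradient (parallel to radial)")
  # re-orthogonalize the filled rows against the local radial direction
  g_l_perp <- g_l_perp - rowSums(g_l_perp * e_R) * e_R
  e_L <- ws_unit_rows(g_l_perp, "apicobasal gradient (parallel to radial)")
  e_C <- ws_cross_rows(e_L, e_R)
  structure(list(e_C = e_C, e_L = e_L, e_R = e_R),
            class = "direction_field")
}

# face-adjacency list of a tetrahedral mesh
ws_cell_adjacency <- function(mesh) {
  cells <- mesh$cells
  m <- nrow(cells)
  faceidx <- rbind(c(2, 3, 4), c(1, 4, 3), c(1, 2, 4), c(1, 3, 2))
  faces <- matrix(0L, 4 * m, 3)
  owner <- rep(seq_len(m), each = 4)
  for (f in 1:4)
    faces[seq(f, by = 4, length.out = m), ] <- cells[, faceidx[f, ], drop = FALSE]
  key <- paste(pmin.int(faces[, 1], faces[, 2], faces[, 3]),
               faces[, 1] + faces[, 2] + faces[, 3] -
                 pmin.int(faces[, 1], faces[, 2], faces[, 3]) -
                 pmax.int(faces[, 1], faces[, 2], faces[, 3]),
               pmax.int(faces[, 1], faces[, 2], faces[, 3]))
  ord <- order(key)
  k <- key[ord]; ow <- owner[ord]
  shared <- which(k[-1] == k[-length(k)])
  cbind(ow[shared], ow[shared + 1])
}

# replace near-zero rows by the mean of face-neighbor rows (iteratively);
# error naming the cells if a zero-gradient patch cannot be resolved
ws_fill_degenerate <- function(g, adj, what, tol = 1e-10) {
  bad <- sqrt(rowSums(g^2)) < tol
  for (pass in 1:100) {
    if (!any(bad)) return(g)
    idx <- which(bad)
    fixed_any <- FALSE
    nb_from <- c(adj[, 1], adj[, 2])
    nb_to <- c(adj[, 2], adj[, 1])
    ok <- !bad[nb_from]
    for (i in idx) {
      sel <- nb_to == i & ok
      if (any(sel)) {
        g[i, ] <- colMeans(g[nb_from[sel], , drop = FALSE])
        fixed_any <- TRUE
      }
    }
    bad <- sqrt(rowSums(g^2)) < tol
    if (!fixed_any) break
  }
  if (any(bad))
    ws_stopf("degenerate %s in cell(s) %s", what,
             paste(utils::head(which(bad), 5), collapse = ", "))
  g
}

#' @method print direction_field
#' @export
print.direction_field <- function(x, ...) {
  cat(sprintf("direction_field: %d cells (e_C, e_L, e_R)\n", nrow(x$e_C)))
  invisible(x)
}
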