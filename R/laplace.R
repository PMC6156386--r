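#' Harmonic coordinate field on a tetrahedral mesh
#'
#' Solves Laplace's equation with piecewise-linear (P1) finite elements.
#' Dirichlet values are prescribed on the nodes of tagged boundary surfaces;
#' all other boundaries receive the natural zero-flux condition.  This is
#' the building block of the Laplace-Dirichlet rule-based direction
#' construction and of the wall partition.
#'
#' @param mesh a [biv_mesh()].
#' @param dirichlet_tags named numeric vector, names are facet tags, values
#'   the Dirichlet data (e.g. `c(LV_ENDO = 0, EPI = 1)`).
#' @param node_values optional extra point-wise Dirichlet data as
#'   `list(index =, value =)` with 1-based node indices; applied after (and
#'   overriding) the tag-based data, which is how the apex "patch" of the
#'   apicobasal field is pinned.
#' @return numeric vector of nodal field values.
#' @export
solve_laplace_coordinate <- function(mesh, dirichlet_tags, node_values = NULL) {
  n <- nrow(mesh$nodes)
  geom <- ws_tet_geom(mesh)
  fixed <- rep(NA_real_, n)
  for (tag in names(dirichlet_tags)) {
    sel <- which(mesh$facet_tags == tag)
    if (length(sel) == 0)
      ws_stopf("Dirichlet tag %s not present on the mesh", tag)
    fixed[unique(as.vector(mesh$facets[sel, ]))] <- dirichlet_tags[[tag]]
  }
  if (!is.null(node_values))
    fixed[node_values$index] <- node_values$value
  fidx <- which(!is.na(fixed))
  if (length(fidx) == 0)
    ws_stopf("no Dirichlet data: the Laplace system is singular")
  if (length(fidx) == n) return(fixed)

  K <- ws_stiffness(mesh, geom)
  free <- which(is.na(fixed))
  rhs <- -K[free, fidx, drop = FALSE] %*% fixed[fidx]
  sol <- Matrix::solve(K[free, free], rhs)
  out <- fixed
  out[free] <- as.numeric(sol)
  out
}

# P1 stiffness matrix, assembled from per-cell shape-function gradients
ws_stiffness <- function(mesh, geom = ws_tet_geom(mesh)) {
  m <- nrow(mesh$cells)
  ii <- jj <- xx <- vector("list", 16)
  k <- 1
  for (a in 1:4) for (b in 1:4) {
    ga <- geom$dndx[, (a - 1) * 3 + (1:3), drop = FALSE]
    gb <- geom$dndx[, (b - 1) * 3 + (1:3), drop = FALSE]
    ii[[k]] <- mesh$cells[, a]
    jj[[k]] <- mesh$cells[, b]
    xx[[k]] <- geom$vol * rowSums(ga * gb)
    k <- k + 1
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(nrow(mesh$nodes), nrow(mesh$nodes)))
}

# per-cell (constant) gradient of a nodal scalar field
ws_cell_gradient <- function(mesh, field, geom = ws_tet_geom(mesh)) {
  g <- matrix(0, nrow(mesh$cells), 3)
  for (a in 1:4)
    g <- g + field[mesh$cells[, a]] * geom$dndx[, (a - 1) * 3 + (1:3), drop = FALSE]
  g
}
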