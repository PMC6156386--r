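#' Remap a deformation gradient to the end-diastolic reference
#'
#' Tracking references the end-systolic configuration, but strain is
#' conventionally reported against end-diastole.  Given the gradient `F` at
#' some frame and the gradient `F_ED` at the end-diastolic frame (both with
#' respect to ES), the relative gradient is `F_rel = F F_ED^-1` and the
#' Green-Lagrange strain with ED as reference is
#' `E = 1/2 (F_rel^T F_rel - I)`, which vanishes identically at ED and for
#' any rigid motion.
#'
#' @param F 3 x 3 deformation gradient at the frame of interest.
#' @param F_ED 3 x 3 deformation gradient at end-diastole.
#' @return 3 x 3 Green-Lagrange strain tensor `E`.
#' @export
remap_reference <- function(F, F_ED) {
  F <- as.matrix(F); F_ED <- as.matrix(F_ED)
  if (det(F) <= 0) ws_stopf("F must have positive determinant")
  dE <- det(F_ED)
  if (abs(dE) < 1e-12) ws_stopf("singular F_ED cannot serve as reference")
  if (dE <= 0) ws_stopf("F_ED must have positive determinant")
  Frel <- F %*% solve(F_ED)
  (crossprod(Frel) - diag(3)) / 2
}

#' Project a strain tensor onto a wall triad
#'
#' Normal strain components along the circumferential, longitudinal and
#' radial directions: `eps_ii = e_i . E e_i`.
#'
#' @param E 3 x 3 Green-Lagrange strain tensor.
#' @param triad list with unit vectors `e_C`, `e_L`, `e_R` (orthonormal).
#' @return named vector `c(CC =, LL =, RR =)`.
#' @export
project_strain <- function(E, triad) {
  E <- as.matrix(E)
  G <- cbind(triad$e_C, triad$e_L, triad$e_R)
  if (max(abs(crossprod(G) - diag(3))) > 1e-6)
    ws_stopf("triad must be orthonormal")
  c(CC = as.numeric(triad$e_C %*% E %*% triad$e_C),
    LL = as.numeric(triad$e_L %*% E %*% triad$e_L),
    RR = as.numeric(triad$e_R %*% E %*% triad$e_R))
}

# vectorized Green-Lagrange components of an m x 9 gradient field,
# projected on a direction_field: returns m x 3 (CC, LL, RR)
ws_projected_strains <- function(Fm, dirs) {
  # C = F^T F, symmetric: six components
  C11 <- Fm[, 1]^2 + Fm[, 4]^2 + Fm[, 7]^2
  C22 <- Fm[, 2]^2 + Fm[, 5]^2 + Fm[, 8]^2
  C33 <- Fm[, 3]^2 + Fm[, 6]^2 + Fm[, 9]^2
  C12 <- Fm[, 1] * Fm[, 2] + Fm[, 4] * Fm[, 5] + Fm[, 7] * Fm[, 8]
  C13 <- Fm[, 1] * Fm[, 3] + Fm[, 4] * Fm[, 6] + Fm[, 7] * Fm[, 9]
  C23 <- Fm[, 2] * Fm[, 3] + Fm[, 5] * Fm[, 6] + Fm[, 8] * Fm[, 9]
  E11 <- (C11 - 1) / 2; E22 <- (C22 - 1) / 2; E33 <- (C33 - 1) / 2
  E12 <- C12 / 2; E13 <- C13 / 2; E23 <- C23 / 2
  quad <- function(e)
    e[, 1]^2 * E11 + e[, 2]^2 * E22 + e[, 3]^2 * E33 +
    2 * (e[, 1] * e[, 2] * E12 + e[, 1] * e[, 3] * E13 +
         e[, 2] * e[, 3] * E23)
  cbind(CC = quad(dirs$e_C), LL = quad(dirs$e_L), RR = quad(dirs$e_R))
}

#' Region average of a per-cell quantity
#'
#' Unweighted mean over the cells of each wall region (the curves are
#' averages "over all the elements"); volume weighting is available behind
#' the `weighted` flag.
#'
#' @param values per-cell numeric vector.
#' @param mesh a [biv_mesh()] with regions assigned.
#' @param weighted use cell-volume weights instead of the plain mean.
#' @return named vector of region means (`LV_FREE`, `SEPTUM`, `RV_FREE`).
#' @export
region_average <- function(values, mesh, weighted = FALSE) {
  if (is.null(mesh$regions)) ws_stopf("mesh has no region labels")
  if (length(values) != nrow(mesh$cells))
    ws_stopf("values must be per-cell (%d cells)", nrow(mesh$cells))
  w <- if (weighted) ws_cell_volumes(mesh$nodes, mesh$cells) else
    rep(1, nrow(mesh$cells))
  out <- vapply(WS_REGIONS, function(r) {
    sel <- mesh$regions == r
    if (!any(sel)) ws_stopf("region %s has no cells", r)
    sum(values[sel] * w[sel]) / sum(w[sel])
  }, numeric(1))
  out
}

#' Region strain-time curves from per-frame deformation gradients
#'
#' Shared post-processing path of both the tracked solution and the
#' phantom oracle: remap every per-cell gradient to the end-diastolic
#' reference, project the Green-Lagrange tensor on the local triads, and
#' average per region.  Strain at the ED frame is zero by construction.
#'
#' @param F_frames list (length n_frames) of m x 9 per-cell deformation
#'   gradients relative to the tracking (ES) configuration, in temporal
#'   order, or a `motion_solution`.
#' @param mesh a [biv_mesh()] with regions.
#' @param dirs a [build_directions()] field.
#' @param frame_times frame times (s); taken from a `motion_solution`
#'   automatically.
#' @param ed_index,es_index end-diastolic / end-systolic frames (0-based).
#' @param weighted volume-weighted region averages.
#' @return an object of class `strain_curves`: a `strains` array
#'   (region x component x frame, dimensionless), `peaks` data frame (in
#'   percent), frame times and bookkeeping.
#' @export
compute_strain_curves <- function(F_frames, mesh, dirs, frame_times = NULL,
                                  ed_index = 0L, es_index = NULL,
                                  weighted = FALSE) {
  if (inherits(F_frames, "motion_solution")) {
    sol <- F_frames
    frame_times <- frame_times %||% sol$frame_times
    ed_index <- sol$ed_index
    es_index <- sol$es_index
    F_frames <- sol$F
  }
  n <- length(F_frames)
  if (is.null(es_index)) ws_stopf("es_index is required")
  if (is.null(frame_times)) frame_times <- (0:(n - 1)) / n
  Fed_inv <- ws_mat3_inv(F_frames[[ed_index + 1]])
  comps <- c("CC", "LL", "RR")
  strains <- array(0, dim = c(3, 3, n),
                   dimnames = list(region = WS_REGIONS, component = comps,
                                   frame = NULL))
  for (f in seq_len(n)) {
    Frel <- ws_mat3_mul(F_frames[[f]], Fed_inv)
    sc <- ws_projected_strains(Frel, dirs)
    for (k in 1:3)
      strains[, k, f] <- region_average(sc[, k], mesh, weighted)
  }
  curves <- structure(list(strains = strains, frame_times = frame_times,
                           ed_index = as.integer(ed_index),
                           es_index = as.integer(es_index),
                           n_cells = table(factor(mesh$regions, WS_REGIONS))),
                      class = "strain_curves")
  curves$peaks <- peak_systolic(curves)
  curves
}

#' Peak systolic strains
#'
#' For the shortening components (circumferential, longitudinal) the most
#' negative value over the ED-to-ES arc; for the radial component the
#' maximum.  Reported in percent with the sign retained.  A whole-cycle
#' window is available (atrial-kick effects can shift extrema past ES).
#'
#' @param curves a `strain_curves` object.
#' @param window `"systole"` (ED to ES arc, default) or `"cycle"`.
#' @return data frame with region, component, peak strain (%), and the
#'   frame at which the peak occurs.
#' @export
peak_systolic <- function(curves, window = c("systole", "cycle")) {
  window <- match.arg(window)
  n <- dim(curves$strains)[3]
  idx <- if (window == "cycle") 0:(n - 1)
         else if (curves$es_index >= curves$ed_index)
           curves$ed_index:curves$es_index
         else c(curves$ed_index:(n - 1), 0:curves$es_index)
  out <- expand.grid(region = WS_REGIONS, component = c("CC", "LL", "RR"),
                     stringsAsFactors = FALSE)
  out$peak_percent <- NA_real_
  out$peak_frame <- NA_integer_
  for (i in seq_len(nrow(out))) {
    tr <- curves$strains[out$region[i], out$component[i], idx + 1]
    j <- if (out$component[i] == "RR") which.max(tr) else which.min(tr)
    out$peak_percent[i] <- 100 * tr[j]
    out$peak_frame[i] <- idx[j]
  }
  out
}

#' @method print strain_curves
#' @export
print.strain_curves <- function(x, ...) {
  n <- dim(x$strains)[3]
  cat(sprintf("strain_curves: %d frames (ED = %d, ES = %d)\n",
              n, x$ed_index, x$es_index))
  pk <- x$peaks
  wide <- stats::reshape(pk[, c("region", "component", "peak_percent")],
                         idvar = "region", timevar = "component",
                         direction = "wide")
  names(wide) <- sub("peak_percent\\.", "peak ", names(wide))
  print(wide, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @method as.data.frame strain_curves
#' @export
as.data.frame.strain_curves <- function(x, ...) {
  n <- dim(x$strains)[3]
  df <- expand.grid(region = WS_REGIONS, component = c("CC", "LL", "RR"),
                    frame = 0:(n - 1), stringsAsFactors = FALSE)
  df$time_s <- x$frame_times[df$frame + 1]
  df$strain <- as.numeric(x$strains)
  df$strain_percent <- 100 * df$strain
  df
}
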