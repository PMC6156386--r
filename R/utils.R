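# Internal helpers shared across modules.

# canonical facet tags and wall regions
WS_TAGS <- c("LV_ENDO", "RV_ENDO", "EPI", "BASE")
WS_REGIONS <- c("LV_FREE", "SEPTUM", "RV_FREE")
WS_TAG_IDS <- stats::setNames(seq_along(WS_TAGS), WS_TAGS)
WS_REGION_IDS <- stats::setNames(seq_along(WS_REGIONS), WS_REGIONS)

`%||%` <- function(a, b) if (is.null(a)) b else a

ws_stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

ws_unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-14) ws_stopf("zero-length vector cannot be normalized")
  v / n
}

# rows of an m x 3 matrix normalized to unit length
ws_unit_rows <- function(m, what = "vector") {
  n <- sqrt(rowSums(m^2))
  bad <- which(n < 1e-12)
  if (length(bad) > 0)
    ws_stopf("degenerate %s in cell(s) %s", what,
             paste(utils::head(bad, 5), collapse = ", "))
  m / n
}

ws_cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# --- 3x3 tensor fields stored as m x 9 matrices, row-major per cell:
# columns (11,12,13,21,22,23,31,32,33), matching the compiled core.

ws_mat3_to_rows <- function(F3) matrix(t(F3), nrow = 1)

ws_rows_to_mat3 <- function(Fm, i) matrix(Fm[i, ], 3, 3, byrow = TRUE)

ws_mat3_mul <- function(A, B) {
  # per-row product C = A %*% B for m x 9 fields
  C <- matrix(0, nrow(A), 9)
  for (i in 1:3) for (j in 1:3) {
    cc <- (i - 1) * 3 + j
    C[, cc] <- A[, (i - 1) * 3 + 1] * B[, j] +
               A[, (i - 1) * 3 + 2] * B[, 3 + j] +
               A[, (i - 1) * 3 + 3] * B[, 6 + j]
  }
  C
}

ws_mat3_det <- function(A) {
  A[, 1] * (A[, 5] * A[, 9] - A[, 6] * A[, 8]) -
  A[, 2] * (A[, 4] * A[, 9] - A[, 6] * A[, 7]) +
  A[, 3] * (A[, 4] * A[, 8] - A[, 5] * A[, 7])
}

ws_mat3_inv <- function(A) {
  d <- ws_mat3_det(A)
  if (any(abs(d) < 1e-300)) ws_stopf("singular tensor field (zero determinant)")
  inv <- matrix(0, nrow(A), 9)
  inv[, 1] <-  (A[, 5] * A[, 9] - A[, 6] * A[, 8]) / d
  inv[, 2] <- -(A[, 2] * A[, 9] - A[, 3] * A[, 8]) / d
  inv[, 3] <-  (A[, 2] * A[, 6] - A[, 3] * A[, 5]) / d
  inv[, 4] <- -(A[, 4] * A[, 9] - A[, 6] * A[, 7]) / d
  inv[, 5] <-  (A[, 1] * A[, 9] - A[, 3] * A[, 7]) / d
  inv[, 6] <- -(A[, 1] * A[, 6] - A[, 3] * A[, 4]) / d
  inv[, 7] <-  (A[, 4] * A[, 8] - A[, 5] * A[, 7]) / d
  inv[, 8] <- -(A[, 1] * A[, 8] - A[, 2] * A[, 7]) / d
  inv[, 9] <-  (A[, 1] * A[, 5] - A[, 2] * A[, 4]) / d
  inv
}

ws_mat3_identity <- function(m) {
  I <- matrix(0, m, 9)
  I[, c(1, 5, 9)] <- 1
  I
}

# C^1 cubic smoothstep on [x0, x1]
ws_smoothstep <- function(x, x0, x1) {
  t <- pmin(pmax((x - x0) / (x1 - x0), 0), 1)
  t * t * (3 - 2 * t)
}
ws_smoothstep_deriv <- function(x, x0, x1) {
  t <- (x - x0) / (x1 - x0)
  ifelse(t <= 0 | t >= 1, 0, 6 * t * (1 - t) / (x1 - x0))
}

#' Cardiac cycle phase profile
#'
#' Smooth phase running from 0 at end-diastole to 1 at end-systole and back
#' to 0 over one cycle.  When end-systole falls at mid-cycle this reduces to
#' \eqn{\sin^2(\pi t)} of the normalized cycle time; for asymmetric systole
#' and diastole the two half-waves are stretched so the maximum stays at the
#' end-systolic frame.
#'
#' @param frame frame index (0-based), may be a vector.
#' @param n_frames frames per cardiac cycle.
#' @param ed_index,es_index end-diastolic and end-systolic frame indices
#'   (0-based).
#' @return numeric vector of phase values in \[0, 1\].
#' @export
cycle_phase <- function(frame, n_frames, ed_index = 0, es_index = round(n_frames / 2)) {
  if (any(frame < 0 | frame >= n_frames))
    ws_stopf("frame index out of range [0, %d)", n_frames)
  tn <- ((frame - ed_index) %% n_frames) / n_frames
  tes <- ((es_index - ed_index) %% n_frames) / n_frames
  if (tes <= 0) ws_stopf("es_index must differ from ed_index")
  ifelse(tn <= tes,
         sin(pi / 2 * tn / tes)^2,
         sin(pi / 2 * (1 - tn) / (1 - tes))^2)
}
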