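#' Cine image series
#'
#' A stack of 3D intensity volumes over one cardiac cycle on a common
#' voxel-to-world affine (mm), with frame timing and the end-systolic /
#' end-diastolic frame indices.  The end-systolic frame is the template
#' (reference image R) of the registration; every other frame acts in turn
#' as the target T.
#'
#' @param frames list of 3D numeric arrays of identical dimension.
#' @param affine 4 x 4 voxel(0-based)-to-world affine (mm).
#' @param frame_times frame times in seconds.
#' @param es_index,ed_index end-systolic / end-diastolic frame indices
#'   (0-based).
#' @param normalized whether intensities are already on \[0, 1\].
#' @param normalization optional record of the normalization applied.
#' @return an object of class `image_series`.
#' @export
image_series <- function(frames, affine, frame_times = NULL,
                         es_index, ed_index = 0L,
                         normalized = FALSE, normalization = NULL) {
  if (!is.list(frames) || length(frames) < 2)
    ws_stopf("an image series needs at least 2 frames")
  dm <- dim(frames[[1]])
  if (length(dm) != 3) ws_stopf("frames must be 3D arrays")
  for (f in frames)
    if (!identical(dim(f), dm)) ws_stopf("inconsistent frame dimensions")
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)) ||
      abs(det(affine[1:3, 1:3])) < 1e-12)
    ws_stopf("affine must be an invertible 4 x 4 matrix")
  n <- length(frames)
  if (is.null(frame_times)) frame_times <- (0:(n - 1)) / n
  if (length(frame_times) != n) ws_stopf("frame_times must match frame count")
  es_index <- as.integer(es_index); ed_index <- as.integer(ed_index)
  if (es_index == ed_index) ws_stopf("es_index must differ from ed_index")
  if (es_index < 0 || es_index >= n || ed_index < 0 || ed_index >= n)
    ws_stopf("es/ed frame indices out of range [0, %d)", n)
  structure(list(frames = frames, affine = affine,
                 frame_times = as.numeric(frame_times),
                 es_index = es_index, ed_index = ed_index,
                 normalized = isTRUE(normalized),
                 normalization = normalization),
            class = "image_series")
}

#' @method print image_series
#' @export
print.image_series <- function(x, ...) {
  dm <- dim(x$frames[[1]])
  cat(sprintf("image_series: %d frames of %dx%dx%d (ES = %d, ED = %d)%s\n",
              length(x$frames), dm[1], dm[2], dm[3], x$es_index, x$ed_index,
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Intensity normalization of a cine series
#'
#' Linearly rescales the whole series so that its 1st and 99th intensity
#' percentiles map to 0 and 1, then clips to \[0, 1\].  The percentiles are
#' series-wide so a frame with unusual content cannot shift the scale of
#' the others.  The applied mapping is recorded for audit.
#'
#' @param x an [image_series()] or a list of 3D arrays.
#' @param ... when `x` is a raw list: arguments forwarded to
#'   [image_series()] (`affine`, `es_index`, ...).
#' @return a normalized [image_series()].
#' @export
normalize_series <- function(x, ...) {
  if (!inherits(x, "image_series")) x <- image_series(x, ...)
  qs <- stats::quantile(unlist(lapply(x$frames, range)), c(0, 1))
  all_v <- unlist(x$frames, use.names = FALSE)
  p <- stats::quantile(all_v, c(0.01, 0.99), names = FALSE)
  if (p[2] - p[1] < 1e-12)
    ws_stopf("constant image series cannot be normalized (p1 = p99 = %g)", p[1])
  frames <- lapply(x$frames, function(f)
    array(pmin(pmax((f - p[1]) / (p[2] - p[1]), 0), 1), dim = dim(f)))
  image_series(frames, x$affine, x$frame_times, x$es_index, x$ed_index,
               normalized = TRUE,
               normalization = list(p01 = p[1], p99 = p[2],
                                    input_range = as.numeric(qs)))
}

# world -> 0-based voxel affine (3 x 4)
ws_world2vox <- function(affine) solve(affine)[1:3, , drop = FALSE]

# smoothed frame + voxel-space gradients packaged for the compiled core
ws_frame_data <- function(series, frame, smooth_sd = 0) {
  arr <- series$frames[[frame + 1]]
  dm <- dim(arr)
  sd3 <- rep(smooth_sd, length.out = 3)
  sm <- if (any(sd3 > 0)) .ws_gauss3(as.numeric(arr), dm, sd3) else arr
  g <- .ws_grad3(as.numeric(sm), dm)
  list(T = as.numeric(sm), gx = g$gx, gy = g$gy, gz = g$gz,
       dim = dm, w2v = ws_world2vox(series$affine))
}

#' Sample intensity and spatial gradient of a frame
#'
#' Trilinear interpolation of the stored intensity; the spatial gradient is
#' taken on a Gaussian-presmoothed copy by central differences and
#' interpolated trilinearly, returned in world (per-mm) units.  Points
#' outside the grid return intensity 0 and a zero gradient.
#'
#' @param series an [image_series()].
#' @param frame frame index (0-based).
#' @param points n x 3 matrix of world coordinates (mm).
#' @param smooth_sd Gaussian presmoothing SD for the gradient, in voxels
#'   (scalar or per-axis); 0 disables smoothing.
#' @return list with `value` (n) and `gradient` (n x 3).
#' @export
sample_image <- function(series, frame, points, smooth_sd = 0) {
  points <- as.matrix(points)
  if (any(!is.finite(points))) ws_stopf("sample points must be finite")
  arr <- series$frames[[frame + 1]]
  dm <- dim(arr)
  w2v <- ws_world2vox(series$affine)
  # intensity from the raw frame
  hom <- cbind(points, 1)
  vox <- hom %*% t(w2v)
  val <- .ws_trilinear(as.numeric(arr), dm, vox, 0)
  # gradient from the presmoothed copy
  fd <- ws_frame_data(series, frame, smooth_sd)
  sg <- .ws_sample_grad(fd$T, fd$gx, fd$gy, fd$gz, dm, fd$w2v, points)
  list(value = as.numeric(val), gradient = sg$gradient)
}
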