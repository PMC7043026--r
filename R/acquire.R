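# Per-sample photon-like noise: Gaussian with variance gain*mean + read_var,
# clamped to the 16-bit range.
apply_shot_noise <- function(values, noise) {
  sd <- sqrt(pmax(noise[[1]] * values, 0) + noise[[2]])
  v <- values + stats::rnorm(length(values), 0, sd)
  pmin(pmax(round(v), 0), 65535)
}

#' Simulate a raster-scan t-series from a scene
#'
#' Samples every pixel of the field of view sequentially in row-major order
#' with the given dwell time, so pixel k of frame f is acquired at
#' t = f * Ny * Nx * dwell + k * dwell. The frame period is Ny * Nx * dwell.
#'
#' @param scene an `sls_scene`.
#' @param dwell per-pixel dwell time (s).
#' @param n_frames number of frames; the scene must cover
#'   n_frames * frame_period.
#' @param noise apply the photon-like noise model (default TRUE).
#' @param seed RNG seed for the noise draw (default derived from the scene).
#' @return object of class `sls_movie` with fields `data`
#'   (array ny x nx x frames), `dwell`, `frame_period`, `pixel_size`.
#' @export
acquire_raster <- function(scene, dwell, n_frames, noise = TRUE,
                           seed = scene$params$seed + 1000L) {
  stopifnot(inherits(scene, "sls_scene"), dwell > 0, n_frames >= 1)
  ny <- scene$params$fov[1]; nx <- scene$params$fov[2]
  frame_period <- ny * nx * dwell
  if (n_frames * frame_period > scene$duration + 1e-9)
    stopf("scene duration %.1f s does not cover %d frames of %.4f s",
          scene$duration, n_frames, frame_period)
  # row-major pixel order: row by row, columns fastest
  xo <- rep(0:(nx - 1), ny)
  yo <- rep(0:(ny - 1), each = nx)
  toff <- (seq_len(ny * nx) - 1) * dwell
  dat <- array(0, dim = c(ny, nx, n_frames))
  lin <- yo * 0L + (yo + 1L) + xo * ny  # row-major -> column-major index
  with_seed(if (noise) seed else NULL, {
    for (f in seq_len(n_frames)) {
      tt <- (f - 1) * frame_period + toff
      v <- scene_eval(scene, xo, yo, tt)
      if (noise) v <- apply_shot_noise(v, scene$params$noise)
      frame <- numeric(ny * nx)
      frame[lin] <- v
      dat[, , f] <- frame
    }
  })
  structure(list(data = dat, dwell = dwell, frame_period = frame_period,
                 pixel_size = scene$params$pixel_size,
                 fs = 1 / frame_period),
            class = "sls_movie")
}

#' Simulate an SLS acquisition of a scene along a trajectory
#'
#' Trajectory pixel k of scan s is sampled at t = s * L * dwell + k * dwell
#' (closed path, no flyback gap); transit pixels are recorded like all
#' others. The scan period is L * dwell.
#'
#' @param scene an `sls_scene`.
#' @param traj an `sls_trajectory` (see [build_trajectory()]); its
#'   coordinates must lie inside the scene FOV.
#' @param n_scans number of scans; n_scans * scan_period must not exceed
#'   the scene duration.
#' @inheritParams acquire_raster
#' @return object of class `sls_recording` with fields `data`
#'   (matrix L x n_scans), `traj`, `dwell`, `scan_period`, `fs`, and `t0`
#'   (scan start times; sample time = t0[s] + (k-1) * dwell).
#' @export
acquire_sls <- function(scene, traj, n_scans, noise = TRUE,
                        seed = scene$params$seed + 2000L) {
  stopifnot(inherits(scene, "sls_scene"), inherits(traj, "sls_trajectory"))
  ny <- scene$params$fov[1]; nx <- scene$params$fov[2]
  if (any(traj$pixels$x < 0 | traj$pixels$x >= nx |
          traj$pixels$y < 0 | traj$pixels$y >= ny))
    stopf("trajectory coordinates outside the %dx%d scene FOV", ny, nx)
  L <- nrow(traj$pixels)
  dwell <- traj$dwell
  scan_period <- L * dwell
  if (n_scans * scan_period > scene$duration + 1e-9)
    stopf("%d scans of %.4f s exceed the scene duration %.1f s",
          n_scans, scan_period, scene$duration)
  dat <- matrix(0, L, n_scans)
  toff <- (seq_len(L) - 1) * dwell
  chunk <- max(1L, floor(2e6 / L))
  with_seed(if (noise) seed else NULL, {
    s0 <- 1L
    while (s0 <= n_scans) {
      s1 <- min(s0 + chunk - 1L, n_scans)
      sc <- s0:s1
      tt <- rep((sc - 1) * scan_period, each = L) + rep(toff, length(sc))
      v <- scene_eval(scene, rep(traj$pixels$x, length(sc)),
                      rep(traj$pixels$y, length(sc)), tt)
      if (noise) v <- apply_shot_noise(v, scene$params$noise)
      dat[, sc] <- v
      s0 <- s1 + 1L
    }
  })
  structure(list(data = dat, traj = traj, dwell = dwell,
                 scan_period = scan_period, fs = 1 / scan_period,
                 t0 = (seq_len(n_scans) - 1) * scan_period),
            class = "sls_recording")
}

#' @export
print.sls_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("raster t-series: %dx%d px, %d frames @ %.3f Hz (dwell %.3g s)\n",
              d[1], d[2], d[3], x$fs, x$dwell))
  invisible(x)
}

#' @export
print.sls_recording <- function(x, ...) {
  cat(sprintf("SLS recording: %d trajectory px x %d scans @ %.2f Hz (dwell %.3g s)\n",
              nrow(x$data), ncol(x$data), x$fs, x$dwell))
  invisible(x)
}

# Mean trace over a set of (x, y) pixels of a movie. `pixels` is a matrix
# with columns x (col, 0-based) and y (row, 0-based).
movie_mask_trace <- function(movie, pixels) {
  ny <- dim(movie$data)[1]
  idx <- pixels[, "y"] + 1L + pixels[, "x"] * ny
  nf <- dim(movie$data)[3]
  m <- matrix(movie$data, ny * dim(movie$data)[2], nf)
  colMeans(m[idx, , drop = FALSE])
}
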