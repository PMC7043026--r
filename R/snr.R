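#' Pixel-wise SNR map of a t-series
#'
#' For each pixel, SNR = max over time of the fluorescence divided by the
#' noise, where noise is the standard deviation of the pixel's values
#' strictly below its 25th percentile (linear-interpolation percentile; a
#' <= fallback is used when the strict subset is degenerate, and pixels
#' that remain degenerate get SNR 0 with a warning).
#'
#' @param movie an `sls_movie` or a ny x nx x frames array.
#' @param interval optional frame index range c(first, last); default the
#'   whole series. At least 8 frames are required.
#' @return object of class `sls_snr_map`: list(snr = ny x nx matrix,
#'   interval).
#' @export
pixel_snr_map <- function(movie, interval = NULL) {
  dat <- if (inherits(movie, "sls_movie")) movie$data else movie
  stopifnot(length(dim(dat)) == 3)
  nf <- dim(dat)[3]
  if (is.null(interval)) interval <- c(1L, nf)
  if (interval[1] < 1 || interval[2] > nf) stopf("interval outside the movie")
  if (diff(interval) + 1 < 8) stopf("interval must span at least 8 frames")
  sub <- dat[, , interval[1]:interval[2], drop = FALSE]
  ny <- dim(sub)[1]; nx <- dim(sub)[2]
  m <- matrix(sub, ny * nx, dim(sub)[3])
  mx <- apply(m, 1, max)
  noise <- row_noise_sd(m)
  snr <- numeric(length(mx))
  ok <- noise > 0
  snr[ok] <- mx[ok] / noise[ok]
  if (any(!ok))
    warnf("%d pixel(s) with degenerate baseline; SNR set to 0", sum(!ok))
  structure(list(snr = matrix(snr, ny, nx), interval = interval),
            class = "sls_snr_map")
}

#' SNR of the mean trace of a pixel set
#'
#' The across-pixel mean trace is formed, then scored as
#' max(trace) / sd(values of the trace strictly below its 25th percentile).
#'
#' @inheritParams pixel_snr_map
#' @param pixels matrix with 0-based columns x (column) and y (row).
#' @return scalar SNR (0 for a degenerate trace).
#' @export
roi_trace_snr <- function(movie, pixels, interval = NULL) {
  dat <- if (inherits(movie, "sls_movie")) movie$data else movie
  stopifnot(nrow(pixels) >= 1)
  nf <- dim(dat)[3]
  if (is.null(interval)) interval <- c(1L, nf)
  ny <- dim(dat)[1]
  m <- matrix(dat, ny * dim(dat)[2], nf)
  idx <- pixels[, "y"] + 1L + pixels[, "x"] * ny
  tr <- colMeans(m[idx, interval[1]:interval[2], drop = FALSE])
  ns <- baseline_noise_sd(tr)
  if (ns == 0) return(0)
  max(tr) / ns
}

#' A square analysis box centered on a cell
#'
#' @param x,y 0-based center pixel coordinates.
#' @param side box side in pixels (odd); default from 11.8 um and the pixel
#'   size, odd-ified so the center is unique.
#' @param pixel_size um per pixel, used when `side` is NULL.
#' @param fov c(ny, nx); the box must lie fully inside.
#' @return object of class `sls_cellbox`.
#' @export
cell_box <- function(x, y, side = NULL, pixel_size = 0.77, fov) {
  if (is.null(side)) {
    side <- round(11.8 / pixel_size)
    if (side %% 2 == 0) side <- side + 1
  }
  if (side < 3) stopf("box side must be >= 3 pixels")
  h <- (side - 1) %/% 2
  if (x - h < 0 || y - h < 0 || x + h > fov[2] - 1 || y + h > fov[1] - 1)
    stopf("box [%d px] at (%d, %d) extends outside the %dx%d FOV",
          side, x, y, fov[1], fov[2])
  structure(list(x = as.integer(x), y = as.integer(y),
                 side = as.integer(side)), class = "sls_cellbox")
}

box_pixels <- function(box) {
  h <- (box$side - 1) %/% 2
  xs <- (box$x - h):(box$x + h)
  ys <- (box$y - h):(box$y + h)
  cbind(x = rep(xs, each = length(ys)), y = rep(ys, length(xs)))
}

#' Select the most informative pixels of a cell
#'
#' Pixels inside the box are ranked by descending pixel SNR (ties broken by
#' row-major order). The ROI-SNR curve A(n) is the SNR of the mean trace of
#' the top-n pixels; the default selection is the top-n* pixels at the
#' argmax of A(n). The alternative literal rule ("threshold") selects all
#' pixels whose individual SNR is at least A(n*).
#'
#' @inheritParams pixel_snr_map
#' @param box an [cell_box()].
#' @param rule "topn" (default) or "threshold"; see Details in the package
#'   vignette for why both readings are provided.
#' @return object of class `sls_roi_selection`: cell box, ranked
#'   candidates, curve A(n), n_star, selected pixel matrix, the reference
#'   frame (highest fluorescence in the box), and the pixel-SNR values.
#' @export
select_pixels <- function(movie, box, interval = NULL, rule = c("topn", "threshold")) {
  rule <- match.arg(rule)
  dat <- if (inherits(movie, "sls_movie")) movie$data else movie
  nf <- dim(dat)[3]
  if (is.null(interval)) interval <- c(1L, nf)
  px <- box_pixels(box)
  ny <- dim(dat)[1]
  m <- matrix(dat, ny * dim(dat)[2], nf)[px[, "y"] + 1L + px[, "x"] * ny,
                                         interval[1]:interval[2], drop = FALSE]
  if (all(m == m[1, 1])) {
    warnf("degenerate (constant) box at (%d, %d); empty selection",
          box$x, box$y)
    return(structure(list(box = box, candidates = px[0, , drop = FALSE],
                          curve = numeric(0), n_star = 0L,
                          selected = px[0, , drop = FALSE],
                          pixel_snr = numeric(0), ref_frame = NA_integer_),
                     class = "sls_roi_selection"))
  }
  frame_max <- apply(m, 2, max)
  ref_frame <- interval[1] + which.max(frame_max) - 1L
  mx <- apply(m, 1, max)
  noise <- row_noise_sd(m)
  snr <- ifelse(noise > 0, mx / noise, 0)
  # descending SNR; ties resolved by row-major pixel order (y * Nx + x)
  rowmaj <- px[, "y"] * dim(dat)[2] + px[, "x"]
  ord <- order(-snr, rowmaj)
  msort <- m[ord, , drop = FALSE]
  csum <- apply(msort, 2, cumsum)              # n x time cumulative sums
  ns <- seq_len(nrow(px))
  curve <- vapply(ns, function(n) {
    tr <- csum[n, ] / n
    s <- baseline_noise_sd(tr)
    if (s == 0) 0 else max(tr) / s
  }, numeric(1))
  n_star <- which.max(curve)
  selected <- if (rule == "topn") {
    px[ord[seq_len(n_star)], , drop = FALSE]
  } else {
    keep <- snr >= curve[n_star]
    px[keep, , drop = FALSE][order(rowmaj[keep]), , drop = FALSE]
  }
  structure(list(box = box, candidates = px[ord, , drop = FALSE],
                 curve = curve, n_star = as.integer(n_star),
                 selected = selected, pixel_snr = snr[ord],
                 peak_snr = curve[n_star], ref_frame = ref_frame,
                 rule = rule),
            class = "sls_roi_selection")
}

#' Colocalization of pixel selections across repeated segmentations
#'
#' Sums binary membership over exactly four equal-shape masks; membership in
#' 1, 2, 3 or 4 masks maps to 0, 50, 75 and 100 percent. Pixels selected in
#' no mask are reported as NA (they are not selected pixels).
#'
#' @param selections list of 4 equal-shape binary/logical matrices.
#' @return matrix of percentages (NA where never selected).
#' @export
colocalization <- function(selections) {
  if (length(selections) != 4) stopf("exactly 4 segmentations are required")
  dims <- lapply(selections, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stopf("segmentation masks have mismatched shapes")
  cnt <- Reduce(`+`, lapply(selections, function(m) (m != 0) * 1L))
  out <- matrix(NA_real_, nrow(cnt), ncol(cnt))
  out[cnt > 0] <- c(0, 50, 75, 100)[cnt[cnt > 0]]
  out
}

# Binary FOV mask from a list of selections.
selection_mask <- function(selections, fov) {
  m <- matrix(0L, fov[1], fov[2])
  for (s in selections) {
    if (nrow(s$selected))
      m[s$selected[, "y"] + 1L + s$selected[, "x"] * fov[1]] <- 1L
  }
  m
}
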