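#' Detect large motion artifacts via an AR(2) fit of PC1
#'
#' The time vector of the first term of the singular-value decomposition
#' of the per-pixel mean-centered \[pixel x scan\] matrix (PC1) is fitted by
#' a second-order autoregressive model on the whole series (least
#' squares). The Pearson correlation between PC1 and its one-step AR(2)
#' prediction is computed in a sliding window (~10 s, stepped one scan at
#' a time); a large artifact is detected wherever the correlation drops
#' below the threshold, and data from the first detection onward are
#' flagged for discard.
#'
#' @param rec an `sls_recording`, or a \[pixel x scan\] matrix plus `fs`.
#' @param threshold correlation threshold (default 0.3).
#' @param window window length in seconds (default 10; rounded to an odd
#'   number of scans, truncated at the edges).
#' @param fs sampling rate, required when `rec` is a bare matrix.
#' @param per_window_fit refit the AR(2) inside each window instead of
#'   once on the full series (default FALSE).
#' @return object of class `sls_artifact_report`: pc1, ar coefficients,
#'   correlation series, detection indices/times, truncation index (or
#'   NA), and the PC1 variance fraction.
#' @export
detect_large_artifacts <- function(rec, threshold = 0.3, window = 10,
                                   fs = NULL, per_window_fit = FALSE) {
  if (inherits(rec, "sls_recording")) {
    X <- rec$data; fs <- rec$fs
  } else {
    X <- as.matrix(rec)
    if (is.null(fs)) stopf("fs is required for a bare matrix")
  }
  ns <- ncol(X)
  if (ns < 4) stopf("at least 4 scans are required")
  if (ns / fs < window) stopf("recording shorter than one %g-s window", window)
  Xc <- X - rowMeans(X)
  sv <- first_singular(Xc)
  pc1 <- sv$v * sv$d
  tot_var <- sum(Xc^2)
  var_frac <- if (tot_var > 0) sv$d^2 / tot_var else 0

  ar_fit <- function(y) {
    n <- length(y)
    A <- cbind(1, y[2:(n - 1)], y[1:(n - 2)])
    stats::lsfit(A, y[3:n], intercept = FALSE)$coefficients
  }
  co <- ar_fit(pc1)
  pred_full <- co[1] + co[2] * pc1[2:(ns - 1)] + co[3] * pc1[1:(ns - 2)]
  obs_full <- pc1[3:ns]

  w <- round(window * fs)
  if (w %% 2 == 0) w <- w + 1
  half <- (w - 1) %/% 2
  n_obs <- length(obs_full)
  corr <- rep(NA_real_, n_obs)
  for (c0 in seq_len(n_obs)) {
    lo <- max(1, c0 - half); hi <- min(n_obs, c0 + half)
    o <- obs_full[lo:hi]
    p <- if (per_window_fit) {
      cw <- ar_fit(pc1[(lo + 2 - 2):(hi + 2)])
      yy <- pc1[(lo + 2 - 2):(hi + 2)]
      cw[1] + cw[2] * yy[2:(length(yy) - 1)] + cw[3] * yy[1:(length(yy) - 2)]
    } else pred_full[lo:hi]
    if (stats::sd(o) == 0 || stats::sd(p) == 0) { corr[c0] <- 1; next }
    corr[c0] <- stats::cor(o, p)
  }
  det <- which(corr < threshold)
  det_scans <- det + 2L                       # observation i is scan i+2
  trunc <- if (length(det)) det_scans[1] else NA_integer_
  structure(list(pc1 = pc1, ar_coef = co, correlation = corr,
                 detections = det_scans,
                 detection_times = (det_scans - 1) / fs,
                 truncation_index = trunc, var_frac = var_frac,
                 threshold = threshold, window_scans = w, fs = fs),
            class = "sls_artifact_report")
}

#' @export
print.sls_artifact_report <- function(x, ...) {
  cat(sprintf("artifact report: %d detections (threshold %.2f, window %d scans); PC1 var %.1f%%\n",
              length(x$detections), x$threshold, x$window_scans,
              100 * x$var_frac))
  invisible(x)
}

#' SNR-based pixel reassignment in sliding windows
#'
#' For each ROI with N originally selected pixels, every ~10-s sliding
#' window (stepped one scan at a time) keeps the N highest-SNR pixels
#' among the ROI's own pixels plus its local surround; the corrected
#' per-scan trace uses the window centered on that scan. Ties are broken
#' by trajectory pixel order.
#'
#' @param rec an `sls_recording`.
#' @param assign an `sls_pixel_assignment`.
#' @param window window length in seconds (default 10).
#' @param step window step in scans (default 1).
#' @return object of class `sls_reassignment`: per-ROI corrected traces
#'   \[ROIs x scans\], per-ROI list of per-window selected pixel indices,
#'   window centers (scan indices), and the candidate sets.
#' @export
reassign_pixels <- function(rec, assign, window = 10, step = 1L) {
  stopifnot(inherits(rec, "sls_recording"),
            inherits(assign, "sls_pixel_assignment"))
  a <- assign$assignment
  ns <- ncol(rec$data)
  fs <- rec$fs
  n_roi <- assign$n_rois
  if (!any(a$group == "local_np")) {
    message("surround width 0: no local pixels, reassignment is the identity")
    tr <- extract_traces(rec, assign)
    return(structure(list(traces = tr$roi, windows = NULL,
                          identity = TRUE), class = "sls_reassignment"))
  }
  w <- round(window * fs); if (w %% 2 == 0) w <- w + 1
  half <- (w - 1) %/% 2
  centers <- seq(1L, ns, by = step)
  traces <- matrix(NA_real_, n_roi, ns)
  sel_list <- vector("list", n_roi)
  for (i in seq_len(n_roi)) {
    own <- which(a$group == "roi" & a$roi == i)
    cand <- which((a$group == "roi" | a$group == "local_np") & a$roi == i)
    N <- length(own)
    if (N > length(cand))
      stopf("ROI %d: N = %d selected pixels exceed the %d available candidates",
            i, N, length(cand))
    sel_w <- vector("list", length(centers))
    for (ci in seq_along(centers)) {
      c0 <- centers[ci]
      lo <- max(1L, c0 - half); hi <- min(ns, c0 + half)
      sub <- rec$data[cand, lo:hi, drop = FALSE]
      nsd <- row_noise_sd(sub)
      snr <- ifelse(nsd > 0, apply(sub, 1, max) / pmax(nsd, 1e-12), 0)
      keep <- cand[order(-snr, cand)[seq_len(N)]]
      sel_w[[ci]] <- sort(keep)
    }
    sel_list[[i]] <- sel_w
    # per-scan trace from the window centered on that scan
    near <- findInterval(seq_len(ns), centers)
    near[near == 0] <- 1L
    for (s in seq_len(ns))
      traces[i, s] <- mean(rec$data[sel_w[[near[s]]], s])
  }
  structure(list(traces = traces, windows = sel_list, centers = centers,
                 identity = FALSE, traj = rec$traj,
                 window_scans = w, fs = fs),
            class = "sls_reassignment")
}

#' Motion displacement read out from pixel reassignment
#'
#' Per window and per ROI, the mean position of the selected pixels;
#' averaged across ROIs and centered by subtracting the time average.
#'
#' @param reass an `sls_reassignment` (not the identity passthrough).
#' @return matrix \[windows x 2\] of centered (x, y) displacement in pixels.
#' @export
displacement_from_reassignment <- function(reass) {
  stopifnot(inherits(reass, "sls_reassignment"))
  if (isTRUE(reass$identity))
    stopf("identity reassignment carries no displacement information")
  px <- reass$traj$pixels
  n_w <- length(reass$centers)
  n_roi <- length(reass$windows)
  xs <- matrix(0, n_w, n_roi); ys <- matrix(0, n_w, n_roi)
  for (i in seq_len(n_roi)) {
    for (ci in seq_len(n_w)) {
      idx <- reass$windows[[i]][[ci]]
      xs[ci, i] <- mean(px$x[idx])
      ys[ci, i] <- mean(px$y[idx])
    }
  }
  out <- cbind(x = rowMeans(xs), y = rowMeans(ys))
  sweep(out, 2, colMeans(out))
}
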