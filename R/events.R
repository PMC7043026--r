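#' dF/F0 normalization of a fluorescence trace
#'
#' Baseline samples are those strictly below the 25th percentile of the
#' trace (with a <= fallback for degenerate traces); F0 is the mean of the
#' baseline samples and negative dF/F0 values are clipped to 0.
#'
#' @param trace positive fluorescence trace.
#' @param baseline_prob percentile defining periods of no activity
#'   (default 0.25).
#' @return object of class `sls_dff`: list(dff, baseline_mask (logical),
#'   f0).
#' @export
dff <- function(trace, baseline_prob = 0.25) {
  q <- stats::quantile(trace, baseline_prob, names = FALSE, type = 7)
  mask <- trace < q
  if (!any(mask)) mask <- trace <= q
  f0 <- mean(trace[mask])
  if (!is.finite(f0) || f0 <= 0)
    stopf("baseline fluorescence F0 = %.3g is not positive", f0)
  raw <- (trace - f0) / f0
  structure(list(dff = pmax(raw, 0), dff_raw = raw, baseline_mask = mask,
                 f0 = f0), class = "sls_dff")
}

#' Detect calcium events on a dF/F0 trace
#'
#' Events are local maxima of the dF/F0 series that (i) lie outside the
#' baseline periods, (ii) exceed the 50th percentile of the dF/F0 trace,
#' and (iii) have an onset-to-peak duration compatible with the indicator
#' kinetics (default 0.05-1.0 s). Event time is the peak time. When the
#' sampling rate cannot resolve the kinetics window, criterion (iii) is
#' disabled with a warning.
#'
#' @param x an `sls_dff` object or a non-negative numeric series.
#' @param fs sampling rate (Hz).
#' @param peak_window c(min, max) admissible onset-to-peak times (s).
#' @param amplitude_prob percentile of the trace an event must exceed
#'   (default 0.5).
#' @param amp_floor_sd additional noise floor: events must also exceed
#'   this many robust standard deviations (MAD) of the unclipped dF/F0
#'   series (default 3.5, which keeps the expected number of false peaks
#'   per few hundred samples well below one). The percentile criterion
#'   alone admits arbitrarily small noise peaks on a clipped trace.
#' @param min_separation events closer than this (s) are merged, keeping
#'   the largest (default 1.0, about half the decay constant; noisy decay
#'   bumps otherwise re-trigger).
#' @param onset_frac onset = last sample before the peak at or below this
#'   fraction of the peak amplitude.
#' @param roi optional ROI id stored with the events.
#' @return data.frame (roi, t_peak, amplitude, i_peak); class `sls_events`.
#' @export
detect_events <- function(x, fs, peak_window = c(0.05, 1.0),
                          amplitude_prob = 0.5, amp_floor_sd = 3.5,
                          min_separation = 1.0, onset_frac = 0.1, roi = NA) {
  if (fs <= 0) stopf("fs must be positive")
  if (inherits(x, "sls_dff")) {
    y <- x$dff; mask <- x$baseline_mask
    yr <- if (!is.null(x$dff_raw)) x$dff_raw else y
  } else {
    y <- as.numeric(x)
    yr <- y
    mask <- y < stats::quantile(y, 0.25, names = FALSE)
  }
  check_ttp <- TRUE
  if (fs * peak_window[2] < 1) {
    warnf("sampling rate %.3g Hz cannot resolve the %g-s kinetics window; criterion (iii) disabled",
          fs, peak_window[2])
    check_ttp <- FALSE
  }
  amp_thr <- stats::quantile(y, amplitude_prob, names = FALSE)
  sigma <- stats::mad(yr)
  if (!is.finite(sigma)) sigma <- 0
  thr <- max(amp_thr, amp_floor_sd * sigma)
  pk <- local_maxima(y)
  pk <- pk[!mask[pk] & y[pk] > thr & y[pk] > 0]
  if (check_ttp && length(pk)) {
    # onset = last sample at or below onset_frac of the peak amplitude;
    # a peak with no such onset nearby is a bump riding an earlier decay
    lookback <- max(1L, ceiling(3 * peak_window[2] * fs))
    ok <- vapply(pk, function(i) {
      j0 <- max(1L, i - lookback)
      below <- which(y[j0:(i - 1)] <= onset_frac * y[i])
      if (!length(below)) return(FALSE)
      ttp <- (i - (j0 + max(below) - 1)) / fs
      ttp >= peak_window[1] && ttp <= peak_window[2]
    }, logical(1))
    pk <- pk[ok]
  }
  if (length(pk) > 1 && min_separation > 0) {
    # greedy non-maximum suppression within min_separation
    ordk <- pk[order(-y[pk], pk)]
    kept <- integer(0)
    for (i in ordk)
      if (!length(kept) || all(abs(kept - i) >= min_separation * fs))
        kept <- c(kept, i)
    pk <- sort(kept)
  }
  ev <- data.frame(roi = rep(roi, length(pk)), t_peak = (pk - 1) / fs,
                   amplitude = y[pk], i_peak = pk)
  class(ev) <- c("sls_events", "data.frame")
  attr(ev, "fs") <- fs
  ev
}

#' Classify events as small or large
#'
#' Threshold at the 50th percentile of the event amplitude distribution;
#' amplitudes at or below the threshold are "small".
#'
#' @param events an `sls_events` data.frame (>= 2 events; a single event
#'   is left unlabeled with a warning).
#' @return the events with an added `size` column.
#' @export
classify_event_size <- function(events) {
  if (nrow(events) < 2) {
    warnf("fewer than 2 events; size classes undefined")
    events$size <- rep(NA_character_, nrow(events))
    return(events)
  }
  thr <- stats::median(events$amplitude)
  events$size <- ifelse(events$amplitude <= thr, "small", "large")
  events
}

#' Event SNR of a dF/F0 trace
#'
#' Absolute maximum of the dF/F0 series divided by the standard deviation
#' of its no-activity (baseline) samples.
#'
#' @param x an `sls_dff` object.
#' @return scalar SNR.
#' @export
series_snr <- function(x) {
  stopifnot(inherits(x, "sls_dff"))
  if (!any(x$baseline_mask)) stopf("empty baseline mask")
  s <- stats::sd(x$dff[x$baseline_mask])
  if (!is.finite(s) || s == 0) stopf("zero baseline standard deviation")
  max(abs(x$dff)) / s
}

#' Stimulus-evoked responsiveness of ROIs
#'
#' A stimulus pulse is valid for a ROI only when preceded by a continuous
#' quiet (event-free) baseline of `quiet` seconds; the ROI is responsive
#' if at least one event peaks within `response_window` seconds of at
#' least one valid pulse.
#'
#' @param events an `sls_events` data.frame with a `roi` column.
#' @param stim_times stimulus onset times (s), inside the recording.
#' @param rois ids to score (default those present in `events`).
#' @param response_window response window after the pulse (s, default 2).
#' @param quiet required pre-stimulus no-activity period (s, default 7).
#' @return data.frame (roi, responsive (logical, NA when the ROI has no
#'   valid pulse), n_valid, n_hits).
#' @export
evoked_responsiveness <- function(events, stim_times, rois = NULL,
                                  response_window = 2, quiet = 7) {
  if (is.null(rois)) rois <- sort(unique(events$roi))
  out <- lapply(rois, function(r) {
    et <- events$t_peak[events$roi == r]
    valid <- vapply(stim_times, function(ts)
      !any(et >= ts - quiet & et < ts), logical(1))
    hits <- vapply(stim_times, function(ts)
      any(et > ts & et <= ts + response_window), logical(1))
    n_valid <- sum(valid)
    data.frame(roi = r,
               responsive = if (n_valid == 0) NA else any(valid & hits),
               n_valid = n_valid, n_hits = sum(valid & hits))
  })
  do.call(rbind, out)
}

#' Detect action potentials in an electrophysiology trace
#'
#' The trace is high-pass filtered (FFT brick wall, corner 100 Hz) and
#' spikes are threshold crossings at two standard deviations of the
#' quietest 10-s segment, with a 2-ms refractory period; spike time is the
#' local absolute maximum after each crossing.
#'
#' @param trace voltage/current series.
#' @param fs sampling rate, >= 1 kHz.
#' @param corner high-pass corner frequency (Hz, default 100).
#' @param quiet_len length of the quiet segment used for the threshold
#'   (s, default 10).
#' @param thresh_sd crossing threshold in quiet-segment standard
#'   deviations (default 2).
#' @param min_amplitude_sd spike peaks must additionally reach this many
#'   quiet-segment standard deviations (default 6). A bare 2-s.d.
#'   crossing rule fires on ~2% of samples of any stationary noise, so a
#'   peak-amplitude floor is required for automated use.
#' @return numeric vector of spike times (s).
#' @export
detect_aps <- function(trace, fs, corner = 100, quiet_len = 10,
                       thresh_sd = 2, min_amplitude_sd = 6) {
  if (fs < 1000) stopf("fs >= 1 kHz is required for AP detection")
  n <- length(trace)
  if (n < quiet_len * fs) stopf("no %g-s quiet segment available", quiet_len)
  # FFT brick-wall high-pass
  ft <- stats::fft(trace - mean(trace))
  freqs <- (seq_len(n) - 1) * fs / n
  freqs <- pmin(freqs, fs - freqs)
  ft[freqs < corner] <- 0
  hp <- Re(stats::fft(ft, inverse = TRUE)) / n
  # quietest window by running RMS
  wl <- round(quiet_len * fs)
  cs <- c(0, cumsum(hp^2))
  starts <- seq(1, n - wl + 1, by = max(1, round(fs / 10)))
  rms <- (cs[starts + wl] - cs[starts]) / wl
  q0 <- starts[which.min(rms)]
  s_quiet <- stats::sd(hp[q0:(q0 + wl - 1)])
  if (s_quiet == 0) stopf("degenerate quiet segment")
  thr <- thresh_sd * s_quiet
  floor_amp <- min_amplitude_sd * s_quiet
  above <- abs(hp) > thr
  cross <- which(above & !c(FALSE, above[-n]))
  refr <- round(0.002 * fs)
  times <- numeric(0)
  last <- -Inf
  for (i in cross) {
    if (i - last < refr) next
    j <- i:min(n, i + refr)
    pk <- j[which.max(abs(hp[j]))]
    if (abs(hp[pk]) < floor_amp) next
    times <- c(times, (pk - 1) / fs)
    last <- pk
  }
  times
}

#' Isolated action potentials
#'
#' Spikes with no other spike within `pre` seconds before and `post`
#' seconds after.
#'
#' @param spikes sorted spike times (s).
#' @param pre,post isolation margins (s, defaults 0.4 and 1).
#' @return the isolated subset of `spikes`.
#' @export
isolated_aps <- function(spikes, pre = 0.4, post = 1) {
  if (length(spikes) <= 1) return(spikes)
  keep <- vapply(seq_along(spikes), function(i) {
    d <- spikes[-i] - spikes[i]
    !any(d >= -pre & d <= post)
  }, logical(1))
  spikes[keep]
}

#' Accuracy of single-AP detection from calcium events
#'
#' Fraction of isolated spikes with at least one event peak inside the
#' tolerance window after the spike; each event can match at most one
#' spike (greedy in time order).
#'
#' @param spikes isolated spike times (s).
#' @param events an `sls_events` data.frame (or numeric peak times).
#' @param tolerance c(min, max) window after the spike (s); default
#'   c(0, 1.5), the kernel rise plus a few sample periods.
#' @return value in \[0, 1\] (NA when there are no spikes).
#' @export
ap_accuracy <- function(spikes, events, tolerance = c(0, 1.5)) {
  if (!length(spikes)) return(NA_real_)
  et <- if (is.data.frame(events)) events$t_peak else as.numeric(events)
  if (!length(et)) return(0)
  et <- sort(et)
  used <- rep(FALSE, length(et))
  hits <- 0L
  for (s in sort(spikes)) {
    ok <- which(!used & et >= s + tolerance[1] & et <= s + tolerance[2])
    if (length(ok)) { used[ok[1]] <- TRUE; hits <- hits + 1L }
  }
  hits / length(spikes)
}

#' Temporal or spatial downsampling of acquisitions
#'
#' Temporal downsampling keeps every k-th frame/scan (rate divided by k).
#' Spatial downsampling keeps, for each ROI, the top fraction of its
#' pixels ranked by SNR on the recording (seeded tie-break), returning a
#' thinned pixel assignment.
#'
#' @param x an `sls_movie`, `sls_recording` or matrix (temporal mode).
#' @param factor integer >= 1 temporal decimation factor.
#' @return the same class as `x` with reduced sampling.
#' @export
downsample_temporal <- function(x, factor) {
  if (factor < 1 || factor != round(factor)) stopf("factor must be an integer >= 1")
  factor <- as.integer(factor)
  if (inherits(x, "sls_movie")) {
    keep <- seq(1, dim(x$data)[3], by = factor)
    if (!length(keep)) stopf("downsampling left no frames")
    x$data <- x$data[, , keep, drop = FALSE]
    x$frame_period <- x$frame_period * factor
    x$fs <- x$fs / factor
    return(x)
  }
  if (inherits(x, "sls_recording")) {
    keep <- seq(1, ncol(x$data), by = factor)
    if (!length(keep)) stopf("downsampling left no scans")
    x$data <- x$data[, keep, drop = FALSE]
    x$scan_period <- x$scan_period * factor
    x$fs <- x$fs / factor
    x$t0 <- x$t0[keep]
    return(x)
  }
  m <- as.matrix(x)
  m[, seq(1, ncol(m), by = factor), drop = FALSE]
}

#' @rdname downsample_temporal
#' @param rec an `sls_recording`.
#' @param assign an `sls_pixel_assignment`.
#' @param fraction fraction of each ROI's pixels to keep, in (0, 1].
#' @param seed RNG seed for the tie-break.
#' @export
downsample_spatial <- function(rec, assign, fraction, seed = 1L) {
  if (fraction <= 0 || fraction > 1) stopf("fraction must lie in (0, 1]")
  a <- assign$assignment
  with_seed(seed, {
    for (i in seq_len(assign$n_rois)) {
      idx <- which(a$group == "roi" & a$roi == i)
      n_keep <- max(1L, floor(fraction * length(idx)))
      sub <- rec$data[idx, , drop = FALSE]
      nsd <- row_noise_sd(sub)
      snr <- ifelse(nsd > 0, apply(sub, 1, max) / pmax(nsd, 1e-12), 0)
      jitter <- stats::runif(length(idx), 0, 1e-9)  # seeded tie-break
      drop <- idx[order(-(snr + jitter))][-seq_len(n_keep)]
      if (length(drop)) a$group[drop] <- "skipped"
    }
  })
  assign$assignment <- a
  assign
}
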