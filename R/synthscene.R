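#' Parameters of a synthetic imaging scene
#'
#' Builds a validated parameter set describing a densely GCaMP6s-labeled
#' field of view: donut-shaped somata with dim nuclei and log-normal
#' brightness, Poisson spiking convolved with slow indicator kinetics, a
#' shared neuropil field, photon-like noise, Ornstein-Uhlenbeck jitter plus
#' optional locomotion bouts, and an air-puff stimulation protocol.
#'
#' @param fov integer c(ny, nx) field-of-view size in pixels.
#' @param pixel_size pixel size in micrometers (default 0.77).
#' @param n_cells number of somata to place.
#' @param soma_diameter c(mean, sd) nominal soma extent in micrometers
#'   (default 11.8 +/- 0.7); sets cell spacing and the analysis box.
#' @param fill_fraction fraction of the nominal extent occupied by the
#'   fluorescent soma (default 0.7, so a 15 px box holds a cell of
#'   roughly 85 px, matching reported whole-cell areas).
#' @param nucleus_fraction nucleus radius as a fraction of the soma radius,
#'   in (0, 1).
#' @param nucleus_dim relative brightness of the nucleus vs cytoplasm.
#' @param nucleus_response attenuation of the calcium modulation in the
#'   nucleus (indicator largely excluded; default 0.2).
#' @param brightness c(meanlog, sdlog) of the log-normal cytoplasmic
#'   brightness distribution (16-bit counts).
#' @param texture_sd sdlog of the per-pixel log-normal brightness texture
#'   inside each cell (non-homogeneous indicator staining).
#' @param baseline_offset additive background offset (counts).
#' @param single_ap_dff peak dF/F0 of a single action potential (free
#'   simulator parameter, default 0.2).
#' @param firing_rate spontaneous mean action-potential rate per cell
#'   (Hz, default 0.29).
#' @param burst_mean mean number of spikes per firing event (bursty
#'   discharge typical of layer IV; event rate is firing_rate/burst_mean
#'   so the mean AP rate is preserved). 1 gives plain Poisson spiking.
#' @param kinetics c(rise, decay) indicator time constants in seconds.
#' @param neuropil_gain neuropil brightness relative to the typical cell.
#' @param noise c(gain, read_var): per-sample Gaussian variance is
#'   gain * mean + read_var. The default gain of 100 counts per detected
#'   photon keeps single pixels in the low-photon regime typical of
#'   microsecond dwell times while the noise stays approximately Gaussian.
#' @param motion list(jitter_sd, jitter_tau, bout_rate, bout_jump,
#'   bout_duration, bout_tremor_tau, bout_dim): OU jitter (um, s) and
#'   Poisson-timed locomotion bouts (Hz, um, s) carrying a step jump, fast
#'   lateral tremor with the given correlation time (s), and synchronous
#'   aperiodic fluorescence dimming of up to `bout_dim` with a weak
#'   stride-rhythm component at `bout_freq` Hz (axial defocus during a
#'   running epoch dims the whole FOV erratically from scan to scan --
#'   the fast synchronous signature the AR(2)/PC1 artifact screen
#'   detects). bout_rate = 0 emulates anesthesia.
#' @param stimulus list describing the air-puff protocol; when `enabled`,
#'   each trial delivers `n_trains` trains (interval `train_interval` s) of
#'   `pulses_per_train` puffs of `pulse_duration` s at duty cycle `duty`.
#' @param duration recording duration in seconds.
#' @param seed integer; fully determines the scene.
#' @param dt internal time grid step (s).
#' @return object of class `sls_scene_params`.
#' @export
scene_params <- function(fov = c(96L, 96L), pixel_size = 0.77, n_cells = 40L,
                         soma_diameter = c(mean = 11.8, sd = 0.7),
                         fill_fraction = 0.7,
                         nucleus_fraction = 0.45, nucleus_dim = 0.25,
                         nucleus_response = 0.2,
                         brightness = c(meanlog = log(2000), sdlog = 0.35),
                         texture_sd = 0.2,
                         baseline_offset = 50,
                         single_ap_dff = 0.2,
                         firing_rate = 0.29,
                         burst_mean = 2.5,
                         kinetics = c(rise = 0.18, decay = 1.8),
                         neuropil_gain = 0.25,
                         noise = c(gain = 100, read_var = 2500),
                         motion = list(jitter_sd = 0.15, jitter_tau = 1.0,
                                       bout_rate = 0, bout_jump = 5,
                                       bout_duration = 12,
                                       bout_tremor_tau = 0.01,
                                       bout_dim = 0.7, bout_freq = 9),
                         stimulus = list(enabled = FALSE, trial_starts = 20,
                                         n_trains = 4, train_interval = 2,
                                         pulses_per_train = 4,
                                         pulse_duration = 0.2, duty = 0.5,
                                         response_prob = 0.6,
                                         responsive_fraction = 0.7,
                                         evoked_spikes = 2),
                         duration = 120, seed = 1L, dt = 0.01) {
  stopifnot(length(fov) == 2, all(fov >= 8))
  if (pixel_size <= 0 || duration <= 0 || dt <= 0)
    stopf("pixel_size, duration and dt must be strictly positive")
  if (n_cells < 0) stopf("n_cells must be >= 0")
  if (soma_diameter[[1]] <= 0) stopf("soma diameter must be positive")
  if (nucleus_fraction <= 0 || nucleus_fraction >= 1)
    stopf("nucleus_fraction must lie in (0, 1)")
  if (any(kinetics <= 0)) stopf("kinetics time constants must be positive")
  if (firing_rate < 0) stopf("firing_rate must be >= 0")
  if (any(noise < 0)) stopf("noise parameters must be >= 0")
  def_stim <- eval(formals(scene_params)$stimulus)
  def_mot <- eval(formals(scene_params)$motion)
  stimulus <- utils::modifyList(def_stim, stimulus)
  motion <- utils::modifyList(def_mot, motion)
  p <- list(fov = as.integer(fov), pixel_size = pixel_size,
            n_cells = as.integer(n_cells), soma_diameter = soma_diameter,
            fill_fraction = fill_fraction,
            nucleus_fraction = nucleus_fraction, nucleus_dim = nucleus_dim,
            nucleus_response = nucleus_response,
            brightness = brightness, texture_sd = texture_sd,
            baseline_offset = baseline_offset,
            single_ap_dff = single_ap_dff, firing_rate = firing_rate,
            burst_mean = burst_mean,
            kinetics = kinetics, neuropil_gain = neuropil_gain,
            noise = noise, motion = motion, stimulus = stimulus,
            duration = duration, seed = as.integer(seed), dt = dt)
  class(p) <- "sls_scene_params"
  p
}

#' Single-spike GCaMP response and spike-train superposition
#'
#' Linear superposition of per-spike kernels
#' (1 - exp(-t/tau_rise)) * exp(-t/tau_decay), each peak-normalized so a
#' single action potential reaches unit amplitude.
#'
#' @param spikes numeric vector of sorted spike times (s).
#' @param t time grid (s).
#' @param kinetics c(rise, decay) time constants (s), both positive.
#' @return non-negative series on `t`.
#' @export
gcamp_response <- function(spikes, t, kinetics = c(rise = 0.18, decay = 1.8)) {
  tr <- kinetics[[1]]; td <- kinetics[[2]]
  if (tr <= 0 || td <= 0) stopf("kinetics time constants must be positive")
  if (length(spikes) && is.unsorted(spikes)) stopf("spike times must be sorted")
  out <- numeric(length(t))
  if (!length(spikes)) return(out)
  # analytic peak of the kernel, used for unit normalization
  tpk <- tr * log(1 + td / tr)
  pk <- (1 - exp(-tpk / tr)) * exp(-tpk / td)
  for (s in spikes) {
    dt <- t - s
    pos <- dt > 0
    out[pos] <- out[pos] + (1 - exp(-dt[pos] / tr)) * exp(-dt[pos] / td) / pk
  }
  out
}

# Air-puff onset times for one protocol, all trials.
stimulus_onsets <- function(stim) {
  if (!isTRUE(stim$enabled)) return(numeric(0))
  period <- stim$pulse_duration / stim$duty
  unlist(lapply(stim$trial_starts, function(t0) {
    trains <- t0 + (seq_len(stim$n_trains) - 1) * stim$train_interval
    as.vector(outer((seq_len(stim$pulses_per_train) - 1) * period, trains, `+`))
  }))
}

# Radial donut profile for one cell over its bounding box, split into a
# cytoplasmic component (full calcium modulation) and a nuclear one
# (dimmer, attenuated response: nuclear GCaMP is largely excluded).
cell_image <- function(cx, cy, r_px, r_nuc, bright, nucleus_dim) {
  x0 <- floor(cx - r_px - 1); x1 <- ceiling(cx + r_px + 1)
  y0 <- floor(cy - r_px - 1); y1 <- ceiling(cy + r_px + 1)
  xs <- x0:x1; ys <- y0:y1
  rr <- sqrt(outer((ys - cy)^2, (xs - cx)^2, `+`))
  w <- pmin(pmax((r_px + 0.25 - rr) / 0.5, 0), 1)  # crisp half-pixel edge
  in_nuc <- rr <= r_nuc
  list(img_cyto = bright * w * !in_nuc,
       img_nuc = bright * nucleus_dim * w * in_nuc,
       x0 = x0, y0 = y0, x1 = x1, y1 = y1)
}

#' Generate a ground-truth synthetic scene
#'
#' Places non-overlapping donut-shaped somata, draws Poisson (plus optional
#' stimulus-evoked) spike trains, builds the shared neuropil field and
#' signal, the motion path, and a continuous-time intensity model that any
#' scanner can sample via [scene_eval()].
#'
#' @param params an [scene_params()] object.
#' @return object of class `sls_scene`.
#' @export
make_scene <- function(params) {
  stopifnot(inherits(params, "sls_scene_params"))
  p <- params
  with_seed(p$seed, {
    ny <- p$fov[1]; nx <- p$fov[2]
    r_mean <- p$soma_diameter[[1]] / 2 / p$pixel_size
    r_sd <- p$soma_diameter[[2]] / 2 / p$pixel_size

    ## --- cell placement with bounded retries -------------------------------
    centers <- matrix(numeric(0), 0, 2)
    radii <- numeric(0)
    tries <- 0L; max_tries <- 2000L * max(p$n_cells, 1L)
    while (nrow(centers) < p$n_cells) {
      tries <- tries + 1L
      if (tries > max_tries)
        stopf("could not place %d non-overlapping cells in a %dx%d FOV (density too high)",
              p$n_cells, ny, nx)
      r <- max(2, stats::rnorm(1, r_mean, r_sd))
      cx <- stats::runif(1, r + 1, nx - r - 2)
      cy <- stats::runif(1, r + 1, ny - r - 2)
      if (nrow(centers)) {
        d <- sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2)
        # bright somata (fill_fraction of nominal) must stay disjoint,
        # including the 1 px sampling support on each side
        if (any(d < p$fill_fraction * (radii + r) + 2.5)) next
      }
      centers <- rbind(centers, c(cx, cy))
      radii <- c(radii, r)
    }

    bright <- stats::rlnorm(p$n_cells, p$brightness[[1]], p$brightness[[2]])
    imgs <- vector("list", p$n_cells)
    cyto <- vector("list", p$n_cells)
    nucl <- vector("list", p$n_cells)
    for (i in seq_len(p$n_cells)) {
      r_b <- p$fill_fraction * radii[i]          # fluorescent soma radius
      r_nuc <- p$nucleus_fraction * r_b
      imgs[[i]] <- cell_image(centers[i, 1], centers[i, 2], r_b, r_nuc,
                              bright[i], p$nucleus_dim)
      if (p$texture_sd > 0) {
        im <- imgs[[i]]
        tex <- matrix(stats::rlnorm(length(im$img_cyto), 0, p$texture_sd),
                      nrow(im$img_cyto))
        imgs[[i]]$img_cyto <- im$img_cyto * tex
        imgs[[i]]$img_nuc <- im$img_nuc * tex
      }
      # ground-truth masks: a pixel is "cytoplasmic" when its recorded
      # intensity is dominated by cytoplasmic fluorescence under the
      # bilinear sampling model, i.e. within one pixel of the bright ring
      im <- imgs[[i]]
      xs <- im$x0:im$x1; ys <- im$y0:im$y1
      gx <- rep(xs, each = length(ys)); gy <- rep(ys, length(xs))
      rr <- sqrt((gx - centers[i, 1])^2 + (gy - centers[i, 2])^2)
      inside <- rr <= r_b + 1.0
      px <- cbind(x = gx[inside], y = gy[inside])
      rrin <- rr[inside]
      cyto[[i]] <- px[rrin > r_nuc, , drop = FALSE]
      nucl[[i]] <- px[rrin <= r_nuc, , drop = FALSE]
    }

    ## --- spikes ------------------------------------------------------------
    stim_times <- stimulus_onsets(p$stimulus)
    responsive <- if (p$n_cells)
      stats::runif(p$n_cells) < p$stimulus$responsive_fraction else logical(0)
    spikes <- vector("list", p$n_cells)
    for (i in seq_len(p$n_cells)) {
      # bursty discharge: Poisson firing events carrying 1+ APs each,
      # with the mean AP rate anchored at firing_rate
      n_ev <- stats::rpois(1, p$firing_rate / p$burst_mean * p$duration)
      ev_t <- stats::runif(n_ev, 0, p$duration)
      sizes <- 1L + stats::rpois(n_ev, p$burst_mean - 1)
      sp <- sort(unlist(lapply(seq_len(n_ev), function(e)
        ev_t[e] + cumsum(c(0, stats::runif(sizes[e] - 1L, 0.01, 0.05))))))
      sp <- sp[sp <= p$duration]
      if (!length(sp)) sp <- numeric(0)
      if (length(stim_times) && responsive[i]) {
        for (ts in stim_times) {
          if (stats::runif(1) < p$stimulus$response_prob) {
            k <- sample.int(p$stimulus$evoked_spikes, 1)
            sp <- c(sp, ts + stats::runif(k, 0.005, 0.06))
          }
        }
        sp <- sort(sp[sp <= p$duration])
      }
      spikes[[i]] <- sp
    }

    ## --- temporal signals on the fine grid ---------------------------------
    tgrid <- seq(0, p$duration, by = p$dt)
    nt <- length(tgrid)
    cal <- matrix(0, nt, max(p$n_cells, 1L))
    for (i in seq_len(p$n_cells))
      cal[, i] <- p$single_ap_dff * gcamp_response(spikes[[i]], tgrid, p$kinetics)
    if (!p$n_cells) cal <- matrix(0, nt, 0)

    # neuropil: low-passed population mean calcium plus an independent slow
    # component; strictly zero when neuropil_gain == 0
    np_t <- rep(0, nt)
    if (p$neuropil_gain > 0) {
      pop <- if (p$n_cells) rowMeans(cal) else rep(0, nt)
      k <- exp(-p$dt / 1.0)
      lp <- stats::filter(pop, k, method = "recursive") * (1 - k)
      slow <- stats::filter(stats::rnorm(nt, 0, 1), exp(-p$dt / 3),
                            method = "recursive")
      slow <- as.numeric(slow) * sqrt(1 - exp(-2 * p$dt / 3))
      # shared flicker is the dominant common-mode noise source in vivo;
      # its sd (~0.15 of the neuropil brightness) sets the floor that the
      # ROI-SNR curve runs into as pixels accrue
      np_t <- as.numeric(lp) + 0.15 * slow
      np_t <- pmax(np_t, -0.9)
    }

    # smooth spatial neuropil weight field from coarse upsampled noise
    np_field <- matrix(0, ny, nx)
    if (p$neuropil_gain > 0) {
      cg <- matrix(stats::rlnorm(64, 0, 0.15), 8, 8)
      xi <- seq(0, 7, length.out = nx); yi <- seq(0, 7, length.out = ny)
      np_field <- matrix(bilinear_sample(cg,
                                         rep(xi, each = ny), rep(yi, nx)),
                         ny, nx)
      np_field <- np_field / mean(np_field)
      np_field <- p$neuropil_gain * exp(p$brightness[[1]]) * np_field
    }

    ## --- motion path -------------------------------------------------------
    motion <- matrix(0, nt, 2)
    dimming <- rep(1, nt)
    m <- p$motion
    if (m$jitter_sd > 0) {
      a <- exp(-p$dt / m$jitter_tau)
      s <- m$jitter_sd * sqrt(1 - a^2)
      for (d in 1:2)
        motion[, d] <- as.numeric(
          stats::filter(stats::rnorm(nt, 0, s), a, method = "recursive"))
    }
    if (m$bout_rate > 0) {
      # locomotion bout: step jump plus fast large tremor for its whole
      # duration -- sustained unpredictable displacement, not one clean
      # discontinuity, is what the AR(2)/PC1 screen keys on
      n_b <- stats::rpois(1, m$bout_rate * p$duration)
      onsets <- sort(stats::runif(n_b, 0, p$duration))
      a_tr <- exp(-p$dt / m$bout_tremor_tau)
      for (b in onsets) {
        th <- stats::runif(1, 0, 2 * pi)
        jump <- c(cos(th), sin(th)) * m$bout_jump
        act <- which(tgrid >= b & tgrid < b + m$bout_duration)
        if (!length(act)) next
        for (d in 1:2) {
          trem <- stats::filter(stats::rnorm(length(act), 0,
                                             m$bout_jump * sqrt(1 - a_tr^2)),
                                a_tr, method = "recursive")
          motion[act, d] <- motion[act, d] + jump[d] + as.numeric(trem)
        }
        if (m$bout_dim > 0) {
          # stride-locked axial defocus: running footfalls (~9 Hz) modulate
          # focus; sampled at 20-60 Hz scan rates this oscillation
          # decorrelates scan-to-scan -- the fast synchronous distortion
          # the AR(2)/PC1 screen flags
          ph <- stats::runif(1, 0, 2 * pi)
          osc <- 0.5 + 0.15 * sin(2 * pi * m$bout_freq * tgrid[act] + ph) +
            0.35 * stats::rnorm(length(act))
          dimming[act] <- pmax(dimming[act] - m$bout_dim * pmin(pmax(osc, 0), 1),
                               0.05)
        }
      }
    }

    scene <- list(params = p,
                  cells = data.frame(id = seq_len(p$n_cells),
                                     x = centers[, 1][seq_len(p$n_cells)],
                                     y = centers[, 2][seq_len(p$n_cells)],
                                     radius = radii[seq_len(p$n_cells)],
                                     brightness = bright[seq_len(p$n_cells)],
                                     responsive = responsive),
                  cell_imgs = imgs, cyto_masks = cyto, nucleus_masks = nucl,
                  spikes = spikes, stim_times = stim_times,
                  tgrid = tgrid, cal = cal, np_t = np_t, np_field = np_field,
                  motion = motion, dimming = dimming, duration = p$duration)
    class(scene) <- "sls_scene"
    scene
  })
}

#' Evaluate scene intensity at arbitrary pixels and times
#'
#' The noiseless intensity model I(x, y, t): baseline offset plus
#' motion-displaced cell donuts modulated by their calcium signals plus the
#' neuropil field times its temporal signal. Coordinates are 0-based pixel
#' centers (x = column, y = row); sub-pixel motion is applied by bilinear
#' interpolation.
#'
#' @param scene an `sls_scene`.
#' @param x,y,t equal-length numeric vectors.
#' @return non-negative intensity vector.
#' @export
scene_eval <- function(scene, x, y, t) {
  stopifnot(inherits(scene, "sls_scene"))
  p <- scene$params
  n <- length(x)
  stopifnot(length(y) == n, length(t) == n)
  mx <- stats::approx(scene$tgrid, scene$motion[, 1], t, rule = 2)$y / p$pixel_size
  my <- stats::approx(scene$tgrid, scene$motion[, 2], t, rule = 2)$y / p$pixel_size
  xs <- x + mx; ys <- y + my
  out <- rep(p$baseline_offset, n)
  for (i in seq_len(p$n_cells)) {
    im <- scene$cell_imgs[[i]]
    sel <- which(xs >= im$x0 & xs <= im$x1 & ys >= im$y0 & ys <= im$y1)
    if (!length(sel)) next
    wc <- bilinear_sample(im$img_cyto, xs[sel] - im$x0, ys[sel] - im$y0)
    wn <- bilinear_sample(im$img_nuc, xs[sel] - im$x0, ys[sel] - im$y0)
    calv <- stats::approx(scene$tgrid, scene$cal[, i], t[sel], rule = 2)$y
    out[sel] <- out[sel] + wc * (1 + calv) +
      wn * (1 + p$nucleus_response * calv)
  }
  if (p$neuropil_gain > 0) {
    npw <- bilinear_sample(scene$np_field,
                           pmin(pmax(xs, 0), ncol(scene$np_field) - 1),
                           pmin(pmax(ys, 0), nrow(scene$np_field) - 1))
    npv <- stats::approx(scene$tgrid, scene$np_t, t, rule = 2)$y
    out <- out + npw * (1 + npv)
  }
  dimv <- stats::approx(scene$tgrid, scene$dimming, t, rule = 2)$y
  pmax(out * dimv, 0)
}

#' @export
print.sls_scene <- function(x, ...) {
  p <- x$params
  cat(sprintf("synthetic scene: %dx%d px (%.2f um/px), %d cells, %.0f s, seed %d\n",
              p$fov[1], p$fov[2], p$pixel_size, p$n_cells, p$duration, p$seed))
  cat(sprintf("  spikes/cell (mean): %.1f; stimulus pulses: %d; motion bouts: %s\n",
              if (p$n_cells) mean(lengths(x$spikes)) else 0,
              length(x$stim_times),
              if (p$motion$bout_rate > 0) "on" else "off"))
  invisible(x)
}
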