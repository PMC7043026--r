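# Shared fixtures, built once per test run and cached. All scenes are
# deliberately small so the default suite stays well inside its budget.

.fx <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

small_scene <- function() fx("scene", function() {
  make_scene(scene_params(fov = c(64L, 64L), n_cells = 6L, duration = 60,
                          seed = 5L))
})

small_movie <- function() fx("movie", function() {
  acquire_raster(small_scene(), dwell = 1 / (64 * 64), n_frames = 55)
})

small_selections <- function() fx("selections", function() {
  sc <- small_scene()
  lapply(seq_len(6), function(i)
    select_pixels(small_movie(),
                  cell_box(round(sc$cells$x[i]), round(sc$cells$y[i]),
                           fov = c(64, 64))))
})

# ~25 Hz trajectory over the small scene's selections, surround 2
small_traj <- function() fx("traj", function() {
  sels <- small_selections()
  tj <- build_trajectory(sels, surround_width = 2L, dwell = 4.4e-6,
                         fov = c(64, 64), seed = 2L)
  tj$dwell <- 0.04 / tj$L        # retime to a realistic ~25 Hz scan rate
  tj$scan_period <- tj$L * tj$dwell
  tj
})

small_recording <- function() fx("rec", function() {
  tj <- small_traj()
  acquire_sls(small_scene(), tj, n_scans = floor(55 / tj$scan_period))
})

small_assignment <- function() fx("assign", function() {
  assign_pixel_groups(small_traj(),
                      lapply(small_selections(), function(s) s$selected))
})

# brute-force oracle for the sub-percentile SNR definition
oracle_pixel_snr <- function(x, prob = 0.25) {
  q <- unname(stats::quantile(x, prob, type = 7))
  lo <- x[x < q]
  s <- if (length(lo) >= 2) stats::sd(lo) else NA
  if (is.na(s) || s == 0) {
    lo <- x[x <= q]
    s <- if (length(lo) >= 2) stats::sd(lo) else NA
  }
  if (is.na(s) || s == 0) return(0)
  max(x) / s
}

# exhaustive closed-tour optimum over ROI centroids
oracle_tsp <- function(centers) {
  n <- nrow(centers)
  D <- as.matrix(stats::dist(centers))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- Inf
  for (p in perms(2:n)) {
    ord <- c(1L, p)
    best <- min(best, sum(D[cbind(ord, ord[c(2:n, 1)])]))
  }
  best
}
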