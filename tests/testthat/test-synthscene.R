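test_that("scene parameters are validated", {
  expect_error(scene_params(nucleus_fraction = 1.2), "nucleus_fraction")
  expect_error(scene_params(kinetics = c(rise = -1, decay = 1.8)), "kinetics")
  expect_error(scene_params(duration = 0), "positive")
  expect_error(scene_params(firing_rate = -0.1), "firing_rate")
})

test_that("gcamp_response matches the closed-form kernel peak", {
  kin <- c(rise = 0.18, decay = 1.8)
  tg <- seq(0, 20, by = 1e-3)
  r <- gcamp_response(5, tg, kin)
  t_star <- kin[[1]] * log(1 + kin[[2]] / kin[[1]])
  expect_equal(max(r), 1, tolerance = 1e-5)
  expect_equal(tg[which.max(r)] - 5, t_star, tolerance = 2e-3)
  # superposition: two far-apart spikes give near-identical transients
  r2 <- gcamp_response(c(1, 1 + 10 * kin[[2]]), seq(0, 40, by = 1e-3), kin)
  pks <- sort(r2[slscan:::local_maxima(r2)], decreasing = TRUE)[1:2]
  expect_lt(abs(pks[1] - pks[2]) / pks[1], 0.01)
  expect_identical(gcamp_response(numeric(0), tg), rep(0, length(tg)))
  expect_error(gcamp_response(1, tg, c(0, 1)), "positive")
  expect_error(gcamp_response(c(2, 1), tg), "sorted")
})

test_that("burst spiking preserves the mean firing-rate anchor", {
  p <- scene_params(fov = c(256L, 256L), n_cells = 110L, duration = 100,
                    firing_rate = 0.3, seed = 42L, neuropil_gain = 0)
  sc <- make_scene(p)
  counts <- lengths(sc$spikes)
  # process variance: events ~ Pois(rate/m * dur), sizes 1 + Pois(m - 1)
  m <- p$burst_mean
  var_proc <- (0.3 / m * 100) * ((m - 1) + m^2)
  se <- sqrt(var_proc / length(counts))
  expect_lt(abs(mean(counts) - 30), 3.5 * se)
  expect_true(all(vapply(sc$spikes, function(s)
    !length(s) || (!is.unsorted(s) && all(s >= 0 & s <= 100)), logical(1))))
})

test_that("air-puff protocol yields 16 onsets with the documented timing", {
  p <- scene_params(stimulus = list(enabled = TRUE))
  st <- slscan:::stimulus_onsets(p$stimulus)
  expect_length(st, 16)
  by_train <- matrix(sort(st), nrow = 4)
  expect_equal(unique(round(diff(by_train[, 1]), 10)), 0.4)  # 200 ms on, duty 0.5
  expect_equal(unique(round(diff(by_train[1, ]), 10)), 2)    # 4 trains at 0.5 Hz
})

test_that("an empty scene is constant up to noise and masks are disjoint", {
  p0 <- scene_params(fov = c(32L, 32L), n_cells = 0L, duration = 2,
                     neuropil_gain = 0, motion = list(jitter_sd = 0),
                     seed = 1L)
  sc0 <- make_scene(p0)
  mv0 <- acquire_raster(sc0, dwell = 1 / (32 * 32 * 4), n_frames = 6,
                        noise = FALSE)
  expect_true(all(apply(mv0$data, c(1, 2), stats::sd) == 0))
  # dense placement fails loudly
  expect_error(make_scene(scene_params(fov = c(32L, 32L), n_cells = 30L,
                                       duration = 1)), "density")
  sc <- small_scene()
  keys <- unlist(lapply(seq_len(6), function(i) {
    px <- rbind(sc$cyto_masks[[i]], sc$nucleus_masks[[i]])
    paste(px[, "x"], px[, "y"])
  }))
  expect_false(any(duplicated(keys)))
})

test_that("raster acquisition follows the dwell-time clock", {
  p <- scene_params(fov = c(128L, 128L), n_cells = 0L, duration = 1,
                    neuropil_gain = 0, seed = 1L)
  sc <- make_scene(p)
  mv <- acquire_raster(sc, dwell = 4.4e-6, n_frames = 10, noise = FALSE)
  expect_equal(mv$frame_period, 128 * 128 * 4.4e-6)  # 72.09 ms
  expect_equal(round(mv$frame_period * 1000, 2), 72.09)
  expect_error(acquire_raster(sc, dwell = 4.4e-6, n_frames = 100000),
               "duration")
})

test_that("noiseless static acquisition is constant and energy-consistent", {
  p <- scene_params(fov = c(48L, 48L), n_cells = 3L, duration = 5,
                    firing_rate = 0, neuropil_gain = 0,
                    motion = list(jitter_sd = 0), seed = 8L)
  sc <- make_scene(p)
  mv <- acquire_raster(sc, dwell = 1 / (48 * 48 * 4), n_frames = 8,
                       noise = FALSE)
  expect_true(all(mv$data == mv$data[, , rep(1, 8)]))
  # energy check: recorded mask sum equals the analytic intensity at the
  # same sample times
  px <- sc$cyto_masks[[1]]
  toff <- (px[, "y"] * 48 + px[, "x"]) * mv$dwell
  direct <- sum(scene_eval(sc, px[, "x"], px[, "y"], toff))
  recorded <- sum(mv$data[cbind(px[, "y"] + 1, px[, "x"] + 1, 1)])
  expect_equal(recorded, direct, tolerance = 1e-3)
})

test_that("SLS acquisition clock, determinism and static invariance hold", {
  tj <- small_traj()
  expect_equal(tj$scan_period, tj$L * tj$dwell)
  # 10,000 px at 4.4 us -> 22.7 Hz
  expect_equal(round(1 / (10000 * 4.4e-6), 1), 22.7)
  p <- scene_params(fov = c(64L, 64L), n_cells = 6L, duration = 10,
                    firing_rate = 0, neuropil_gain = 0,
                    motion = list(jitter_sd = 0), seed = 5L)
  scs <- make_scene(p)
  rec <- acquire_sls(scs, tj, n_scans = 20, noise = FALSE)
  expect_true(all(rec$data == rec$data[, rep(1, 20)]))
  expect_error(acquire_sls(scs, tj, n_scans = 1e7), "exceed")
  rec_a <- acquire_sls(small_scene(), tj, n_scans = 10)
  rec_b <- acquire_sls(small_scene(), tj, n_scans = 10)
  expect_identical(rec_a$data, rec_b$data)
})

test_that("a spiking cell's mask trace follows its calcium ground truth", {
  # acquisition fidelity is tested without the shared neuropil flicker,
  # which is a (deliberate) separate confound handled by the neuropil
  # correction stage
  sc <- make_scene(scene_params(fov = c(48L, 48L), n_cells = 4L,
                                duration = 60, neuropil_gain = 0,
                                seed = 6L))
  mv <- acquire_raster(sc, dwell = 1 / (48 * 48), n_frames = 55)
  i <- which.max(lengths(sc$spikes))
  tr <- slscan:::movie_mask_trace(mv, sc$cyto_masks[[i]])
  truth <- stats::approx(sc$tgrid, sc$cal[, i],
                         (seq_len(55) - 0.5) * mv$frame_period)$y
  expect_gt(stats::cor(tr, truth), 0.9)
})
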