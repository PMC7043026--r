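test_that("dff matches a brute-force oracle and clips negatives", {
  # frozen 20-sample vector; oracle computed inline
  v <- c(100, 102, 98, 101, 99, 150, 230, 180, 140, 120,
         105, 100, 97, 103, 99, 101, 250, 190, 130, 104)
  q <- unname(stats::quantile(v, 0.25, type = 7))
  mask_o <- v < q
  f0_o <- mean(v[mask_o])
  d <- dff(v)
  expect_equal(d$f0, f0_o)
  expect_equal(d$baseline_mask, mask_o)
  expect_equal(d$dff, pmax((v - f0_o) / f0_o, 0))
  # constant trace
  dc <- dff(rep(7, 30))
  expect_equal(dc$f0, 7)
  expect_true(all(dc$dff == 0))
  expect_error(dff(c(-5, -6, -7, -8, 1, 1)), "F0")
  # known modulation recovered
  g <- 0.5 * gcamp_response(3, seq(0, 30, by = 0.1))
  tr <- 200 * (1 + g)
  dg <- dff(tr)
  expect_lt(max(abs(dg$dff - g)), 0.03)
})

test_that("dff is idempotent for event content", {
  set.seed(1)
  tg <- seq(0, 60, by = 1 / 20)
  tr <- 1000 * (1 + 0.3 * gcamp_response(c(12, 40), tg)) +
    stats::rnorm(length(tg), 0, 10)
  d1 <- dff(tr)
  ev1 <- detect_events(d1, 20)
  d2 <- dff(d1$dff + 1)
  ev2 <- detect_events(d2, 20)
  expect_equal(ev1$t_peak, ev2$t_peak, tolerance = 0.2)
})

test_that("event detection finds real transients and rejects artifacts", {
  set.seed(1)
  tg <- seq(0, 60, by = 1 / 20)
  cal <- gcamp_response(c(10, 30, 45), tg)
  ev <- detect_events(dff(1000 * (1 + 0.2 * cal) +
                            stats::rnorm(length(tg), 0, 8)), 20)
  expect_equal(nrow(ev), 3)
  t_star <- 0.18 * log(1 + 10)
  expect_equal(ev$t_peak, c(10, 30, 45) + t_star, tolerance = 0.15)
  # all-zero series
  z <- structure(list(dff = numeric(100), dff_raw = numeric(100),
                      baseline_mask = rep(TRUE, 100), f0 = 1),
                 class = "sls_dff")
  expect_equal(nrow(detect_events(z, 10)), 0)
  # one-sample artifact rejected by the time-to-peak criterion
  set.seed(3)
  zr <- stats::rnorm(1000, 0, 0.005); zr[500] <- 1
  d3 <- structure(list(dff = pmax(zr, 0), dff_raw = zr,
                       baseline_mask = zr < stats::quantile(zr, 0.25), f0 = 1),
                  class = "sls_dff")
  expect_equal(nrow(detect_events(d3, 100)), 0)
  # unresolvable kinetics window disables criterion (iii) with a warning
  expect_warning(detect_events(d3, 0.5), "disabled")
})

test_that("event size classes split at the amplitude median", {
  ev <- data.frame(roi = 1, t_peak = 1:4, amplitude = c(1, 2, 3, 4),
                   i_peak = 1:4)
  cl <- classify_event_size(ev)
  expect_equal(cl$size, c("small", "small", "large", "large"))
  expect_warning(one <- classify_event_size(ev[1, ]), "2 events")
  expect_true(is.na(one$size))
  tied <- classify_event_size(data.frame(roi = 1, t_peak = 1:3,
                                         amplitude = c(2, 2, 2), i_peak = 1:3))
  expect_true(all(tied$size == "small"))
})

test_that("series SNR scales inversely with injected noise", {
  set.seed(5)
  tg <- seq(0, 40, by = 1 / 20)
  shape <- 0.8 * gcamp_response(10, tg)
  snr_at <- function(sigma) {
    tr <- 500 * (1 + shape) + stats::rnorm(length(tg), 0, sigma)
    series_snr(dff(tr))
  }
  s1 <- mean(vapply(1:5, function(i) snr_at(5), numeric(1)))
  s2 <- mean(vapply(1:5, function(i) snr_at(10), numeric(1)))
  expect_gt(s1 / s2, 1.5)
  expect_lt(s1 / s2, 2.7)
  const <- structure(list(dff = rep(0, 50), dff_raw = rep(0, 50),
                          baseline_mask = rep(TRUE, 50), f0 = 1),
                     class = "sls_dff")
  expect_error(series_snr(const), "standard deviation")
})

test_that("evoked responsiveness honors quiet baselines and windows", {
  ev <- data.frame(roi = c(1, 1, 2), t_peak = c(20.5, 50, 23), amplitude = 1,
                   i_peak = 1)
  res <- evoked_responsiveness(ev, stim_times = c(20, 40), rois = 1:3)
  expect_true(res$responsive[res$roi == 1])    # event at stim + 0.5
  expect_false(res$responsive[res$roi == 2])   # event only at stim + 3
  expect_true(is.na(res$responsive[res$roi == 3]) ||
                res$responsive[res$roi == 3] == FALSE)
  # a stimulus inside a preceding event's 7-s window is invalid
  ev2 <- data.frame(roi = 1, t_peak = c(18, 20.5), amplitude = 1, i_peak = 1)
  res2 <- evoked_responsiveness(ev2, stim_times = 20, rois = 1)
  expect_equal(res2$n_valid, 0)
  expect_true(is.na(res2$responsive))
})

test_that("AP detection, isolation and accuracy behave as documented", {
  set.seed(4)
  fs <- 10000; n <- 20 * fs
  eph <- stats::rnorm(n, 0, 1)
  truth <- c(5, 5.2, 9, 14.5)
  for (t in truth) {
    i <- round(t * fs)
    eph[i:(i + 10)] <- eph[i:(i + 10)] + 30 * exp(-(0:10) / 3)
  }
  sp <- detect_aps(eph, fs)
  expect_true(all(vapply(truth, function(t) any(abs(sp - t) < 0.005),
                         logical(1))))  # 5x-threshold spikes all recovered
  iso <- isolated_aps(sp)
  expect_true(all(abs(iso - c(9, 14.5)) < 0.005))
  # burst of 3 close spikes -> none isolated; single spike -> isolated
  expect_length(isolated_aps(c(1, 1.05, 1.1)), 0)
  expect_equal(isolated_aps(5), 5)
  expect_error(detect_aps(eph[1:100], fs), "quiet")
  expect_error(detect_aps(eph, 500), "1 kHz")
  # accuracy worked cases
  expect_equal(ap_accuracy(c(1, 5), c(1.3, 5.4)), 1)
  expect_equal(ap_accuracy(c(1, 5), numeric(0)), 0)
  expect_equal(ap_accuracy(c(1, 1.1), 1.2), 0.5)  # one event matches once
})

test_that("downsampling reduces rate and pixel counts as asked", {
  rec <- small_recording()
  expect_identical(downsample_temporal(rec, 1)$data, rec$data)
  d2 <- downsample_temporal(rec, 2)
  expect_equal(d2$fs, rec$fs / 2)
  expect_equal(ncol(d2$data), ceiling(ncol(rec$data) / 2))
  mv <- small_movie()
  m2 <- downsample_temporal(mv, 2)
  expect_equal(dim(m2$data)[3], ceiling(dim(mv$data)[3] / 2))
  expect_error(downsample_temporal(rec, 0.5), "integer")
  assign <- small_assignment()
  half <- downsample_spatial(rec, assign, 0.5, seed = 1)
  for (i in seq_len(assign$n_rois)) {
    n0 <- sum(assign$assignment$group == "roi" & assign$assignment$roi == i)
    n1 <- sum(half$assignment$group == "roi" & half$assignment$roi == i)
    expect_equal(n1, max(1, floor(n0 / 2)))
  }
  expect_error(downsample_spatial(rec, assign, 0), "fraction")
})
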