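test_that("non-negative deconvolution reconstructs clean kernel responses", {
  fs <- 20
  tg <- seq(0, 30, by = 1 / fs)
  y <- gcamp_response(10, tg)
  den <- suppressWarnings(denoise_nonneg(y, fs))
  expect_lt(max(abs(den - y)), 0.01)
  expect_identical(denoise_nonneg(numeric(100), fs), numeric(100))
  set.seed(2)
  noise <- stats::rnorm(400, 0, 0.2)   # zero-mean white noise
  den_n <- suppressWarnings(denoise_nonneg(noise, fs))
  expect_lt(sum(den_n^2), 0.1 * sum(noise^2))
})

test_that("binarization thresholds at 3 s.d. of the trace", {
  expect_true(all(binarize_activity(numeric(50))$active == 0))
  tr <- c(rep(0.01, 95), 5, 5, 5, 0.01, 0.01)
  b <- binarize_activity(tr)
  expect_equal(which(b$active[1, ] == 1), 96:98)
  # threshold scales with the injected noise
  set.seed(3)
  lo <- binarize_activity(abs(stats::rnorm(500, 0, 0.1)))
  hi <- binarize_activity(abs(stats::rnorm(500, 0, 10)))
  expect_lt(abs(mean(lo$active) - mean(hi$active)), 0.02)
})

test_that("the coactivity threshold matches a binomial oracle", {
  set.seed(7)
  n_roi <- 20; p <- 0.1; nT <- 600
  m <- matrix(stats::rbinom(n_roi * nT, 1, p), n_roi)
  ks <- coactivity_threshold(m, n_surrogates = 300, seed = 4)
  # oracle: pooled surrogate counts are Binomial(n_roi, ~p); k* is the
  # smallest k with P(X >= k) < 0.05
  phat <- mean(m)
  oracle <- min(which(1 - stats::pbinom(0:n_roi - 1, n_roi, phat) < 0.05)) - 1
  expect_lte(abs(ks - oracle), 1)
  expect_identical(ks, coactivity_threshold(m, n_surrogates = 300, seed = 4))
  expect_error(coactivity_threshold(m[1, , drop = FALSE]), "2 ROIs")
  expect_true(is.na(coactivity_threshold(matrix(0L, 5, 50))))
})

test_that("a planted synchronous frame is flagged with controlled false positives", {
  set.seed(9)
  n_roi <- 15; nT <- 400
  m <- matrix(stats::rbinom(n_roi * nT, 1, 0.05), n_roi)
  m[, 200] <- 1
  ks <- coactivity_threshold(m, n_surrogates = 300, seed = 2)
  ens <- detect_ensembles(m, ks, fs = 10)
  expect_true(200 %in% ens$frames)
  expect_lte((length(ens$frames) - 1) / (nT - 1), 0.05 + 2 * sqrt(0.05 * 0.95 / nT))
  # empty raster -> rate 0
  e0 <- detect_ensembles(matrix(0L, 4, 100), NA_integer_, fs = 10)
  expect_equal(e0$rate, 0)
  expect_length(e0$frames, 0)
})

test_that("event binning starts at t = 0 and ORs events within bins", {
  ev <- data.frame(roi = c(1, 1, 2), t_peak = c(0.1, 0.3, 2.4),
                   amplitude = 1, i_peak = 1)
  r <- bin_raster(ev, duration = 3, bin = 0.5)
  expect_equal(dim(r$active), c(2, 6))
  expect_equal(r$active[1, ], c(1L, 0L, 0L, 0L, 0L, 0L))  # two events, one bin
  expect_equal(r$active[2, ], c(0L, 0L, 0L, 0L, 1L, 0L))
  expect_equal(r$fs, 2)
})

test_that("NMF attains exact rank, monotone VAF, and seeded determinism", {
  set.seed(11)
  F1 <- outer(abs(stats::rnorm(8)) + 0.1, abs(stats::rnorm(60)) + 0.1)
  nm <- nmf_decompose(F1, 1, seed = 3)
  expect_equal(nm$vaf, 100, tolerance = 1e-6)
  Fm <- outer(abs(stats::rnorm(8)), abs(stats::rnorm(60))) +
    outer(abs(stats::rnorm(8)), abs(stats::rnorm(60)))
  v <- vapply(c(1, 2, 4, 8), function(k)
    nmf_decompose(Fm, k, seed = 3, maxit = 1000, n_restarts = 8)$vaf,
    numeric(1))
  expect_true(all(diff(v) >= -0.01))
  expect_equal(nmf_decompose(Fm, 2, seed = 5)$M,
               nmf_decompose(Fm, 2, seed = 5)$M)
  expect_error(nmf_decompose(Fm, 9, seed = 1), "k must")
  expect_error(nmf_decompose(-Fm, 2), "non-negative")
})

test_that("VAF and sparseness match their closed forms", {
  F1 <- matrix(1:6, 2)
  M <- matrix(c(1, 2), 2); A <- matrix(c(1, 1, 1), 1)
  E <- F1 - M %*% A
  expect_equal(vaf(F1, M, A), 100 * (1 - sum(E^2) / sum(F1^2)))
  expect_equal(vaf(F1, F1, diag(3)), 100)                       # E = 0
  expect_equal(vaf(F1, matrix(0, 2, 1), matrix(0, 1, 3)), 0)    # M A = 0
  expect_error(vaf(matrix(0, 2, 2), M, A), "all-zero")
  expect_equal(sparseness(c(0, 0, 0.7, 0)), 1)
  expect_equal(sparseness(rep(2, 8)), 1 / 8)
  expect_equal(sparseness(c(3, 4)), 25 / 49)
  expect_equal(sparseness(c(3, 4) * 17), 25 / 49)  # scale invariance
  expect_error(sparseness(c(0, 0)), "all-zero")
  expect_error(sparseness(c(-1, 2)), "non-negative")
})

test_that("stimulus decoding is calibrated on null and separable data", {
  set.seed(13)
  n <- 240
  labels <- rep(c(0, 1), each = n / 2)[sample.int(n)]
  null_act <- matrix(stats::rnorm(10 * n), 10)
  dn <- decode_stimulus(null_act, labels, seed = 1)
  expect_lt(abs(dn$above_chance), 3 * sqrt(0.25 / (n / 2)) + 0.05)
  sep_act <- null_act * 0.1 + outer(seq(0.5, 1.5, length.out = 10), labels * 4)
  ds <- decode_stimulus(sep_act, labels, seed = 1)
  expect_gt(ds$accuracy, 0.95)
  expect_gt(ds$above_chance, 0.3)
  expect_error(decode_stimulus(null_act, rep(1, n)), "single class")
})

test_that("the decoding inclusion rule counts responsive ROIs", {
  ev <- data.frame(roi = c(1, 1, 2), t_peak = c(10.5, 20.5, 10.5),
                   amplitude = 1, i_peak = 1)
  expect_true(decoding_inclusion(ev, c(10, 20), rois = 1:2))
  expect_false(decoding_inclusion(ev, c(10, 20), rois = 1:5))
})
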