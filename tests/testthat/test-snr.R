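test_that("pixel SNR matches a brute-force sub-percentile oracle", {
  # degenerate printed vector: baseline is all-equal, so the fallback and
  # the zero-noise rule both apply
  v <- c(1, 1, 1, 2, 1, 1, 1, 9, 1, 3, 1, 1)
  expect_equal(oracle_pixel_snr(v), 0)
  set.seed(71)
  arr <- array(stats::rpois(10 * 8 * 30, 40) + stats::rnorm(2400, 0, 3),
               c(10, 8, 30))
  sm <- suppressWarnings(pixel_snr_map(arr))
  expect_equal(dim(sm$snr), c(10, 8))
  for (idx in list(c(1, 1), c(5, 3), c(10, 8))) {
    expect_equal(sm$snr[idx[1], idx[2]],
                 oracle_pixel_snr(arr[idx[1], idx[2], ]))
  }
  expect_true(all(sm$snr >= 0))
  # constant pixel -> 0 with a warning
  arr[2, 2, ] <- 7
  expect_warning(sm2 <- pixel_snr_map(arr), "degenerate")
  expect_equal(sm2$snr[2, 2], 0)
  expect_error(pixel_snr_map(arr, c(1, 5)), "8 frames")
})

test_that("pixel SNR is invariant to positive rescaling", {
  set.seed(3)
  arr <- array(stats::runif(8 * 8 * 20, 10, 50), c(8, 8, 20))
  base <- suppressWarnings(pixel_snr_map(arr)$snr)
  for (a in c(0.5, 2)) {
    scaled <- suppressWarnings(pixel_snr_map(arr * a)$snr)
    expect_equal(scaled, base, tolerance = 1e-10)
  }
})

test_that("roi_trace_snr reduces to the pixel value and averages noise", {
  set.seed(4)
  arr <- array(stats::rnorm(6 * 6 * 40, 100, 10), c(6, 6, 40))
  px1 <- cbind(x = 2L, y = 3L)
  expect_equal(roi_trace_snr(arr, px1),
               oracle_pixel_snr(arr[4, 3, ]))
  # k i.i.d. replicas of one signal: SNR grows roughly like sqrt(k)
  base_tr <- 100 + 20 * gcamp_response(5, seq(0, 20, by = 0.5))
  k <- 16
  arr2 <- array(0, c(1, k, length(base_tr)))
  for (j in seq_len(k)) arr2[1, j, ] <- base_tr + stats::rnorm(length(base_tr), 0, 15)
  s1 <- mean(vapply(seq_len(k), function(j)
    roi_trace_snr(arr2, cbind(x = j - 1L, y = 0L)), numeric(1)))
  sk <- roi_trace_snr(arr2, cbind(x = 0:(k - 1), y = rep(0L, k)))
  expect_gt(sk / s1, sqrt(k) * 0.5)
  expect_lt(sk / s1, sqrt(k) * 2)
  # all-constant set -> 0 via fallback
  arr3 <- array(5, c(2, 2, 10))
  expect_equal(roi_trace_snr(arr3, cbind(x = 0:1, y = c(0L, 1L))), 0)
})

test_that("select_pixels finds a bright pixel and respects the box", {
  set.seed(9)
  arr <- array(stats::rnorm(15 * 15 * 40, 100, 5), c(15, 15, 40))
  arr[8, 8, ] <- 100 + 60 * gcamp_response(4, seq(0, 20, length.out = 40))
  box <- cell_box(7, 7, side = 9, fov = c(15, 15))
  sel <- select_pixels(arr, box)
  expect_equal(unname(sel$candidates[1, ]), c(7, 7))  # brightest first
  expect_lt(sel$n_star, 10)
  bp <- slscan:::box_pixels(box)
  expect_true(all(paste(sel$selected[, "x"], sel$selected[, "y"]) %in%
                    paste(bp[, "x"], bp[, "y"])))
  # degenerate box
  flat <- array(3, c(9, 9, 10))
  expect_warning(s0 <- select_pixels(flat, cell_box(4, 4, side = 5, fov = c(9, 9))),
                 "degenerate")
  expect_equal(nrow(s0$selected), 0)
})

test_that("both selection rules are available and consistent", {
  set.seed(10)
  arr <- array(stats::rnorm(11 * 11 * 40, 100, 8), c(11, 11, 40))
  arr[5:7, 5:7, ] <- arr[5:7, 5:7, ] +
    rep(80 * gcamp_response(3, seq(0, 20, length.out = 40)), each = 9)
  box <- cell_box(5, 5, side = 11, fov = c(11, 11))
  s_top <- select_pixels(arr, box, rule = "topn")
  s_thr <- select_pixels(arr, box, rule = "threshold")
  expect_equal(nrow(s_top$selected), s_top$n_star)
  expect_true(all(s_thr$pixel_snr[seq_len(nrow(s_thr$selected))] >= 0))
  expect_identical(s_top$curve, s_thr$curve)
})

test_that("colocalization maps membership counts to the documented percentages", {
  m <- function(...) matrix(c(...), 2, 2)
  masks <- list(m(1, 0, 1, 0), m(1, 0, 1, 0), m(1, 0, 1, 0), m(1, 1, 0, 0))
  cl <- colocalization(masks)
  expect_equal(cl[1, 1], 100)  # in all 4
  expect_equal(cl[1, 2], 75)   # in 3 of 4
  expect_equal(cl[2, 1], 0)    # in 1 of 4
  expect_true(is.na(cl[2, 2])) # never selected
  expect_error(colocalization(masks[1:3]), "exactly 4")
  masks[[2]] <- matrix(0, 3, 3)
  expect_error(colocalization(masks), "mismatched")
})

test_that("donut cells have brighter-SNR cytoplasm than nucleus", {
  sc <- small_scene()
  sm <- suppressWarnings(pixel_snr_map(small_movie()))
  ratio <- vapply(seq_len(6), function(i) {
    cy <- sc$cyto_masks[[i]]; nu <- sc$nucleus_masks[[i]]
    mean(sm$snr[cbind(cy[, "y"] + 1, cy[, "x"] + 1)]) /
      mean(sm$snr[cbind(nu[, "y"] + 1, nu[, "x"] + 1)])
  }, numeric(1))
  expect_gt(mean(ratio > 1), 0.8)
})
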