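px_set <- function(x, y) cbind(x = as.integer(x), y = as.integer(y))

test_that("the GA tour matches the exhaustive optimum on small instances", {
  corners <- list(px_set(0, 0), px_set(10, 0), px_set(10, 10), px_set(0, 10))
  ga <- order_cells_ga(corners, seed = 1)
  expect_equal(ga$cost, 40)
  set.seed(2)
  for (rep in 1:3) {
    sets <- lapply(1:5, function(i) px_set(stats::runif(1, 0, 50),
                                           stats::runif(1, 0, 50)))
    cen <- t(vapply(sets, function(p) c(p[1, 1], p[1, 2]), numeric(2)))
    ga <- order_cells_ga(sets, seed = rep)
    expect_equal(ga$cost, oracle_tsp(cen), tolerance = 1e-9)
  }
  expect_equal(order_cells_ga(list(px_set(1, 1)), seed = 1)$order, 1L)
})

test_that("the GA beats random orders, is monotone and deterministic", {
  set.seed(5)
  sets <- lapply(1:30, function(i) px_set(stats::runif(1, 0, 100),
                                          stats::runif(1, 0, 100)))
  gp <- list(pop_size = 100L, max_generations = 400L, stagnation = 80L)
  ga1 <- order_cells_ga(sets, gp, seed = 7)
  ga2 <- order_cells_ga(sets, gp, seed = 7)
  expect_identical(ga1$order, ga2$order)
  expect_true(all(diff(ga1$history) <= 0))
  D <- as.matrix(stats::dist(t(vapply(sets, function(p)
    c(p[1, 1], p[1, 2]), numeric(2)))))
  tour_cost <- function(ord) { n <- length(ord); sum(D[cbind(ord, ord[c(2:n, 1)])]) }
  expect_lte(ga1$cost, tour_cost(seq_len(30)))
  set.seed(11)
  rnd <- replicate(1000, tour_cost(sample.int(30)))
  expect_lte(ga1$cost, stats::median(rnd))
})

test_that("within-ROI ordering chains nearest neighbors", {
  expect_equal(order_pixels_within_roi(px_set(3, 4), c(0, 0)),
               px_set(3, 4))
  block <- px_set(c(0, 1, 0, 1), c(0, 0, 1, 1))
  path <- order_pixels_within_roi(block, c(-1, -1))
  steps <- sqrt(diff(path[, "x"])^2 + diff(path[, "y"])^2)
  expect_equal(length(steps), 3)
  expect_true(all(steps == 1))
  line <- px_set(c(4, 2, 0, 6), c(0, 0, 0, 0))
  p2 <- order_pixels_within_roi(line, c(0, 0))
  expect_equal(p2[, "x"], c(0, 2, 4, 6))  # monotone sweep
})

test_that("surround dilation uses chessboard distance and resolves overlaps", {
  sets <- list(px_set(5, 5))
  expect_identical(add_surround(sets, 0, c(20, 20))[[1]]$roi, sets[[1]])
  sw <- add_surround(sets, 1, c(20, 20))
  expect_equal(nrow(sw[[1]]$surround), 8)   # 3x3 block minus the pixel
  sw3 <- add_surround(sets, 3, c(20, 20))
  expect_equal(nrow(sw3[[1]]$surround), 48) # 7x7 minus the pixel
  # two adjacent ROIs: no pixel carries two labels
  two <- list(px_set(5, 5), px_set(8, 5))
  sw2 <- add_surround(two, 2, c(20, 20))
  all_px <- rbind(sw2[[1]]$roi, sw2[[1]]$surround,
                  sw2[[2]]$roi, sw2[[2]]$surround)
  expect_false(any(duplicated(paste(all_px[, "x"], all_px[, "y"]))))
  expect_warning(add_surround(list(px_set(0, 0)), 2, c(10, 10)), "clipped")
  expect_error(add_surround(sets, 5, c(20, 20)), "width")
})

test_that("trajectories visit every selected pixel once, contiguously", {
  sels <- list(px_set(c(3, 4, 3), c(3, 3, 4)),
               px_set(c(15, 16), c(15, 15)),
               px_set(c(3, 4), c(15, 15)))
  tj <- build_trajectory(sels, surround_width = 1, dwell = 4.4e-6,
                         fov = c(24, 24), seed = 1)
  expect_true(tj$closed)
  expect_equal(tj$scan_period, tj$L * tj$dwell)
  sel_keys <- unlist(lapply(sels, function(p) paste(p[, "x"], p[, "y"])))
  traj_roi <- tj$pixels[tj$pixels$label == "roi", ]
  expect_setequal(paste(traj_roi$x, traj_roi$y), sel_keys)
  expect_false(any(duplicated(paste(traj_roi$x, traj_roi$y))))
  # each ROI's pixels occupy one contiguous stretch
  for (id in stats::na.omit(unique(tj$pixels$roi))) {
    w <- which(tj$pixels$roi == id)
    expect_equal(w, seq(min(w), max(w)))
  }
  expect_error(build_trajectory(sels, 1, 4.4e-6, fov = c(24, 24),
                                max_length = 10),
               "Hz")
})

test_that("a reference patch is appended in boustrophedon order", {
  sels <- list(px_set(c(3, 4), c(3, 3)))
  tj <- build_trajectory(sels, 0, 4.4e-6, fov = c(24, 24),
                         reference_patch = list(x = 18L, y = 2L, side = 3L))
  rp <- tj$pixels[tj$pixels$label == "reference_patch", ]
  expect_equal(nrow(rp), 9)
  expect_equal(rp$x, c(18, 19, 20, 20, 19, 18, 18, 19, 20))
  expect_equal(rp$y, rep(2:4, each = 3))
})

test_that("trajectory files round-trip losslessly in XML and JSON", {
  tj <- small_traj()
  for (ext in c("xml", "json")) {
    f <- withr::local_tempfile(fileext = paste0(".", ext))
    write_trajectory(tj, f)
    back <- read_trajectory(f)
    expect_equal(back$pixels$x, tj$pixels$x)
    expect_equal(back$pixels$y, tj$pixels$y)
    expect_equal(back$pixels$label, tj$pixels$label)
    expect_equal(back$pixels$roi, as.integer(tj$pixels$roi))
    expect_equal(back$dwell, tj$dwell)
  }
  # hand-written 3-pixel file parses to the expected coordinates
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(c('<trajectory dwell="4.4e-06" surround="0" ny="8" nx="8">',
               '<px x="1" y="2" label="roi" roi="1"/>',
               '<px x="2" y="2" label="roi" roi="1"/>',
               '<px x="3" y="3" label="transit"/>',
               '</trajectory>'), f)
  tr <- read_trajectory(f)
  expect_equal(tr$pixels$x, 1:3)
  expect_equal(tr$pixels$y, c(2, 2, 3))
  expect_equal(tr$L, 3)
  # malformed input fails with a located parse error
  f2 <- withr::local_tempfile(fileext = ".xml")
  writeLines(c('<trajectory dwell="1" surround="0" ny="8" nx="8">',
               '<px y="2" label="roi"/>', '</trajectory>'), f2)
  expect_error(read_trajectory(f2), "pixel element 1")
  expect_error(read_trajectory("/nonexistent/t.xml"), "no such")
})

test_that("scan duration grows linearly with cell count, steeper with surround", {
  set.seed(14)
  centers <- cbind(stats::runif(20, 10, 110), stats::runif(20, 10, 110))
  mk_cell <- function(cx, cy) {
    ang <- stats::runif(12, 0, 2 * pi); rr <- stats::runif(12, 0, 2.5)
    unique(px_set(round(cx + rr * cos(ang)), round(cy + rr * sin(ang))))
  }
  cells <- lapply(seq_len(20), function(i) mk_cell(centers[i, 1], centers[i, 2]))
  gp <- list(pop_size = 60L, max_generations = 150L, stagnation = 40L)
  slope <- numeric(2)
  for (si in 1:2) {
    sw <- c(0L, 2L)[si]
    ns <- seq(2, 20, by = 3)
    dur <- vapply(ns, function(n)
      build_trajectory(cells[seq_len(n)], sw, 4.4e-6, fov = c(128, 128),
                       seed = 3, ga_params = gp)$scan_period, numeric(1))
    fit <- stats::lm(dur ~ ns)
    expect_gt(summary(fit)$r.squared, 0.95)
    slope[si] <- stats::coef(fit)[2]
  }
  expect_gt(slope[2], slope[1])
})
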