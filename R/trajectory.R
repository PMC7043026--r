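# Closed-tour cost over a distance matrix for an ordering.
tour_cost <- function(ord, D) {
  n <- length(ord)
  if (n < 2) return(0)
  sum(D[cbind(ord, ord[c(2:n, 1)])])
}

#' Order cells with a traveling-salesman genetic algorithm
#'
#' Heuristically minimizes the total inter-ROI travel of the closed scan
#' path (including the closing first-last edge) over ROI centroids, using
#' order crossover plus swap/flip mutations. The result is deterministic
#' for a fixed seed and never worse than the input order.
#'
#' @param roi_pixel_sets list of pixel matrices (columns x, y), one per ROI.
#' @param ga_params list(pop_size, max_generations, stagnation, p_mut)
#'   overriding the defaults (200, 2000, 200, 0.3).
#' @param seed RNG seed.
#' @return list(order, cost, history) where `history` is the best cost per
#'   generation (non-increasing).
#' @export
order_cells_ga <- function(roi_pixel_sets, ga_params = list(), seed = 1L) {
  n <- length(roi_pixel_sets)
  if (n < 1) stopf("at least one ROI is required")
  cen <- t(vapply(roi_pixel_sets, function(p)
    c(mean(p[, "x"]), mean(p[, "y"])), numeric(2)))
  D <- as.matrix(stats::dist(cen))
  if (n <= 2)
    return(list(order = seq_len(n), cost = tour_cost(seq_len(n), D),
                history = tour_cost(seq_len(n), D)))
  gp <- utils::modifyList(list(pop_size = 200L, max_generations = 2000L,
                               stagnation = 200L, p_mut = 0.3), ga_params)
  with_seed(seed, {
    pop <- c(list(seq_len(n)),
             replicate(gp$pop_size - 1L, sample.int(n), simplify = FALSE))
    costs <- vapply(pop, tour_cost, numeric(1), D = D)
    best <- which.min(costs)
    best_ord <- pop[[best]]; best_cost <- costs[best]
    history <- best_cost
    stagnant <- 0L
    for (g in seq_len(gp$max_generations)) {
      new_pop <- vector("list", gp$pop_size)
      new_pop[[1]] <- best_ord                       # elitism
      for (k in 2:gp$pop_size) {
        pa <- pop[[sample.int(gp$pop_size, 1)]]
        pb <- pop[[sample.int(gp$pop_size, 1)]]
        # order crossover (OX)
        cut <- sort(sample.int(n, 2))
        child <- integer(n)
        seg <- pa[cut[1]:cut[2]]
        child[cut[1]:cut[2]] <- seg
        child[-(cut[1]:cut[2])] <- pb[!pb %in% seg]
        if (stats::runif(1) < gp$p_mut) {           # swap mutation
          ij <- sample.int(n, 2)
          child[ij] <- child[rev(ij)]
        }
        if (stats::runif(1) < gp$p_mut) {           # 2-opt flip mutation
          ij <- sort(sample.int(n, 2))
          child[ij[1]:ij[2]] <- rev(child[ij[1]:ij[2]])
        }
        new_pop[[k]] <- child
      }
      pop <- new_pop
      costs <- vapply(pop, tour_cost, numeric(1), D = D)
      gen_best <- which.min(costs)
      if (costs[gen_best] < best_cost - 1e-12) {
        best_cost <- costs[gen_best]
        best_ord <- pop[[gen_best]]
        stagnant <- 0L
      } else stagnant <- stagnant + 1L
      history <- c(history, best_cost)
      if (stagnant >= gp$stagnation) break
    }
    list(order = best_ord, cost = best_cost, history = history)
  })
}

#' Greedy nearest-neighbor ordering of pixels inside one ROI
#'
#' Chains pixels starting from the one closest to the entry point, each
#' step moving to the nearest unvisited pixel (Euclidean); ties are broken
#' by row-major order.
#'
#' @param pixels matrix with columns x, y (0-based).
#' @param entry c(x, y) entry point.
#' @param fov_nx FOV width used for the row-major tie-break (default large).
#' @return the reordered pixel matrix.
#' @export
order_pixels_within_roi <- function(pixels, entry, fov_nx = 10000L) {
  n <- nrow(pixels)
  if (n == 0) stopf("empty pixel set")
  rowmaj <- pixels[, "y"] * fov_nx + pixels[, "x"]
  left <- seq_len(n)
  d0 <- (pixels[, "x"] - entry[1])^2 + (pixels[, "y"] - entry[2])^2
  pick <- left[order(d0, rowmaj)[1]]
  path <- pick
  left <- setdiff(left, pick)
  while (length(left)) {
    cur <- pixels[pick, ]
    d <- (pixels[left, "x"] - cur["x"])^2 + (pixels[left, "y"] - cur["y"])^2
    pick <- left[order(d, rowmaj[left])[1]]
    path <- c(path, pick)
    left <- setdiff(left, pick)
  }
  pixels[path, , drop = FALSE]
}

#' Add surround regions to ROI pixel sets
#'
#' Morphological dilation by chessboard (Chebyshev) distance up to `width`
#' pixels. Surround pixels are labeled separately from ROI pixels; a
#' candidate surround pixel claimed by several cells goes to the nearest
#' ROI (Euclidean distance to the ROI's pixels, ties to the lower id), and
#' dilations beyond the FOV are clipped with a warning.
#'
#' @param roi_pixel_sets list of pixel matrices (columns x, y).
#' @param width surround width, one of 0:3.
#' @param fov c(ny, nx).
#' @return list with one element per ROI: list(roi = pixels, surround =
#'   pixels).
#' @export
add_surround <- function(roi_pixel_sets, width, fov) {
  if (!width %in% 0:3) stopf("surround width must be in {0, 1, 2, 3}")
  n <- length(roi_pixel_sets)
  out <- lapply(roi_pixel_sets, function(p)
    list(roi = p, surround = p[0, , drop = FALSE]))
  if (width == 0) return(out)
  occupied <- do.call(rbind, roi_pixel_sets)
  occ_key <- occupied[, "y"] * fov[2] + occupied[, "x"]
  offs <- expand.grid(dx = -width:width, dy = -width:width)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0), ]
  clipped <- FALSE
  cand <- list()
  for (i in seq_len(n)) {
    p <- roi_pixel_sets[[i]]
    sx <- outer(p[, "x"], offs$dx, `+`)
    sy <- outer(p[, "y"], offs$dy, `+`)
    s <- unique(cbind(x = as.vector(sx), y = as.vector(sy)))
    inside <- s[, "x"] >= 0 & s[, "x"] < fov[2] &
      s[, "y"] >= 0 & s[, "y"] < fov[1]
    if (any(!inside)) clipped <- TRUE
    s <- s[inside, , drop = FALSE]
    s <- s[!(s[, "y"] * fov[2] + s[, "x"]) %in% occ_key, , drop = FALSE]
    if (nrow(s))
      cand[[length(cand) + 1L]] <- cbind(s, roi = i)
  }
  if (clipped) warnf("surround dilation clipped at the FOV border")
  if (!length(cand)) return(out)
  cand <- do.call(rbind, cand)
  key <- cand[, "y"] * fov[2] + cand[, "x"]
  # resolve multi-cell claims: nearest ROI, ties to lower id
  dup_keys <- unique(key[duplicated(key)])
  keep <- rep(TRUE, nrow(cand))
  for (k in dup_keys) {
    rows <- which(key == k)
    px <- cand[rows[1], c("x", "y")]
    d <- vapply(cand[rows, "roi"], function(i) {
      p <- roi_pixel_sets[[i]]
      min((p[, "x"] - px["x"])^2 + (p[, "y"] - px["y"])^2)
    }, numeric(1))
    win <- rows[order(d, cand[rows, "roi"])[1]]
    keep[setdiff(rows, win)] <- FALSE
  }
  cand <- cand[keep, , drop = FALSE]
  for (i in seq_len(n)) {
    s <- cand[cand[, "roi"] == i, c("x", "y"), drop = FALSE]
    out[[i]]$surround <- s
  }
  out
}

#' Build a closed SLS trajectory over selected pixels
#'
#' Cells are visited in GA order (the cycle is rotated so the longest
#' inter-ROI edge becomes the closing first-last junction); within each
#' cell the ROI pixels and then its surround pixels are chained by greedy
#' nearest neighbor; straight 8-connected Bresenham transit pixels connect
#' consecutive cells and close the path; an optional square reference
#' patch is appended in boustrophedon order before the closing transit.
#'
#' @param selections list of `sls_roi_selection` objects or raw pixel
#'   matrices (columns x, y).
#' @param surround_width surround size in pixels, 0:3.
#' @param dwell per-pixel dwell time in seconds (default 4.4e-6).
#' @param fov c(ny, nx).
#' @param reference_patch optional list(x, y, side): a square box appended
#'   at the end of the trajectory for independent motion readout.
#' @param max_length trajectory length limit in pixels; exceeding it is an
#'   error naming the implied scan rate.
#' @param seed,ga_params forwarded to [order_cells_ga()].
#' @return object of class `sls_trajectory`: data.frame `pixels`
#'   (x, y, label, roi), `dwell`, `L`, `scan_period`, `surround_width`,
#'   `closed = TRUE`.
#' @export
build_trajectory <- function(selections, surround_width = 1L, dwell = 4.4e-6,
                             fov, reference_patch = NULL,
                             max_length = 250000L, seed = 1L,
                             ga_params = list()) {
  sets <- lapply(selections, function(s)
    if (inherits(s, "sls_roi_selection")) s$selected else s)
  if (!length(sets) || any(vapply(sets, nrow, integer(1)) == 0))
    stopf("every selection must contain at least one pixel")
  n <- length(sets)
  ga <- order_cells_ga(sets, ga_params, seed)
  ord <- ga$order
  # rotate so the longest inter-ROI edge is the closing junction
  if (n > 2) {
    cen <- t(vapply(sets, function(p)
      c(mean(p[, "x"]), mean(p[, "y"])), numeric(2)))
    edges <- vapply(seq_len(n), function(k) {
      a <- ord[k]; b <- ord[if (k == n) 1L else k + 1L]
      sqrt(sum((cen[a, ] - cen[b, ])^2))
    }, numeric(1))
    k <- which.max(edges)
    if (k < n) ord <- ord[c((k + 1L):n, 1L:k)]
  }
  sw <- add_surround(sets[ord], surround_width, fov)
  px <- list(); labels <- character(0); roi_ids <- integer(0)
  entry <- c(0, 0)
  for (k in seq_len(n)) {
    cellpx <- rbind(sw[[k]]$roi, sw[[k]]$surround)
    lab <- c(rep("roi", nrow(sw[[k]]$roi)),
             rep("surround", nrow(sw[[k]]$surround)))
    op <- order_pixels_within_roi(cellpx, entry, fov[2])
    # carry labels through the reordering
    keym <- stats::setNames(lab, paste(cellpx[, "x"], cellpx[, "y"]))
    lab_o <- keym[paste(op[, "x"], op[, "y"])]
    if (k > 1) {
      prev <- px[[length(px)]]
      last <- prev[nrow(prev), ]
      tr <- bresenham(last["x"], last["y"], op[1, "x"], op[1, "y"])
      tr <- tr[-c(1, nrow(tr)), , drop = FALSE]
      if (nrow(tr)) {
        px[[length(px) + 1L]] <- tr
        labels <- c(labels, rep("transit", nrow(tr)))
        roi_ids <- c(roi_ids, rep(NA_integer_, nrow(tr)))
      }
    }
    px[[length(px) + 1L]] <- op
    labels <- c(labels, lab_o)
    roi_ids <- c(roi_ids, rep(ord[k], nrow(op)))
    entry <- op[nrow(op), c("x", "y")]
  }
  all_px <- do.call(rbind, px)
  if (!is.null(reference_patch)) {
    rp <- reference_patch
    xs <- rp$x:(rp$x + rp$side - 1L)
    ys <- rp$y:(rp$y + rp$side - 1L)
    bx <- integer(0); by <- integer(0)
    for (r in seq_along(ys)) {           # boustrophedon rows
      row_x <- if (r %% 2 == 1) xs else rev(xs)
      bx <- c(bx, row_x); by <- c(by, rep(ys[r], length(xs)))
    }
    last <- all_px[nrow(all_px), ]
    tr <- bresenham(last["x"], last["y"], bx[1], by[1])
    tr <- tr[-c(1, nrow(tr)), , drop = FALSE]
    if (nrow(tr)) {
      all_px <- rbind(all_px, tr)
      labels <- c(labels, rep("transit", nrow(tr)))
      roi_ids <- c(roi_ids, rep(NA_integer_, nrow(tr)))
    }
    all_px <- rbind(all_px, cbind(x = bx, y = by))
    labels <- c(labels, rep("reference_patch", length(bx)))
    roi_ids <- c(roi_ids, rep(NA_integer_, length(bx)))
  }
  # closing transit back to the first pixel (closed path, no flyback gap)
  last <- all_px[nrow(all_px), ]
  first <- all_px[1, ]
  if (!all(last == first)) {
    tr <- bresenham(last["x"], last["y"], first["x"], first["y"])
    tr <- tr[-c(1, nrow(tr)), , drop = FALSE]
    if (nrow(tr)) {
      all_px <- rbind(all_px, tr)
      labels <- c(labels, rep("transit", nrow(tr)))
      roi_ids <- c(roi_ids, rep(NA_integer_, nrow(tr)))
    }
  }
  L <- nrow(all_px)
  if (L > max_length)
    stopf("trajectory of %d pixels exceeds max_length %d (implied scan rate %.2f Hz)",
          L, max_length, 1 / (L * dwell))
  structure(list(pixels = data.frame(x = as.integer(all_px[, "x"]),
                                     y = as.integer(all_px[, "y"]),
                                     label = labels, roi = roi_ids,
                                     stringsAsFactors = FALSE),
                 dwell = dwell, L = L, scan_period = L * dwell,
                 surround_width = as.integer(surround_width),
                 cell_order = ord, ga_cost = ga$cost, closed = TRUE,
                 fov = as.integer(fov),
                 reference_patch = reference_patch),
            class = "sls_trajectory")
}

#' @export
print.sls_trajectory <- function(x, ...) {
  tab <- table(x$pixels$label)
  cat(sprintf("SLS trajectory: L = %d px, scan period %.4g s (%.2f Hz), surround %d\n",
              x$L, x$scan_period, 1 / x$scan_period, x$surround_width))
  cat("  ", paste(names(tab), tab, sep = ": ", collapse = ", "), "\n")
  invisible(x)
}

#' Serialize and parse trajectories (XML or JSON)
#'
#' The XML dialect stores one element per pixel with attributes x, y,
#' label and roi plus trajectory-level dwell and fov; JSON mirrors the
#' same fields. Round-trips are lossless.
#'
#' @param traj an `sls_trajectory`.
#' @param path output file; format chosen by extension (.xml or .json).
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns the `sls_trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "sls_trajectory"))
  if (traj$L == 0) stopf("refusing to write an empty trajectory")
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- list(dwell = traj$dwell, surround_width = traj$surround_width,
                fov = traj$fov, pixels = traj$pixels)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    doc <- xml2::xml_new_root("trajectory",
                              dwell = format(traj$dwell, digits = 17),
                              surround = traj$surround_width,
                              ny = traj$fov[1], nx = traj$fov[2])
    p <- traj$pixels
    for (i in seq_len(nrow(p))) {
      nd <- xml2::xml_add_child(doc, "px", x = p$x[i], y = p$y[i],
                                label = p$label[i])
      if (!is.na(p$roi[i])) xml2::xml_set_attr(nd, "roi", p$roi[i])
    }
    xml2::write_xml(doc, path)
  }
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stopf("no such trajectory file: %s", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    p <- as.data.frame(obj$pixels)
    dwell <- obj$dwell; fov <- as.integer(obj$fov)
    sw <- as.integer(obj$surround_width)
  } else {
    doc <- tryCatch(xml2::read_xml(path), error = function(e)
      stopf("malformed trajectory XML (%s): %s", path, conditionMessage(e)))
    root <- xml2::xml_name(doc)
    if (root != "trajectory") stopf("line 1: expected <trajectory> root, got <%s>", root)
    dwell <- as.numeric(xml2::xml_attr(doc, "dwell"))
    sw <- as.integer(xml2::xml_attr(doc, "surround"))
    fov <- c(as.integer(xml2::xml_attr(doc, "ny")),
             as.integer(xml2::xml_attr(doc, "nx")))
    kids <- xml2::xml_find_all(doc, "px")
    if (!length(kids)) stopf("trajectory file contains no pixels")
    p <- data.frame(x = as.integer(xml2::xml_attr(kids, "x")),
                    y = as.integer(xml2::xml_attr(kids, "y")),
                    label = xml2::xml_attr(kids, "label"),
                    roi = suppressWarnings(as.integer(xml2::xml_attr(kids, "roi"))),
                    stringsAsFactors = FALSE)
    bad <- which(is.na(p$x) | is.na(p$y) | is.na(p$label))
    if (length(bad))
      stopf("parse error at pixel element %d: missing x/y/label", bad[1])
  }
  if (!nrow(p)) stopf("trajectory file contains no pixels")
  p$roi <- as.integer(p$roi)
  structure(list(pixels = p, dwell = dwell, L = nrow(p),
                 scan_period = nrow(p) * dwell, surround_width = sw,
                 closed = TRUE, fov = fov, reference_patch = NULL),
            class = "sls_trajectory")
}
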