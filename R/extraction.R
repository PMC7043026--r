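#' Assign trajectory pixels to cellular compartments
#'
#' Each trajectory pixel is classified by its Euclidean distance d to the
#' nearest pixel of each reference ROI (the segmentation of the raster
#' series that built the trajectory): d < 1 -> `roi`; 2 < d < 4 ->
#' `local_np` of that ROI; d > 4 from all ROIs -> `global_np`. Pixels in
#' the gaps (1 <= d <= 2 or d = 4) or claimed by more than one ROI are
#' `skipped`, honoring the strict inequalities literally. Reference-patch
#' pixels keep their own group.
#'
#' @param traj an `sls_trajectory`.
#' @param reference_rois list of pixel matrices (columns x, y), one per
#'   ROI, from the reference segmentation.
#' @return object of class `sls_pixel_assignment`: data.frame with columns
#'   `group` ("roi", "local_np", "global_np", "reference_patch",
#'   "skipped") and `roi` (id or NA), one row per trajectory pixel.
#' @export
assign_pixel_groups <- function(traj, reference_rois) {
  stopifnot(inherits(traj, "sls_trajectory"))
  n_roi <- length(reference_rois)
  if (!n_roi) stopf("at least one reference ROI is required")
  labeled <- unique(stats::na.omit(traj$pixels$roi))
  if (any(labeled > n_roi))
    stopf("trajectory references ROI %d but only %d reference ROIs supplied",
          max(labeled), n_roi)
  p <- traj$pixels
  L <- nrow(p)
  # distance from every trajectory pixel to each ROI's nearest pixel
  dmat <- matrix(Inf, L, n_roi)
  for (i in seq_len(n_roi)) {
    rp <- reference_rois[[i]]
    d2 <- outer(p$x, rp[, "x"], `-`)^2 + outer(p$y, rp[, "y"], `-`)^2
    dmat[, i] <- sqrt(apply(d2, 1, min))
  }
  group <- rep("skipped", L)
  roi <- rep(NA_integer_, L)
  in_roi <- dmat < 1
  in_loc <- dmat > 2 & dmat < 4
  n_in_roi <- rowSums(in_roi)
  n_in_loc <- rowSums(in_loc)
  for (k in seq_len(L)) {
    if (p$label[k] == "reference_patch") {
      group[k] <- "reference_patch"
    } else if (n_in_roi[k] == 1 && n_in_loc[k] == 0) {
      group[k] <- "roi"; roi[k] <- which(in_roi[k, ])
    } else if (n_in_roi[k] == 0 && n_in_loc[k] == 1) {
      group[k] <- "local_np"; roi[k] <- which(in_loc[k, ])
    } else if (n_in_roi[k] == 0 && n_in_loc[k] == 0 && all(dmat[k, ] > 4)) {
      group[k] <- "global_np"
    } # else: boundary gap or multi-group conflict -> skipped
  }
  structure(list(assignment = data.frame(group = group, roi = roi,
                                         stringsAsFactors = FALSE),
                 n_rois = n_roi),
            class = "sls_pixel_assignment")
}

#' Extract per-compartment traces from an SLS recording
#'
#' Per-scan means over each group's pixels: one raw trace per ROI, one
#' local-neuropil trace per ROI, the global-neuropil pixel raster, and the
#' reference-patch samples reshaped into a mini-movie.
#'
#' @param rec an `sls_recording`.
#' @param assign an `sls_pixel_assignment` for the same trajectory.
#' @return object of class `sls_traces`: list(roi = matrix ROIs x scans,
#'   local_np = matrix ROIs x scans (NA rows when a ROI has no local
#'   pixels), global_np = pixel x scan matrix, patch = array mini-movie or
#'   NULL, fs, assignment, rec).
#' @export
extract_traces <- function(rec, assign) {
  stopifnot(inherits(rec, "sls_recording"),
            inherits(assign, "sls_pixel_assignment"))
  a <- assign$assignment
  if (nrow(a) != nrow(rec$data))
    stopf("assignment rows (%d) do not match trajectory length (%d)",
          nrow(a), nrow(rec$data))
  n_roi <- assign$n_rois
  ns <- ncol(rec$data)
  roi_tr <- matrix(NA_real_, n_roi, ns)
  loc_tr <- matrix(NA_real_, n_roi, ns)
  loc_raster <- vector("list", n_roi)
  for (i in seq_len(n_roi)) {
    ri <- which(a$group == "roi" & a$roi == i)
    if (!length(ri)) stopf("ROI %d has zero assigned pixels", i)
    roi_tr[i, ] <- colMeans(rec$data[ri, , drop = FALSE])
    li <- which(a$group == "local_np" & a$roi == i)
    if (length(li)) {
      loc_tr[i, ] <- colMeans(rec$data[li, , drop = FALSE])
      loc_raster[[i]] <- rec$data[li, , drop = FALSE]
    }
  }
  gi <- which(a$group == "global_np")
  global_np <- rec$data[gi, , drop = FALSE]
  patch <- NULL
  pi <- which(a$group == "reference_patch")
  if (length(pi)) {
    rp <- rec$traj$reference_patch
    side <- rp$side
    # pixels were appended in boustrophedon order; invert it
    px <- rec$traj$pixels[pi, ]
    patch <- array(0, dim = c(side, side, ns))
    rowi <- px$y - rp$y + 1L
    coli <- px$x - rp$x + 1L
    for (s in seq_len(ns))
      patch[cbind(rowi, coli, s)] <- rec$data[pi, s]
  }
  structure(list(roi = roi_tr, local_np = loc_tr,
                 local_np_raster = loc_raster, global_np = global_np,
                 patch = patch, fs = rec$fs, assignment = assign,
                 scan_period = rec$scan_period),
            class = "sls_traces")
}

#' Rigid shift of a mini-movie by phase correlation
#'
#' Each frame is registered against the temporal median frame using the
#' phase-correlation peak, refined to sub-pixel precision by a parabolic
#' fit around the peak. A featureless (flat) patch yields zero shifts with
#' a warning.
#'
#' @param mini_movie array side x side x frames, >= 2 frames.
#' @return matrix \[frames x 2\] of (dx, dy) shifts in pixels.
#' @export
estimate_rigid_shift <- function(mini_movie) {
  d <- dim(mini_movie)
  if (length(d) != 3 || d[3] < 2) stopf("a mini-movie with >= 2 frames is required")
  ref <- apply(mini_movie, c(1, 2), stats::median)
  if (stats::sd(ref) == 0) {
    warnf("featureless reference patch; returning zero shifts")
    return(matrix(0, d[3], 2, dimnames = list(NULL, c("dx", "dy"))))
  }
  Fr <- stats::fft(ref)
  out <- matrix(0, d[3], 2)
  ny <- d[1]; nx <- d[2]
  para <- function(cm, c0, cp) {
    den <- cm - 2 * c0 + cp
    if (den == 0) 0 else 0.5 * (cm - cp) / den
  }
  for (f in seq_len(d[3])) {
    Ff <- stats::fft(mini_movie[, , f])
    cross <- Fr * Conj(Ff)
    mag <- Mod(cross)
    mag[mag == 0] <- 1
    cc <- Re(stats::fft(cross / mag, inverse = TRUE))
    pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    py <- pk[1]; px <- pk[2]
    wrap <- function(i, n) ((i - 1) %% n) + 1
    dy <- py - 1; if (dy > ny / 2) dy <- dy - ny
    dx <- px - 1; if (dx > nx / 2) dx <- dx - nx
    sy <- para(cc[wrap(py - 1, ny), px], cc[py, px], cc[wrap(py + 1, ny), px])
    sx <- para(cc[py, wrap(px - 1, nx)], cc[py, px], cc[py, wrap(px + 1, nx)])
    out[f, ] <- c(-(dx + sx), -(dy + sy))
  }
  colnames(out) <- c("dx", "dy")
  out
}
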