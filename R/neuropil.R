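#' First SVD component of a pixel or ROI raster
#'
#' Returns the first right-singular time vector of the (per-row
#' mean-centered) raster, sign-fixed so its correlation with the raster
#' row-mean is non-negative, together with the per-row coefficients
#' (projections) used by the weighted strategy.
#'
#' @param raster matrix \[pixels-or-ROIs x scans\], >= 2 rows and columns.
#' @param center subtract each row's mean first (default TRUE).
#' @return list(time = unit-norm time vector, coef = per-row projections,
#'   d = singular value, var_frac = variance fraction explained).
#' @export
np_first_component <- function(raster, center = TRUE) {
  X <- as.matrix(raster)
  if (nrow(X) < 2 || ncol(X) < 2) stopf("raster must be at least 2 x 2")
  if (all(X == 0)) stopf("all-zero raster has no principal component")
  rm_ <- rowMeans(X)
  Xc <- if (center) X - rm_ else X
  sv <- first_singular(Xc)
  v <- sv$v
  cm <- colMeans(Xc)
  if (stats::sd(cm) > 0 && stats::sd(v) > 0 &&
      stats::cor(v, cm) < 0) {
    v <- -v
    sv$u <- -sv$u
  }
  tot <- sum(Xc^2)
  list(time = v, coef = as.vector(Xc %*% v), d = sv$d,
       var_frac = if (tot > 0) sv$d^2 / tot else 0)
}

#' Neuropil decontamination of ROI traces
#'
#' Three strategies: `global` subtracts alpha times the first SVD time
#' component of the global-neuropil pixel raster, amplitude-matched to
#' each ROI by least-squares projection; `local` does the same per ROI
#' with that ROI's local-neuropil pixel raster (requires surround width >
#' 1); `weighted_pc1` subtracts each ROI's own projection onto the first
#' component of the \[ROI x scan\] raster (no alpha). Corrected traces are
#' not clipped here; clipping happens at the dF/F0 stage.
#'
#' @param traces an `sls_traces` object (see [extract_traces()]) or a
#'   plain \[ROI x scan\] matrix (then only `weighted_pc1` and, with
#'   `global_np`, `global` are available).
#' @param strategy one of "global", "local", "weighted_pc1".
#' @param alpha neuropil scale factor (default 0.7).
#' @param rescale amplitude-match the component to each ROI by least
#'   squares before alpha-scaling ("ls", default) or subtract the raw
#'   component ("none").
#' @param global_np optional \[pixel x scan\] matrix when `traces` is a bare
#'   matrix.
#' @return list(corrected = \[ROI x scan\] matrix, model) where model is an
#'   `sls_neuropil_model`.
#' @export
correct_neuropil <- function(traces, strategy = c("global", "local", "weighted_pc1"),
                             alpha = 0.7, rescale = c("ls", "none"),
                             global_np = NULL) {
  strategy <- match.arg(strategy)
  rescale <- match.arg(rescale)
  if (alpha < 0) stopf("alpha must be >= 0")
  if (inherits(traces, "sls_traces")) {
    R <- traces$roi
    G <- traces$global_np
    loc_rasters <- traces$local_np_raster
  } else {
    R <- as.matrix(traces)
    G <- global_np
    if (strategy == "local")
      stopf("strategy 'local' requires an sls_traces object with surround pixels")
  }
  n_roi <- nrow(R); ns <- ncol(R)
  corrected <- R
  comp <- NULL; weights <- NULL
  subtract_ls <- function(trace, tv) {
    beta <- if (rescale == "ls") sum(trace * tv) / sum(tv^2) else 1
    trace - alpha * beta * tv
  }
  if (strategy == "global") {
    if (is.null(G) || nrow(G) < 2)
      stopf("strategy 'global' requires >= 2 global-neuropil pixels")
    comp <- np_first_component(G)
    for (i in seq_len(n_roi))
      corrected[i, ] <- subtract_ls(R[i, ] - mean(R[i, ]), comp$time) + mean(R[i, ])
  } else if (strategy == "local") {
    comp <- vector("list", n_roi)
    for (i in seq_len(n_roi)) {
      Li <- loc_rasters[[i]]
      if (is.null(Li) || nrow(Li) < 2)
        stopf("strategy 'local' needs surround width > 1 (ROI %d has %d local pixels)",
              i, if (is.null(Li)) 0L else nrow(Li))
      comp[[i]] <- np_first_component(Li)
      corrected[i, ] <- subtract_ls(R[i, ] - mean(R[i, ]), comp[[i]]$time) +
        mean(R[i, ])
    }
  } else { # weighted_pc1
    comp <- np_first_component(R)
    weights <- comp$coef
    for (i in seq_len(n_roi))
      corrected[i, ] <- R[i, ] - weights[i] * comp$time
  }
  model <- structure(list(strategy = strategy, alpha = alpha,
                          component = comp, weights = weights,
                          rescale = rescale),
                     class = "sls_neuropil_model")
  list(corrected = corrected, model = model)
}

#' Mean pairwise Pearson correlation across ROI traces
#'
#' @param traces matrix \[ROIs x scans\], >= 2 ROIs.
#' @return mean correlation over all unordered pairs; pairs involving a
#'   constant trace are skipped with a warning.
#' @export
mean_pairwise_correlation <- function(traces) {
  R <- as.matrix(traces)
  if (nrow(R) < 2) stopf("at least 2 ROI traces are required")
  sds <- apply(R, 1, stats::sd)
  if (any(sds == 0))
    warnf("%d constant trace(s); their pairs are skipped", sum(sds == 0))
  keep <- which(sds > 0)
  if (length(keep) < 2) stopf("fewer than 2 non-constant traces")
  cm <- stats::cor(t(R[keep, , drop = FALSE]))
  mean(cm[upper.tri(cm)])
}
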