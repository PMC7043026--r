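# GCaMP kernel sampled at fs, unit peak, truncated at 5 decay constants.
gcamp_kernel <- function(fs, kinetics = c(rise = 0.18, decay = 1.8)) {
  tr <- kinetics[[1]]; td <- kinetics[[2]]
  t <- seq(0, 5 * td, by = 1 / fs)
  k <- (1 - exp(-t / tr)) * exp(-t / td)
  k / max(k)
}

#' Non-negative deconvolution denoising of a dF/F0 trace
#'
#' Solves min ||K s - y||^2 + lambda ||s||_1 subject to s >= 0 by
#' accelerated projected gradient (FISTA), where K convolves with the
#' indicator kernel; the denoised trace is the reconvolution K s. The
#' sparsity weight lambda is scaled to the robust noise level of the
#' trace, so a noiseless kernel response is reproduced almost exactly
#' while pure noise is suppressed. Used as the activity estimate feeding
#' the binarization step.
#'
#' @param y non-negative dF/F0 series (or `sls_dff`).
#' @param fs sampling rate (Hz).
#' @param kinetics c(rise, decay) kernel time constants (s).
#' @param lambda_scale sparsity weight in units of the robust noise s.d.
#'   times the kernel norm (default 2).
#' @param maxit,tol iteration cap and relative-improvement tolerance; on
#'   non-convergence the best iterate is returned with a warning.
#' @return non-negative denoised trace, same length as `y`.
#' @export
denoise_nonneg <- function(y, fs, kinetics = c(rise = 0.18, decay = 1.8),
                           lambda_scale = 2, maxit = 2000L, tol = 1e-10) {
  if (inherits(y, "sls_dff")) y <- y$dff
  n <- length(y)
  if (all(y == 0)) return(numeric(n))
  k <- gcamp_kernel(fs, kinetics)
  nk <- length(k)
  # FFT-based causal convolution (length-preserving); nk grows with the
  # scan rate, so O(n log n) matters here
  N <- stats::nextn(n + nk - 1, 2)
  Kf <- stats::fft(c(k, numeric(N - nk)))
  conv <- function(s) {
    Re(stats::fft(stats::fft(c(s, numeric(N - n))) * Kf,
                  inverse = TRUE))[seq_len(n)] / N
  }
  corr <- function(r) rev(conv(rev(r)))   # adjoint of the Toeplitz operator
  lip <- sum(k)^2                     # Lipschitz bound for K^T K
  sigma <- stats::mad(y)
  lambda <- lambda_scale * sigma * sqrt(sum(k^2))
  # FISTA: accelerated projected gradient on the non-negative cone
  s <- pmax(y, 0)
  z <- s
  tt <- 1
  obj_old <- Inf
  converged <- FALSE
  for (it in seq_len(maxit)) {
    r <- conv(z) - y
    s_new <- pmax(z - (corr(r) + lambda) / lip, 0)
    obj <- sum((conv(s_new) - y)^2) + lambda * sum(s_new)
    if (is.finite(obj_old) &&
        (abs(obj_old - obj) < tol * max(obj_old, 1e-12) ||
         obj < 1e-6 * sum(y^2))) {
      s <- s_new
      converged <- TRUE
      break
    }
    tt_new <- (1 + sqrt(1 + 4 * tt^2)) / 2
    z <- s_new + (tt - 1) / tt_new * (s_new - s)
    s <- s_new
    tt <- tt_new
    obj_old <- obj
  }
  if (!converged) warnf("deconvolution did not converge in %d iterations; returning best iterate", maxit)
  conv(s)
}

#' Binarize denoised activity traces
#'
#' A frame is active when the trace exceeds `k_sd` standard deviations of
#' the (full) trace above zero. Constant-zero traces are all inactive.
#'
#' @param traces matrix \[ROIs x frames\] of non-negative denoised traces
#'   (a vector is treated as one ROI).
#' @param k_sd threshold in trace standard deviations (default 3).
#' @param fs frame rate stored with the raster.
#' @return object of class `sls_raster`: list(active = binary matrix, fs,
#'   provenance = "native").
#' @export
binarize_activity <- function(traces, k_sd = 3, fs = NULL) {
  m <- if (is.matrix(traces)) traces else matrix(traces, nrow = 1)
  act <- t(apply(m, 1, function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) rep(0L, length(x)) else as.integer(x > k_sd * s)
  }))
  structure(list(active = act, fs = fs, provenance = "native"),
            class = "sls_raster")
}

#' Surrogate-based coactivity threshold
#'
#' Each of `n_surrogates` surrogates independently permutes every ROI's
#' frames; the per-frame coactive counts of all surrogate frames are
#' pooled and k* is the smallest count whose exceedance probability is
#' below `alpha`.
#'
#' @param raster an `sls_raster` or binary matrix \[ROIs x frames\].
#' @param n_surrogates number of surrogates (default 1000).
#' @param alpha significance level (default 0.05).
#' @param seed RNG seed.
#' @param statistic pool all surrogate frames ("pooled", default) or use
#'   per-surrogate maxima ("max").
#' @return integer k* (NA for an all-zero raster, where no ensembles are
#'   possible).
#' @export
coactivity_threshold <- function(raster, n_surrogates = 1000L, alpha = 0.05,
                                 seed = 1L, statistic = c("pooled", "max")) {
  statistic <- match.arg(statistic)
  m <- if (inherits(raster, "sls_raster")) raster$active else raster
  if (nrow(m) < 2) stopf("coactivity requires at least 2 ROIs")
  if (all(m == 0)) return(NA_integer_)
  nT <- ncol(m)
  n_active <- rowSums(m)
  with_seed(seed, {
    # tally surrogate coactive counts without materializing all frames
    kmax_obs <- max(colSums(m))
    tal <- numeric(nrow(m) + 1L)   # tal[k + 1] = #frames with count k
    maxima <- integer(n_surrogates)
    for (b in seq_len(n_surrogates)) {
      counts <- integer(nT)
      for (i in seq_len(nrow(m))) {
        if (n_active[i] == 0) next
        pos <- sample.int(nT, n_active[i])
        counts[pos] <- counts[pos] + 1L
      }
      if (statistic == "pooled") {
        tb <- tabulate(counts + 1L, nbins = nrow(m) + 1L)
        tal <- tal + tb
      } else maxima[b] <- max(counts)
    }
    if (statistic == "max")
      tal <- tabulate(maxima + 1L, nbins = nrow(m) + 1L)
    total <- sum(tal)
    exceed <- rev(cumsum(rev(tal))) / total  # P(count >= k), k = 0..n_roi
    kstar <- NA_integer_
    for (k in seq_along(exceed)) {
      if (exceed[k] < alpha) { kstar <- as.integer(k - 1L); break }
    }
    if (is.na(kstar)) kstar <- as.integer(max(kmax_obs, nrow(m)) + 1L)
    kstar
  })
}

#' Detect significant coactivity frames (ensembles)
#'
#' Ensemble frames are those whose coactive-ROI count reaches
#' max(k*, 2); the ensemble rate is their number divided by the
#' recording duration.
#'
#' @param raster an `sls_raster` or binary matrix.
#' @param k_star surrogate threshold from [coactivity_threshold()] (NA ->
#'   no ensembles).
#' @param fs frame rate (taken from the raster when available).
#' @return object of class `sls_ensembles`: list(frames, counts, k_star,
#'   rate, n_frames, fs).
#' @export
detect_ensembles <- function(raster, k_star, fs = NULL) {
  m <- if (inherits(raster, "sls_raster")) raster$active else raster
  if (is.null(fs) && inherits(raster, "sls_raster")) fs <- raster$fs
  counts <- colSums(m)
  frames <- if (is.na(k_star)) integer(0) else
    which(counts >= max(k_star, 2))
  dur <- if (!is.null(fs)) ncol(m) / fs else NA_real_
  structure(list(frames = frames, counts = counts, k_star = k_star,
                 rate = if (is.na(dur)) NA_real_ else length(frames) / dur,
                 n_frames = ncol(m), fs = fs),
            class = "sls_ensembles")
}

#' Bin detected events into a fixed-width activity raster
#'
#' A bin is active when at least one event falls inside it; the bin grid
#' starts at t = 0.
#'
#' @param events an `sls_events` data.frame (columns roi, t_peak).
#' @param duration recording duration (s).
#' @param bin bin width (s, default 0.5).
#' @param rois ROI ids defining the rows (default those present).
#' @return `sls_raster` with provenance "binned".
#' @export
bin_raster <- function(events, duration, bin = 0.5, rois = NULL) {
  if (is.null(rois)) rois <- sort(unique(events$roi))
  n_bins <- ceiling(duration / bin)
  m <- matrix(0L, length(rois), n_bins)
  for (r in seq_along(rois)) {
    et <- events$t_peak[events$roi == rois[r]]
    b <- pmin(floor(et / bin) + 1L, n_bins)
    m[r, unique(b)] <- 1L
  }
  structure(list(active = m, fs = 1 / bin, provenance = "binned"),
            class = "sls_raster")
}

#' Non-negative matrix factorization of population activity
#'
#' Factorizes the non-negative \[ROIs x frames\] matrix F as M A + E with
#' multiplicative (Lee-Seung, Frobenius) updates; the best of
#' `n_restarts` seeded restarts by residual norm is kept.
#'
#' @param F non-negative matrix \[ROIs x frames\].
#' @param k number of modules, 1 <= k <= nrow(F).
#' @param seed RNG seed.
#' @param n_restarts restarts (default 5).
#' @param maxit updates per restart (default 500).
#' @return object of class `sls_nmf`: list(M [ROIs x k], A \[k x frames\],
#'   vaf, sparseness (per module), residual).
#' @export
nmf_decompose <- function(F, k, seed = 1L, n_restarts = 5L, maxit = 500L) {
  F <- as.matrix(F)
  if (any(F < 0)) stopf("F must be non-negative")
  n <- nrow(F)
  if (k < 1 || k > n) stopf("k must lie in [1, %d]", n)
  eps <- 1e-12
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      M <- matrix(stats::runif(n * k, 0.1, 1), n, k) * sqrt(mean(F) + eps)
      A <- matrix(stats::runif(k * ncol(F), 0.1, 1), k, ncol(F)) *
        sqrt(mean(F) + eps)
      for (it in seq_len(maxit)) {
        A <- A * (crossprod(M, F) + eps) / (crossprod(M, M %*% A) + eps)
        M <- M * (F %*% t(A) + eps) / (M %*% A %*% t(A) + eps)
      }
      res <- sum((F - M %*% A)^2)
      if (is.null(best) || res < best$residual)
        best <- list(M = M, A = A, residual = res)
    }
  })
  v <- vaf(F, best$M, best$A)
  sp <- apply(best$M, 2, sparseness)
  structure(list(M = best$M, A = best$A, vaf = v, sparseness = sp,
                 residual = best$residual, k = k), class = "sls_nmf")
}

#' Percent variance accounted for by a factorization
#'
#' VAF = 100 * (1 - sum(E^2) / sum(F^2)) with E = F - M A.
#'
#' @param F data matrix (not all zero).
#' @param M,A factor matrices with conforming shapes.
#' @return percentage (<= 100).
#' @export
vaf <- function(F, M, A) {
  F <- as.matrix(F)
  if (all(F == 0)) stopf("all-zero F has undefined VAF")
  E <- F - M %*% A
  100 * (1 - sum(E^2) / sum(F^2))
}

#' Spatial sparseness of a module weight vector
#'
#' s = sum(w^2) / (sum(w))^2, reaching its maximal value 1 when exactly
#' one ROI participates and 1/N for N equal weights; invariant to positive
#' scaling.
#'
#' @param w non-negative weights, not all zero.
#' @return value in (0, 1].
#' @export
sparseness <- function(w) {
  if (any(w < 0)) stopf("weights must be non-negative")
  s <- sum(w)
  if (s == 0) stopf("all-zero weight vector")
  sum(w^2) / s^2
}

# Linear max-margin classifier (L2-regularized squared hinge), fit by BFGS.
svm_fit <- function(X, y, C) {
  n <- nrow(X); p <- ncol(X)
  obj <- function(th) {
    w <- th[1:p]; b <- th[p + 1]
    m <- 1 - y * (X %*% w + b)
    sum(pmax(m, 0)^2) * C / n + 0.5 * sum(w^2)
  }
  grad <- function(th) {
    w <- th[1:p]; b <- th[p + 1]
    m <- as.vector(1 - y * (X %*% w + b))
    act <- m > 0
    gm <- -2 * y * m * act
    c(as.vector(crossprod(X, gm)) * C / n + w, sum(gm) * C / n)
  }
  fit <- stats::optim(numeric(p + 1), obj, grad, method = "BFGS",
                      control = list(maxit = 200))
  list(w = fit$par[1:p], b = fit$par[p + 1])
}

svm_predict <- function(model, X) {
  sign(as.vector(X %*% model$w + model$b))
}

#' Decode stimulus presence from population activity
#'
#' Trains a linear maximum-margin classifier on per-frame population
#' vectors using a random 50/50 train/test split; the regularization
#' strength is chosen by 10-fold cross-validation on the training half.
#' Reports test accuracy minus chance (the majority-class proportion).
#'
#' @param activity matrix \[ROIs x frames\].
#' @param labels per-frame binary labels (stimulus present / absent).
#' @param seed RNG seed for the split and CV folds.
#' @param C_grid regularization grid.
#' @return list(accuracy, chance, above_chance, C).
#' @export
decode_stimulus <- function(activity, labels, seed = 1L,
                            C_grid = c(0.01, 0.1, 1, 10)) {
  X <- t(as.matrix(activity))
  y <- as.integer(labels)
  if (length(unique(y)) < 2) stopf("labels contain a single class")
  y2 <- ifelse(y == max(y), 1, -1)
  n <- nrow(X)
  with_seed(seed, {
    idx <- sample.int(n)
    tr <- idx[seq_len(floor(n / 2))]
    te <- setdiff(idx, tr)
    folds <- rep_len(1:10, length(tr))[sample.int(length(tr))]
    cv_acc <- vapply(C_grid, function(C) {
      accs <- vapply(1:10, function(f) {
        in_f <- tr[folds == f]; out_f <- tr[folds != f]
        if (length(unique(y2[out_f])) < 2) return(NA_real_)
        m <- svm_fit(X[out_f, , drop = FALSE], y2[out_f], C)
        mean(svm_predict(m, X[in_f, , drop = FALSE]) == y2[in_f])
      }, numeric(1))
      mean(accs, na.rm = TRUE)
    }, numeric(1))
    C_best <- C_grid[which.max(cv_acc)]
    m <- svm_fit(X[tr, , drop = FALSE], y2[tr], C_best)
    acc <- mean(svm_predict(m, X[te, , drop = FALSE]) == y2[te])
    chance <- max(table(y2[te])) / length(te)
    list(accuracy = acc, chance = chance, above_chance = acc - chance,
         C = C_best)
  })
}

#' Inclusion rule for decoding
#'
#' A series qualifies for decoding when at least half of the ROIs show
#' calcium events in at least half of the stimuli.
#'
#' @param events an `sls_events` data.frame.
#' @param stim_times stimulus times (s).
#' @param rois ROI ids.
#' @param response_window window after each stimulus (s, default 2).
#' @return logical.
#' @export
decoding_inclusion <- function(events, stim_times, rois,
                               response_window = 2) {
  frac <- vapply(rois, function(r) {
    et <- events$t_peak[events$roi == r]
    mean(vapply(stim_times, function(ts)
      any(et > ts & et <= ts + response_window), logical(1)))
  }, numeric(1))
  mean(frac >= 0.5) >= 0.5
}
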