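#' @keywords internal
"_PACKAGE"

# Evaluate expr with a temporary RNG state seeded by `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Noise estimate from sub-baseline samples
#'
#' Standard deviation of the values strictly below the given percentile of a
#' trace (linear-interpolation percentile). If the strict subset is empty or
#' has zero spread, values less than or equal to the percentile are used; if
#' the spread is still zero, 0 is returned.
#'
#' @param x numeric vector.
#' @param prob percentile defining "baseline" samples (default 0.25).
#' @return non-negative scalar noise estimate (0 signals a degenerate trace).
#' @export
baseline_noise_sd <- function(x, prob = 0.25) {
  q <- stats::quantile(x, prob, names = FALSE, type = 7)
  lo <- x[x < q]
  s <- if (length(lo) >= 2) stats::sd(lo) else NA_real_
  if (!is.finite(s) || s == 0) {
    lo <- x[x <= q]
    s <- if (length(lo) >= 2) stats::sd(lo) else NA_real_
  }
  if (!is.finite(s)) s <- 0
  s
}

# Row-wise baseline_noise_sd for a [row x time] matrix.
row_noise_sd <- function(m, prob = 0.25) {
  apply(m, 1L, baseline_noise_sd, prob = prob)
}

# Bilinear sampling of matrix `img` at fractional coordinates.
# x = column, y = row, both 0-based at pixel centers. Points outside the
# image return `outside` (default 0).
bilinear_sample <- function(img, x, y, outside = 0) {
  ny <- nrow(img); nx <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  val <- rep(outside, length(x))
  px <- function(ix, iy) {
    # clamp so edge pixels extrapolate flat within the valid bbox
    ix <- pmin(pmax(ix, 0), nx - 1L)
    iy <- pmin(pmax(iy, 0), ny - 1L)
    img[iy + ix * ny + 1L]
  }
  inside <- x >= -0.5 & x <= nx - 0.5 & y >= -0.5 & y <= ny - 0.5
  if (any(inside)) {
    ix <- x0[inside]; iy <- y0[inside]
    gx <- fx[inside]; gy <- fy[inside]
    v <- (1 - gx) * (1 - gy) * px(ix, iy) +
      gx * (1 - gy) * px(ix + 1, iy) +
      (1 - gx) * gy * px(ix, iy + 1) +
      gx * gy * px(ix + 1, iy + 1)
    val[inside] <- v
  }
  val
}

# 8-connected Bresenham line between two integer pixels (0-based x = col,
# y = row). Returns a matrix [n x 2] of (x, y) including both endpoints.
bresenham <- function(x0, y0, x1, y1) {
  dx <- abs(x1 - x0); dy <- abs(y1 - y0)
  sx <- ifelse(x0 < x1, 1L, -1L); sy <- ifelse(y0 < y1, 1L, -1L)
  err <- dx - dy
  xs <- integer(0); ys <- integer(0)
  x <- x0; y <- y0
  repeat {
    xs <- c(xs, x); ys <- c(ys, y)
    if (x == x1 && y == y1) break
    e2 <- 2L * err
    if (e2 > -dy) { err <- err - dy; x <- x + sx }
    if (e2 < dx)  { err <- err + dx; y <- y + sy }
  }
  cbind(x = xs, y = ys)
}

# Leading singular triplet of X by alternating power iteration.
# Deterministic start (column means; falls back to a fixed ramp).
first_singular <- function(X, tol = 1e-12, maxit = 1000L) {
  X <- as.matrix(X)
  v <- colMeans(X)
  nv <- sqrt(sum(v^2))
  if (!is.finite(nv) || nv == 0) v <- seq_len(ncol(X)) / ncol(X)
  v <- v / sqrt(sum(v^2))
  d_old <- 0; u <- rep(0, nrow(X)); d <- 0
  for (it in seq_len(maxit)) {
    u <- as.vector(X %*% v)
    du <- sqrt(sum(u^2))
    if (du == 0) return(list(u = u, d = 0, v = v))
    u <- u / du
    v <- as.vector(crossprod(X, u))
    d <- sqrt(sum(v^2))
    if (d == 0) return(list(u = u, d = 0, v = v))
    v <- v / d
    if (abs(d - d_old) <= tol * d) break
    d_old <- d
  }
  list(u = u, d = d, v = v)
}

# Indices of strict local maxima (first sample of any plateau).
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  i[x[i] > x[i - 1] & x[i] >= x[i + 1]]
}

# Deterministic polynomial hash of a character string (provenance stamps),
# returned as 8 hex digits. Not cryptographic.
content_hash <- function(s) {
  b <- as.integer(charToRaw(paste(s, collapse = "\n")))
  m <- 2147483647 # 2^31 - 1
  h <- 17
  for (x in b) h <- (h * 131 + x + 1) %% m
  sprintf("%08x", as.integer(h))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
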