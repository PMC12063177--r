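## Internal numerical helpers: Gaussian kernels, reflect-padded FFT
## convolution, histogram peak finding with topographic prominence, and
## local Gaussian peak fits.

## discrete Gaussian kernel truncated at +-4 sd, unit sum
.gaussKernel <- function(sigmaSamples) {
  half <- max(1L, ceiling(4 * sigmaSamples))
  k <- stats::dnorm(seq(-half, half), sd = max(sigmaSamples, 1e-8))
  k / sum(k)
}

## zero-phase convolution with a symmetric odd-length kernel; reflect
## padding keeps the output length equal to the input length.
.convReflect <- function(x, kernel) {
  n <- length(x)
  half <- (length(kernel) - 1L) %/% 2L
  if (half == 0L) return(x * kernel)
  if (n <= half)
    stop("trace shorter than filter kernel")
  xp <- c(x[half:1], x, x[n:(n - half + 1L)])
  ## FFT convolution, zero-padded to a 2-3-5-smooth length (unpadded FFTs
  ## can hit large prime lengths and degrade badly); kernel is symmetric so
  ## orientation is irrelevant
  m <- length(xp)
  L <- m + length(kernel) - 1L
  N <- stats::nextn(L, c(2L, 3L, 5L))
  X <- stats::fft(c(xp, numeric(N - m)))
  K <- stats::fft(c(kernel, numeric(N - length(kernel))))
  full <- Re(stats::fft(X * K, inverse = TRUE)) / N
  full[(2L * half + 1L):(2L * half + n)]
}

## local maxima of y with topographic prominence >= promFrac * max(y);
## returns indices sorted by position
.peakIndices <- function(y, promFrac = 0.05) {
  n <- length(y)
  if (n < 3L || max(y) <= 0) return(integer())
  left <- c(-Inf, y[-n])
  right <- c(y[-1L], -Inf)
  cand <- which(y > left & y >= right)
  if (!length(cand)) return(integer())
  prom <- vapply(cand, function(i) {
    lmin <- if (any(y[seq_len(i - 1)] > y[i])) {
      j <- max(which(y[seq_len(i - 1)] > y[i]))
      min(y[j:i])
    } else 0
    upper <- if (i < n) y[(i + 1):n] else numeric()
    rmin <- if (any(upper > y[i])) {
      j <- i + min(which(upper > y[i]))
      min(y[i:j])
    } else 0
    y[i] - max(lmin, rmin)
  }, numeric(1))
  cand[prom >= promFrac * max(y)]
}

## weighted mean/sd of a histogram restricted to a window around a peak
.peakMoments <- function(x, y, idx, halfWindow) {
  sel <- which(abs(x - x[idx]) <= halfWindow & y > 0)
  if (length(sel) < 2L) sel <- max(1L, idx - 2L):min(length(x), idx + 2L)
  w <- y[sel]
  mu <- sum(w * x[sel]) / sum(w)
  sd <- sqrt(max(sum(w * (x[sel] - mu)^2) / sum(w), 1e-12))
  list(mean = mu, sd = sd, height = y[idx])
}

## local Gaussian least-squares fit around a histogram peak; falls back to
## weighted moments when the optimizer fails
.fitGaussianPeak <- function(x, y, idx, halfWindow) {
  mom <- .peakMoments(x, y, idx, halfWindow)
  sel <- which(abs(x - x[idx]) <= halfWindow)
  if (length(sel) < 4L) return(mom)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      yy ~ A * exp(-(xx - mu)^2 / (2 * s^2)),
      data = list(xx = x[sel], yy = y[sel]),
      start = list(A = max(y[sel]), mu = mom$mean, s = mom$sd),
      lower = c(A = 0, mu = min(x[sel]), s = 1e-6),
      upper = c(A = Inf, mu = max(x[sel]), s = diff(range(x[sel])) + 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(mom)
  cf <- stats::coef(fit)
  list(mean = unname(cf["mu"]), sd = unname(cf["s"]),
       height = unname(cf["A"]))
}

## smoothed histogram peaks with local Gaussian refits; x must be sorted
.histogramPeaks <- function(x, counts, smoothSDbins = 3, promFrac = 0.05,
                            refit = TRUE) {
  if (!length(counts) || max(counts) <= 0)
    return(data.frame(mean = numeric(), sd = numeric(),
                      height = numeric()))
  sm <- .convReflect(counts, .gaussKernel(smoothSDbins))
  idx <- .peakIndices(sm, promFrac)
  if (!length(idx))
    return(data.frame(mean = numeric(), sd = numeric(),
                      height = numeric()))
  bw <- if (length(x) > 1) x[2] - x[1] else 1
  out <- lapply(idx, function(i) {
    ## half-window: distance to nearest neighbouring peak (or edge), capped
    nb <- idx[idx != i]
    lim <- if (length(nb)) min(abs(x[nb] - x[i])) / 2 else Inf
    hw <- min(lim, max(10 * bw, 6 * bw * smoothSDbins))
    if (refit) .fitGaussianPeak(x, counts, i, hw)
    else .peakMoments(x, counts, i, hw)
  })
  data.frame(mean = vapply(out, `[[`, numeric(1), "mean"),
             sd = vapply(out, `[[`, numeric(1), "sd"),
             height = vapply(out, `[[`, numeric(1), "height"))
}

.isCount <- function(x) length(x) == 1L && is.finite(x) && x >= 0 &&
  abs(x - round(x)) < 1e-9

## deterministic number formatting for file output
.fmtNum <- function(x, digits = 10) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.*g", digits, v)
  }, character(1))
  out
}
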