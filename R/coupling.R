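# Correlation/coherence battery between generator time courses: lagged
# cross-correlation, phase-randomization surrogates, surrogate-thresholded
# Welch coherence, windowed Pearson density histograms, and gamma-band mean
# frequency from the autocorrelation.

#' Lagged cross-correlation between two time courses
#'
#' \code{R(lag) = cor(x(t), y(t + lag))}, the normalized correlation
#' coefficient \eqn{R = C_{12}/\sqrt{C_{11} C_{22}}} at each lag. A positive
#' \code{tau_max} means y lags x (x leads). Optionally the significance of
#' the peak is assessed against phase-randomization surrogates.
#'
#' @param x,y numeric vectors of equal length (>= 10 x the lag span).
#' @param fs sampling rate, Hz.
#' @param maxLag maximum lag, seconds.
#' @param nSurrogates surrogate count for peak significance (0 to skip).
#' @param alpha significance level (default 0.05).
#' @return list of class \code{"CCResult"}: \code{lags_s}, \code{R},
#'   \code{cc_max} (signed R at the absolute peak), \code{tau_max_s},
#'   \code{significant}, \code{threshold}.
#' @export
crossCorrLagged <- function(x, y, fs, maxLag, nSurrogates = 0, alpha = 0.05) {
  n <- length(x)
  stopifnot(length(y) == n)
  L <- round(maxLag * fs)
  if (n < 10 * L) stop("series too short for the requested lag span")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero-variance input")
  ccAt <- function(a, b) {
    vapply(-L:L, function(l) {
      if (l >= 0) stats::cor(a[seq_len(n - l)], b[seq_len(n - l) + l])
      else stats::cor(a[seq_len(n + l) - l], b[seq_len(n + l)])
    }, 0)
  }
  R <- ccAt(x, y)
  lags <- (-L:L) / fs
  # peak of |R|; ties (periodic signals) resolved to the smallest |lag|
  ipk <- which(abs(R) >= max(abs(R)) - 1e-12)
  ipk <- ipk[which.min(abs(lags[ipk]))]
  thr <- NA_real_; sig <- NA
  if (nSurrogates > 0) {
    peaks <- vapply(seq_len(nSurrogates), function(s) {
      max(abs(ccAt(phaseRandomize(x), phaseRandomize(y))))
    }, 0)
    thr <- stats::quantile(peaks, 1 - alpha, names = FALSE)
    sig <- abs(R[ipk]) > thr
  }
  structure(list(lags_s = lags, R = R, cc_max = R[ipk],
                 tau_max_s = lags[ipk], threshold = thr, significant = sig),
            class = "CCResult")
}

#' Phase-randomization surrogate of a time series
#'
#' Randomizes the Fourier phases while keeping the amplitude spectrum (and
#' hence the power spectrum and autocorrelation) intact to machine precision;
#' conjugate symmetry keeps the surrogate real and the mean preserved.
#'
#' @param x real-valued series.
#' @param seed optional integer seed.
#' @return surrogate series of the same length.
#' @export
phaseRandomize <- function(x, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  .randPhase(stats::fft(x))
}

# phase rotation given a precomputed forward FFT (hot loop of the coherence
# surrogate test)
.randPhase <- function(X) {
  n <- length(X)
  half <- (n - 1) %/% 2
  if (half >= 1) {
    rot <- exp(2i * pi * stats::runif(half))
    X[2:(half + 1)] <- X[2:(half + 1)] * rot
    X[n:(n - half + 1)] <- Conj(X[2:(half + 1)])
  }
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Welch magnitude-squared coherence with surrogate significance
#'
#' \eqn{C_{xy}(f) = |P_{xy}(f)|^2 / (P_{xx}(f) P_{yy}(f))} from
#' segment-averaged (Welch, Hann window) spectra. The per-frequency
#' significance threshold is the \code{1 - alpha} quantile of coherences of
#' phase-randomized surrogate pairs (both inputs randomized independently).
#' A frequency is flagged significant iff its coherence exceeds the
#' threshold.
#'
#' @param x,y numeric vectors of equal length (>= 8 Welch segments).
#' @param fs sampling rate, Hz.
#' @param nSurrogates surrogate count (default 1000; smaller counts such
#'   as 400 remain exactly calibrated by the order-statistic threshold).
#' @param alpha significance level (default 0.05).
#' @param segLength Welch segment length, seconds (default 1).
#' @param overlap segment overlap fraction (default 0.5).
#' @param mask optional logical vector (TRUE = excluded sample); segments
#'   touching an excluded sample are dropped.
#' @param seed optional integer seed for the surrogate stream.
#' @return list of class \code{"CoherenceResult"}: \code{freqs_hz},
#'   \code{coherence}, \code{threshold}, \code{significant},
#'   \code{nSurrogates}, \code{nSegments}.
#' @export
coherenceWithSignificance <- function(x, y, fs, nSurrogates = 1000,
                                      alpha = 0.05, segLength = 1,
                                      overlap = 0.5, mask = NULL,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(x)
  stopifnot(length(y) == n)
  nseg <- round(segLength * fs)
  starts <- .segStarts(n, nseg, overlap)
  if (!is.null(mask)) {
    keep <- vapply(starts, function(s0) !any(mask[s0:(s0 + nseg - 1L)]), TRUE)
    starts <- starts[keep]
  }
  if (length(starts) < 8)
    stop("estimator error: fewer than 8 Welch segments available")
  idx <- outer(seq_len(nseg) - 1L, starts, `+`) + 0L
  storage.mode(idx) <- "integer"
  win <- .hann(nseg)
  msc <- function(a, b) {
    w <- .welchXY(a, b, idx, win)
    Mod(w$Pxy)^2 / (w$Pxx * w$Pyy)
  }
  C <- msc(x, y)
  freqs <- (seq_along(C)) * fs / nseg
  # surrogates: forward FFTs computed once; each draw rotates the phases
  Xf <- stats::fft(x); Yf <- stats::fft(y)
  surr <- matrix(0, length(C), nSurrogates)
  for (s in seq_len(nSurrogates)) {
    surr[, s] <- msc(.randPhase(Xf), .randPhase(Yf))
  }
  # per-frequency Monte-Carlo threshold: k-th order statistic with
  # k = ceiling((1 - alpha) (N + 1)), the exact level-alpha construction
  # under exchangeability of the observed pair with its surrogates
  k <- min(nSurrogates, ceiling((1 - alpha) * (nSurrogates + 1)))
  thr <- apply(surr, 1, function(v) sort.int(v, partial = k)[k])
  structure(list(freqs_hz = freqs, coherence = C, threshold = thr,
                 significant = C > thr, nSurrogates = nSurrogates,
                 alpha = alpha, nSegments = length(starts)),
            class = "CoherenceResult")
}

#' Windowed Pearson correlation density histogram
#'
#' Chops both series into consecutive windows of \code{dt} seconds (the
#' incomplete trailing window is dropped), computes the Pearson coefficient
#' per window, and summarizes the values as a density histogram with mean
#' \code{chi} and SD \code{sigma}. Long windows track the slow envelope
#' correlation; short windows emphasize fast-fluctuation coupling (the
#' histograms flatten as \code{dt} decreases). Zero-variance windows yield
#' missing values, not zeros; windows touching a masked sample are dropped.
#'
#' @param x,y numeric vectors of equal length.
#' @param fs sampling rate, Hz.
#' @param dt window length, seconds (\code{dt * fs >= 3} samples; the
#'   canonical comparison set is 1, 0.1 and 0.01 s).
#' @param bins histogram bin count on [-1, 1] (default 41).
#' @param mask optional logical exclusion vector.
#' @return list of class \code{"WindowedCorrelation"}: \code{window_s},
#'   \code{r} (per-window, NA where undefined), \code{edges},
#'   \code{density}, \code{chi}, \code{sigma}, \code{nWindows}.
#' @export
windowedPearson <- function(x, y, fs, dt, bins = 41, mask = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  w <- round(dt * fs)
  if (w < 3) stop("dt * fs must be >= 3 samples")
  nw <- n %/% w
  if (nw < 20) stop("need at least 20 windows")
  use <- seq_len(nw * w)
  X <- matrix(x[use], w); Y <- matrix(y[use], w)
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- X - rep(cx, each = w); Yc <- Y - rep(cy, each = w)
  sx <- colSums(Xc^2); sy <- colSums(Yc^2)
  r <- colSums(Xc * Yc) / sqrt(sx * sy)
  r[sx == 0 | sy == 0] <- NA_real_
  if (!is.null(mask)) {
    Mk <- matrix(mask[use], w)
    r[colSums(Mk) > 0] <- NA_real_
  }
  edges <- seq(-1, 1, length.out = bins + 1)
  h <- graphics::hist(r[!is.na(r)], breaks = edges, plot = FALSE)
  structure(list(window_s = dt, r = r, edges = edges, density = h$density,
                 chi = mean(r, na.rm = TRUE),
                 sigma = stats::sd(r[!is.na(r)]),
                 nWindows = sum(!is.na(r))),
            class = "WindowedCorrelation")
}

#' Mean oscillation frequency from the autocorrelation
#'
#' Band-passes the series (default 30--100 Hz, the gamma band), computes the
#' autocorrelation, locates the first positive-lag local maximum (with
#' parabolic interpolation), and returns its reciprocal in Hz.
#'
#' @param x numeric vector, longer than 100 cycles of the band's low edge.
#' @param fs sampling rate, Hz.
#' @param band \code{c(low, high)} Hz (default \code{c(30, 100)}).
#' @param minPeak minimum autocorrelation at the peak for a defined estimate
#'   (default 0.05).
#' @return frequency in Hz, or \code{NA} with attribute
#'   \code{undefined = TRUE} when no peak rises above the noise floor.
#' @export
meanFrequencyAutocorr <- function(x, fs, band = c(30, 100), minPeak = 0.05) {
  if (length(x) / fs < 100 / band[1])
    stop("series shorter than 100 cycles of the band's low edge")
  xb <- filterSignal(x, "bandpass", band, fs)
  maxLag <- round(2 * fs / band[1])
  ac <- stats::acf(xb, lag.max = maxLag, plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  # first local maximum at positive lag (index 1 of ac is lag 0)
  pk <- NA_integer_
  for (i in 3:(length(ac) - 1)) {
    if (ac[i] > ac[i - 1] && ac[i] >= ac[i + 1]) { pk <- i; break }
  }
  if (is.na(pk) || ac[pk] < minPeak) {
    out <- NA_real_; attr(out, "undefined") <- TRUE
    return(out)
  }
  # parabolic interpolation around the peak
  y1 <- ac[pk - 1]; y2 <- ac[pk]; y3 <- ac[pk + 1]
  denom <- y1 - 2 * y2 + y3
  shift <- if (denom != 0) 0.5 * (y1 - y3) / denom else 0
  lag <- (pk - 1 + shift) / fs
  1 / lag
}
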