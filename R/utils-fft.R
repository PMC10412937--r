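# FFT plumbing shared by preprocessing, coherence and the synthetic generator.
# All filters are applied in the frequency domain with mirror padding: the gain
# is the magnitude-squared (forward-backward) Butterworth response, so the
# result is exactly zero-phase.

# per-bin absolute frequency for an n-point FFT at rate fs
.fftFreqs <- function(n, fs) {
  k <- 0:(n - 1)
  f <- k / n * fs
  f[f > fs / 2] <- fs - f[f > fs / 2]
  f
}

# |H|^2 of an order-`ord` Butterworth high-pass / low-pass at cutoff fc
.butterHP2 <- function(f, fc, ord = 4L) {
  g <- numeric(length(f))
  nz <- f > 0
  g[nz] <- 1 / (1 + (fc / f[nz])^(2 * ord))
  g
}
.butterLP2 <- function(f, fc, ord = 4L) 1 / (1 + (f / fc)^(2 * ord))

# apply a real gain(f) to a vector with mirror padding (npad samples each end)
.applyGain <- function(x, fs, gainFun, npad = NULL) {
  n <- length(x)
  if (is.null(npad)) npad <- min(n, 2048L)
  npad <- min(npad, n)
  xp <- c(rev(x[seq_len(npad)]), x, rev(x[n - seq_len(npad) + 1L]))
  np <- length(xp)
  g <- gainFun(.fftFreqs(np, fs))
  y <- Re(stats::fft(stats::fft(xp) * g, inverse = TRUE)) / np
  y[(npad + 1L):(npad + n)]
}

# Fourier-domain resampling (ideal anti-alias); n_out must be integral
.resampleFFT <- function(x, nOut) {
  n <- length(x)
  X <- stats::fft(x) / n
  H <- complex(length.out = nOut)
  H[1] <- X[1]
  kmax <- ceiling(min(n, nOut) / 2) - 1L  # strictly below both Nyquists
  if (kmax >= 1L) {
    ks <- seq_len(kmax)
    H[ks + 1L] <- X[ks + 1L]
    H[nOut - ks + 1L] <- Conj(X[ks + 1L])
  }
  Re(stats::fft(H, inverse = TRUE))
}

.hann <- function(n) 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))

# segment start indices for Welch averaging
.segStarts <- function(n, nseg, overlap) {
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, n - nseg + 1L, by = step)
  starts
}

# Welch one-sided auto/cross spectra of x and y over prebuilt segment indices.
# idx: nseg x nsegments matrix of sample indices; win: window vector.
# Both signals' segments go through one batched mvfft; DC and Nyquist bins
# are dropped.
.welchXY <- function(x, y, idx, win) {
  nseg <- nrow(idx); ns <- ncol(idx)
  B <- matrix(c(x[idx], y[idx]), nseg)
  B <- (B - rep(colMeans(B), each = nseg)) * win
  FB <- stats::mvfft(B)
  keep <- 2:(nseg %/% 2L)
  FX <- FB[keep, seq_len(ns), drop = FALSE]
  FY <- FB[keep, ns + seq_len(ns), drop = FALSE]
  ones <- rep(1 / ns, ns)
  Pxx <- as.vector((Re(FX)^2 + Im(FX)^2) %*% ones)
  Pyy <- as.vector((Re(FY)^2 + Im(FY)^2) %*% ones)
  Pxy <- as.vector((Conj(FX) * FY) %*% ones)
  list(Pxx = Pxx, Pyy = Pyy, Pxy = Pxy, kbins = keep - 1L)
}

# band-limited unit-variance Gaussian noise via brick-wall FFT masking
.bandNoise <- function(n, fs, band) {
  z <- stats::rnorm(n)
  Z <- stats::fft(z)
  f <- .fftFreqs(n, fs)
  Z[f < band[1] | f > band[2]] <- 0
  out <- Re(stats::fft(Z, inverse = TRUE)) / n
  s <- stats::sd(out)
  if (s == 0) stop("empty band: no Fourier bins inside [", band[1], ", ",
                   band[2], "] Hz")
  out / s
}

# deterministic sub-seed streams derived from one global seed
.seedStream <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, n)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  s
}
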