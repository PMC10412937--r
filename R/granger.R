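# Pairwise temporal and spectral Granger causality over sliding windows with
# block-resampling surrogate significance.
#
# Temporal statistic per direction: F_{X->Y} = ln(|Sigma_YY| / |Sigma'_YY|),
# the log ratio of residual variances of the reduced (own-past) and full
# (own + other's past) autoregressive models, fitted by ordinary least
# squares per window and averaged across windows. Spectral statistic: the
# Geweke frequency-domain decomposition computed from the fitted bivariate
# VAR transfer function.

# lag matrix: rows t = p+1..n, columns x(t-1), ..., x(t-p)
.lagEmbed <- function(x, p) {
  n <- length(x)
  stats::embed(x, p + 1L)[, -1L, drop = FALSE]
}

# window row ranges over the lag-aligned sample axis (targets t = p+1..n)
.grangerWindows <- function(nAligned, fs, window, overlap) {
  wlen <- round(window * fs)
  step <- max(1L, round(wlen * (1 - overlap)))
  starts <- seq(1L, nAligned - wlen + 1L, by = step)
  lapply(starts, function(s0) s0:(s0 + wlen - 1L))
}

# per-window OLS F for one direction, given precomputed lag matrices.
# Overlapping windows share crossprod work: the sample axis is split at all
# window boundaries, one crossprod is computed per segment, and each window's
# Gram matrix is the sum over its segments.
# Returns per-window F and the reduced-model AR coefficients (for stability).
.grangerFdir <- function(target, ownLags, otherLags, winRows, p,
                         withCoef = FALSE) {
  Cfull <- cbind(1, target, ownLags, otherLags)
  it <- 2L                       # target column in the crossprod
  iOwn <- 2L + seq_len(p)        # own-lag columns
  iRed <- c(1L, iOwn)            # reduced model: intercept + own lags
  iFull <- c(1L, iOwn, 2L + p + seq_len(p))
  starts <- vapply(winRows, `[`, 0L, 1L)
  ends <- vapply(winRows, function(r) r[length(r)], 0L)
  bounds <- sort(unique(c(starts, ends + 1L)))
  nb <- length(bounds) - 1L
  segG <- vector("list", nb)
  for (i in seq_len(nb)) {
    segG[[i]] <- crossprod(Cfull[bounds[i]:(bounds[i + 1L] - 1L), ,
                                 drop = FALSE])
  }
  Fw <- numeric(length(winRows))
  coefs <- if (withCoef) vector("list", length(winRows)) else NULL
  for (w in seq_along(winRows)) {
    segs <- which(bounds >= starts[w] & bounds <= ends[w])
    segs <- segs[segs <= nb]
    G <- segG[[segs[1L]]]
    for (i in segs[-1L]) G <- G + segG[[i]]
    nw <- ends[w] - starts[w] + 1L
    solveS2 <- function(idx) {
      b <- tryCatch(solve(G[idx, idx], G[idx, it]),
                    error = function(e) {
                      ridge <- diag(1e-10 * mean(diag(G[idx, idx])),
                                    length(idx))
                      solve(G[idx, idx] + ridge, G[idx, it])
                    })
      s2 <- (G[it, it] - sum(G[idx, it] * b)) / nw
      list(b = b, s2 = max(s2, .Machine$double.eps))
    }
    red <- solveS2(iRed)
    full <- solveS2(iFull)
    Fw[w] <- log(red$s2 / full$s2)
    if (withCoef) coefs[[w]] <- red$b[-1L]   # AR coefficients, no intercept
  }
  list(Fw = Fw, coefs = coefs)
}

# TRUE when the AR(p) polynomial 1 - a1 z - ... - ap z^p has all roots
# outside the unit circle (stable model)
.arStable <- function(a) {
  if (all(a == 0)) return(TRUE)
  all(Mod(polyroot(c(1, -a))) > 1)
}

#' Temporal pairwise Granger causality over sliding windows
#'
#' Per window, the reduced model predicts each series from its own past and
#' the full model adds the other series' past (both order \code{p}, OLS with
#' intercept); \eqn{F = \ln(\Sigma_{YY}/\Sigma'_{YY})}. The reported
#' statistic per direction is the average across windows. Windows whose
#' reduced AR fit is unstable (roots inside the unit circle) are flagged and
#' excluded from the average.
#'
#' @param x,y numeric vectors at rate \code{fs} (resample upstream if
#'   needed); length must cover at least 3 windows.
#' @param fs sampling rate, Hz (default 250).
#' @param window window length, seconds (default 5).
#' @param overlap window overlap fraction (default 0.8).
#' @param p model order (default 12).
#' @return list of class \code{"GrangerResult"}: \code{F_xy}, \code{F_yx}
#'   (window-averaged), \code{perWindow} (data.frame), \code{nWindowsUsed},
#'   \code{nWindowsExcluded}, \code{params}.
#' @export
grangerTemporal <- function(x, y, fs = 250, window = 5, overlap = 0.8,
                            p = 12) {
  n <- length(x)
  stopifnot(length(y) == n)
  wlen <- round(window * fs)
  nAligned <- n - p
  if (nAligned < wlen + 2L * max(1L, round(wlen * (1 - overlap))))
    stop("series too short: need at least 3 windows")
  xt <- x[(p + 1):n]; yt <- y[(p + 1):n]
  Lx <- .lagEmbed(x, p); Ly <- .lagEmbed(y, p)
  winRows <- .grangerWindows(nAligned, fs, window, overlap)
  dxy <- .grangerFdir(yt, Ly, Lx, winRows, p, withCoef = TRUE)  # X -> Y
  dyx <- .grangerFdir(xt, Lx, Ly, winRows, p, withCoef = TRUE)  # Y -> X
  stable <- vapply(seq_along(winRows), function(w) {
    .arStable(dxy$coefs[[w]]) && .arStable(dyx$coefs[[w]])
  }, TRUE)
  if (!any(stable)) stop("no stable windows: cannot average Granger statistic")
  perWindow <- data.frame(window = seq_along(winRows),
                          F_xy = dxy$Fw, F_yx = dyx$Fw, stable = stable)
  structure(list(F_xy = mean(dxy$Fw[stable]), F_yx = mean(dyx$Fw[stable]),
                 perWindow = perWindow,
                 nWindowsUsed = sum(stable),
                 nWindowsExcluded = sum(!stable),
                 params = list(fs = fs, window = window, overlap = overlap,
                               p = p)),
            class = "GrangerResult")
}

#' Spectral (Geweke) pairwise Granger causality
#'
#' Fits one bivariate VAR(\code{p}) by OLS over the whole series and
#' evaluates the Geweke frequency-domain causality from the model transfer
#' function \eqn{H(f)} and residual covariance: for the direction
#' \eqn{X \to Y},
#' \eqn{f(f) = \ln[S_{yy}(f) / (S_{yy}(f) -
#' (\Sigma_{xx} - \Sigma_{xy}^2/\Sigma_{yy}) |H_{yx}(f)|^2)]}.
#' Nonnegative at all frequencies by construction (clamped at numerical
#' zero).
#'
#' @param x,y numeric vectors at rate \code{fs}.
#' @param fs sampling rate, Hz.
#' @param p model order (default 12).
#' @param nFreq number of frequency points on [0, fs/2] (default 129).
#' @return list of class \code{"GrangerSpectralResult"}: \code{freqs_hz},
#'   \code{gc_xy}, \code{gc_yx}, \code{Sigma}, \code{A} (list of lag
#'   coefficient matrices), \code{spectralRadius}, \code{stable}.
#' @export
grangerSpectral <- function(x, y, fs, p = 12, nFreq = 129) {
  n <- length(x)
  stopifnot(length(y) == n, n > 10 * p)
  xt <- x[(p + 1):n]; yt <- y[(p + 1):n]
  Z <- cbind(1, .lagEmbed(x, p), .lagEmbed(y, p))
  Tg <- cbind(xt, yt)
  B <- tryCatch(solve(crossprod(Z), crossprod(Z, Tg)),
                error = function(e) {
                  G <- crossprod(Z)
                  solve(G + diag(1e-10 * mean(diag(G)), ncol(G)),
                        crossprod(Z, Tg))
                })
  E <- Tg - Z %*% B
  Sigma <- crossprod(E) / (nrow(Z) - ncol(Z))
  if (rcond(Sigma) < 1e-12) {
    message("near-singular residual covariance: adding jitter 1e-10 * tr")
    Sigma <- Sigma + diag(1e-10 * sum(diag(Sigma)), 2)
  }
  # lag coefficient matrices A_k (2 x 2): rows = target (x, y)
  A <- lapply(seq_len(p), function(k) {
    rbind(c(B[1 + k, 1], B[1 + p + k, 1]),
          c(B[1 + k, 2], B[1 + p + k, 2]))
  })
  comp <- matrix(0, 2 * p, 2 * p)
  for (k in seq_len(p)) comp[1:2, (2 * k - 1):(2 * k)] <- A[[k]]
  if (p > 1) comp[3:(2 * p), 1:(2 * p - 2)] <- diag(2 * p - 2)
  sr <- max(Mod(eigen(comp, only.values = TRUE)$values))
  if (sr >= 1)
    warning("fitted VAR is unstable (spectral radius ", signif(sr, 4), ")")
  freqs <- seq(0, fs / 2, length.out = nFreq)
  gcxy <- numeric(nFreq); gcyx <- numeric(nFreq)
  s2xg <- Sigma[1, 1] - Sigma[1, 2]^2 / Sigma[2, 2]  # partial of x given y
  s2yg <- Sigma[2, 2] - Sigma[1, 2]^2 / Sigma[1, 1]
  for (i in seq_len(nFreq)) {
    Af <- diag(2) + 0i
    for (k in seq_len(p)) Af <- Af - A[[k]] * exp(-2i * pi * freqs[i] * k / fs)
    H <- solve(Af)
    S <- H %*% Sigma %*% Conj(t(H))
    gcxy[i] <- log(Re(S[2, 2]) /
                     max(Re(S[2, 2]) - s2xg * Mod(H[2, 1])^2,
                         .Machine$double.eps))
    gcyx[i] <- log(Re(S[1, 1]) /
                     max(Re(S[1, 1]) - s2yg * Mod(H[1, 2])^2,
                         .Machine$double.eps))
  }
  structure(list(freqs_hz = freqs, gc_xy = pmax(gcxy, 0),
                 gc_yx = pmax(gcyx, 0), Sigma = Sigma, A = A,
                 spectralRadius = sr, stable = sr < 1,
                 params = list(fs = fs, p = p)),
            class = "GrangerSpectralResult")
}

#' Block-resampling surrogate (single random cut, blocks swapped)
#'
#' Cuts the series at one uniformly random interior point and swaps the two
#' blocks, preserving the sample multiset and length exactly and nearly all
#' of the autocorrelation structure (only the seam changes).
#'
#' @param x numeric vector of length >= 2.
#' @param seed optional integer seed.
#' @return the permuted series.
#' @export
blockResample <- function(x, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(x)
  stopifnot(n >= 2)
  j <- sample.int(n - 1L, 1L)
  c(x[(j + 1L):n], x[seq_len(j)])
}

#' Surrogate significance for temporal Granger causality
#'
#' Builds the null by block-resampling the putative source (default) or both
#' inputs, recomputing the window-averaged statistic per surrogate with the
#' same windowing and window set as the observed run, fitting a normal
#' distribution to the surrogate statistics, and thresholding at its
#' \code{1 - alpha} quantile (the value where the fitted cumulative
#' distribution reaches \code{1 - alpha}).
#'
#' @param x,y numeric vectors at rate \code{fs}.
#' @param fs,window,overlap,p as in [grangerTemporal()].
#' @param nSurrogates surrogate count (default 1000).
#' @param alpha significance level (default 0.05).
#' @param resample \code{"source"} (resample only the putative source of the
#'   direction under test) or \code{"both"}.
#' @param seed optional integer seed.
#' @return list of class \code{"GrangerSignificance"}: the observed
#'   \code{"GrangerResult"} plus per-direction \code{threshold},
#'   \code{significant}, surrogate mean/SD, and parameters.
#' @export
grangerSignificance <- function(x, y, fs = 250, window = 5, overlap = 0.8,
                                p = 12, nSurrogates = 1000, alpha = 0.05,
                                resample = c("source", "both"),
                                seed = NULL) {
  resample <- match.arg(resample)
  if (!is.null(seed)) set.seed(seed)
  obs <- grangerTemporal(x, y, fs, window, overlap, p)
  stable <- obs$perWindow$stable
  n <- length(x)
  winRows <- .grangerWindows(n - p, fs, window, overlap)[stable]
  oneDir <- function(src, tgt) {
    # tgt's own past is fixed; src is block-resampled per surrogate
    tgtT <- tgt[(p + 1):n]
    Ltgt <- .lagEmbed(tgt, p)
    Fs <- numeric(nSurrogates)
    for (s in seq_len(nSurrogates)) {
      srcS <- blockResample(src)
      tgtS <- if (resample == "both") blockResample(tgt) else NULL
      if (is.null(tgtS)) {
        d <- .grangerFdir(tgtT, Ltgt, .lagEmbed(srcS, p), winRows, p)
      } else {
        d <- .grangerFdir(tgtS[(p + 1):n], .lagEmbed(tgtS, p),
                          .lagEmbed(srcS, p), winRows, p)
      }
      Fs[s] <- mean(d$Fw)
    }
    mu <- mean(Fs); sdv <- stats::sd(Fs)
    if (sdv == 0) stop("degenerate surrogate distribution (zero variance)")
    list(threshold = stats::qnorm(1 - alpha, mu, sdv), mu = mu, sd = sdv)
  }
  sxy <- oneDir(x, y)
  syx <- oneDir(y, x)
  structure(list(observed = obs,
                 F_xy = obs$F_xy, F_yx = obs$F_yx,
                 threshold_xy = sxy$threshold, threshold_yx = syx$threshold,
                 significant_xy = obs$F_xy > sxy$threshold,
                 significant_yx = obs$F_yx > syx$threshold,
                 surrogate_xy = c(mean = sxy$mu, sd = sxy$sd),
                 surrogate_yx = c(mean = syx$mu, sd = syx$sd),
                 nSurrogates = nSurrogates, alpha = alpha,
                 resample = resample),
            class = "GrangerSignificance")
}

#' @export
print.GrangerResult <- function(x, ...) {
  cat(sprintf("Granger (temporal): F_xy = %.4f, F_yx = %.4f over %d windows (%d excluded)\n",
              x$F_xy, x$F_yx, x$nWindowsUsed, x$nWindowsExcluded))
  invisible(x)
}

#' @export
print.GrangerSignificance <- function(x, ...) {
  cat(sprintf("Granger significance (%d block-resampling surrogates, alpha = %g):\n",
              x$nSurrogates, x$alpha))
  cat(sprintf("  X->Y: F = %.4f, threshold = %.4f, significant = %s\n",
              x$F_xy, x$threshold_xy, x$significant_xy))
  cat(sprintf("  Y->X: F = %.4f, threshold = %.4f, significant = %s\n",
              x$F_yx, x$threshold_yx, x$significant_yx))
  invisible(x)
}
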