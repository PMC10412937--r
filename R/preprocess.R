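#' Zero-phase Butterworth filtering
#'
#' Applies the magnitude-squared response of a 4th-order Butterworth filter
#' (the forward-backward, zero group delay response) in the frequency domain
#' with mirror padding. \code{highpass} at 0.5 Hz is the standard slow-artifact
#' removal step; \code{bandpass} 30--100 Hz isolates the gamma band of
#' generator time courses.
#'
#' @param x numeric vector, channels x time matrix, or \linkS4class{Recording}.
#' @param kind \code{"highpass"} or \code{"bandpass"}.
#' @param band cutoff(s) in Hz: one value for highpass, \code{c(low, high)}
#'   for bandpass.
#' @param fs sampling rate, Hz (taken from the Recording when given one).
#' @param order filter order (per pass), default 4.
#' @return Same shape/class as the input.
#' @examples
#' fs <- 1000; t <- seq(0, 2, by = 1/fs)
#' x <- sin(2 * pi * 10 * t) + 5
#' y <- filterSignal(x, "highpass", 0.5, fs)
#' @export
filterSignal <- function(x, kind = c("highpass", "bandpass"), band, fs = NULL,
                         order = 4L) {
  kind <- match.arg(kind)
  if (is(x, "Recording")) {
    out <- x
    out@samples <- filterSignal(x@samples, kind, band, x@fs, order)
    return(out)
  }
  if (is.null(fs)) stop("fs required for plain numeric input")
  if (any(band >= fs / 2))
    stop("parameter error: band edge at or above Nyquist (", fs / 2, " Hz)")
  if (any(band <= 0)) stop("parameter error: band edges must be positive")
  gainFun <- switch(kind,
    highpass = {
      if (length(band) != 1L) stop("highpass takes a single cutoff")
      function(f) .butterHP2(f, band, order)
    },
    bandpass = {
      if (length(band) != 2L || band[1] >= band[2])
        stop("bandpass takes c(low, high) with low < high")
      function(f) .butterHP2(f, band[1], order) * .butterLP2(f, band[2], order)
    }
  )
  fl <- band[1]
  npad <- min(if (is.matrix(x)) ncol(x) else length(x),
              max(2048L, ceiling(3 * fs / fl)))
  if (is.matrix(x)) {
    t(apply(x, 1L, .applyGain, fs = fs, gainFun = gainFun, npad = npad))
  } else {
    .applyGain(x, fs, gainFun, npad = npad)
  }
}

#' Resample a series or Recording to a lower rate
#'
#' Fourier-domain resampling with an ideal anti-alias cut at the new Nyquist
#' frequency. The target rate must make the output length integral
#' (rational ratio with respect to the input length); anything else is
#' rejected. Duration is preserved exactly and passband content (below 0.4 x
#' target rate) is untouched.
#'
#' @param x numeric vector, matrix (channels x time) or
#'   \linkS4class{Recording}.
#' @param targetFs target sampling rate, Hz; must be below the current rate.
#' @param fs current rate for plain numeric input.
#' @return Same class as input, at \code{targetFs}.
#' @export
downsampleRecording <- function(x, targetFs, fs = NULL) {
  if (is(x, "Recording")) {
    out <- x
    out@samples <- downsampleRecording(x@samples, targetFs, x@fs)
    out@fs <- targetFs
    return(out)
  }
  if (is.null(fs)) stop("fs required for plain numeric input")
  if (targetFs >= fs) stop("parameter error: targetFs must be below fs")
  n <- if (is.matrix(x)) ncol(x) else length(x)
  nOut <- n * targetFs / fs
  if (abs(nOut - round(nOut)) > 1e-6)
    stop("parameter error: non-rational resampling ratio (output length ",
         nOut, " is not integral)")
  nOut <- as.integer(round(nOut))
  if (is.matrix(x)) t(apply(x, 1L, .resampleFFT, nOut = nOut))
  else .resampleFFT(x, nOut)
}

#' Replace a faulty interior channel by its neighbours' mean
#'
#' Faulty interior sites are interpolated sample-wise as the arithmetic mean
#' of the two adjacent channels; faulty outer sites cannot be interpolated
#' and are rejected.
#'
#' @param x a \linkS4class{Recording}.
#' @param channel 1-based channel index; must have both neighbours.
#' @return The Recording with the channel replaced.
#' @export
interpolateChannel <- function(x, channel) {
  stopifnot(is(x, "Recording"))
  m <- nrow(x@samples)
  if (channel <= 1L || channel >= m)
    stop("rejection error: outer-site channels cannot be interpolated ",
         "(faulty outer recordings are rejected)")
  x@samples[channel, ] <- (x@samples[channel - 1L, ] +
                             x@samples[channel + 1L, ]) / 2
  x
}

#' Detect and mask large transient events (SPW stand-in)
#'
#' Flags contiguous intervals where the signal deviates from its median by
#' more than \code{k} robust standard deviations (median absolute deviation
#' x 1.4826), pads them by \code{pad} seconds, and returns the interval table
#' plus a logical mask. Downstream statistics
#' ([windowedPearson()], [coherenceWithSignificance()]) accept the mask and
#' skip windows/segments that touch an excluded interval.
#'
#' @param x numeric vector.
#' @param fs sampling rate, Hz.
#' @param k threshold in robust-SD multiples (default 5); \code{Inf} disables
#'   exclusion.
#' @param pad padding around each excluded interval, seconds (default 0.05).
#' @return list with \code{mask} (logical, TRUE = excluded), \code{intervals}
#'   (data.frame \code{onset_s}, \code{offset_s}, \code{label}) and
#'   \code{masked} (the series with excluded samples set to \code{NA}).
#' @export
excludeLargeEvents <- function(x, fs, k = 5, pad = 0.05) {
  stopifnot(k > 0)
  n <- length(x)
  baseline <- stats::median(x)
  rsd <- stats::mad(x)
  if (!is.finite(k) || rsd == 0) {
    hit <- rep(FALSE, n)
  } else {
    hit <- abs(x - baseline) > k * rsd
  }
  if (any(hit)) {
    padN <- round(pad * fs)
    r <- rle(hit)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    mask <- rep(FALSE, n)
    for (i in which(r$values)) {
      mask[max(1L, starts[i] - padN):min(n, ends[i] + padN)] <- TRUE
    }
  } else mask <- hit
  if (all(mask)) stop("degenerate input: all samples excluded")
  r <- rle(mask)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  iv <- which(r$values)
  intervals <- data.frame(
    onset_s = (starts[iv] - 1L) / fs,
    offset_s = ends[iv] / fs,
    label = rep("large_event", length(iv))
  )
  masked <- x
  masked[mask] <- NA_real_
  list(mask = mask, intervals = intervals, masked = masked)
}

#' Standard preprocessing of a Recording
#'
#' Convenience wrapper: 0.5 Hz high-pass, then down-sample to the analysis
#' rate. Mirrors the standard treatment of wide-band laminar recordings.
#'
#' @param x \linkS4class{Recording} or \linkS4class{BilateralRecording}.
#' @param highpassHz high-pass cutoff (default 0.5 Hz); \code{NULL} skips.
#' @param targetFs analysis rate (default 4000 Hz); \code{NULL} skips;
#'   ignored when already at or below the target.
#' @return Preprocessed object of the same class.
#' @export
preprocessRecording <- function(x, highpassHz = 0.5, targetFs = 4000) {
  if (is(x, "BilateralRecording")) {
    return(BilateralRecording(
      preprocessRecording(x@left, highpassHz, targetFs),
      preprocessRecording(x@right, highpassHz, targetFs)
    ))
  }
  stopifnot(is(x, "Recording"))
  if (!is.null(highpassHz)) x <- filterSignal(x, "highpass", highpassHz)
  if (!is.null(targetFs) && targetFs < x@fs)
    x <- downsampleRecording(x, targetFs)
  x
}
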