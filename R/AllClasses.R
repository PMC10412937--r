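#' @import methods
NULL

#' Recording: one laminar probe's multichannel field potentials
#'
#' Container for the voltages recorded along one linear probe: a channels x
#' time matrix in mV, the sampling rate, and the (uniformly spaced) recording
#' depths in micrometres. The probe geometry enters the current-source-density
#' estimate through the inter-site distance \code{h}; the channel dimension is
#' the spatial axis on which generator depth profiles live.
#'
#' @slot samples numeric matrix, channels x time samples, mV.
#' @slot fs sampling rate, Hz.
#' @slot depths per-channel depth, micrometres; must be uniformly spaced.
#' @slot side \code{"left"} or \code{"right"}.
#' @slot meta free-form named list (subject id, epoch id, ...).
#'
#' @exportClass Recording
setClass("Recording",
  representation(
    samples = "matrix",
    fs = "numeric",
    depths = "numeric",
    side = "character",
    meta = "list"
  )
)

setValidity("Recording", function(object) {
  msgs <- character(0)
  s <- object@samples
  if (!is.numeric(s) || nrow(s) < 2L)
    msgs <- c(msgs, "samples must be a numeric matrix with >= 2 channels")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msgs <- c(msgs, "fs must be a single positive number")
  if (length(object@depths) != nrow(s))
    msgs <- c(msgs, "depths must have one entry per channel")
  if (length(object@depths) >= 2L) {
    dd <- diff(object@depths)
    if (max(abs(dd - dd[1])) > 1e-9)
      msgs <- c(msgs, "depth spacing must be constant to within 1e-9 um")
    if (abs(dd[1]) <= 0)
      msgs <- c(msgs, "depth spacing must be non-zero")
  }
  if (!(object@side %in% c("left", "right")))
    msgs <- c(msgs, "side must be 'left' or 'right'")
  if (anyNA(s) || any(!is.finite(s)))
    msgs <- c(msgs, "samples must contain no non-finite values")
  if (length(msgs)) msgs else TRUE
})

#' Construct a Recording
#'
#' @param samples channels x time numeric matrix, mV.
#' @param fs sampling rate, Hz.
#' @param depths per-channel depth, micrometres. Defaults to 65 um spacing
#'   starting at 0 (the standard 32-site silicon probe pitch).
#' @param side \code{"left"} or \code{"right"}.
#' @param meta named list of free-form metadata.
#' @return A \linkS4class{Recording}.
#' @examples
#' rec <- Recording(matrix(rnorm(4 * 100), 4), fs = 1000)
#' nChannels(rec)
#' @export
Recording <- function(samples, fs, depths = NULL, side = "left", meta = list()) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (is.null(depths)) depths <- (seq_len(nrow(samples)) - 1) * 65
  new("Recording", samples = samples, fs = as.numeric(fs),
      depths = as.numeric(depths), side = side, meta = meta)
}

#' BilateralRecording: paired left/right homotopic probes
#'
#' @slot left,right \linkS4class{Recording} objects with equal sampling rate,
#'   channel count and duration.
#' @exportClass BilateralRecording
setClass("BilateralRecording",
  representation(left = "Recording", right = "Recording")
)

setValidity("BilateralRecording", function(object) {
  l <- object@left; r <- object@right
  msgs <- character(0)
  if (nrow(l@samples) != nrow(r@samples))
    msgs <- c(msgs, "pairing error: left and right channel counts differ")
  if (l@fs != r@fs)
    msgs <- c(msgs, "pairing error: left and right sampling rates differ")
  if (ncol(l@samples) != ncol(r@samples))
    msgs <- c(msgs, "pairing error: left and right durations differ")
  if (length(msgs)) msgs else TRUE
})

#' Construct a BilateralRecording from two single-probe recordings
#'
#' @param left,right \linkS4class{Recording} objects. Sides are forced to
#'   \code{"left"}/\code{"right"}.
#' @return A \linkS4class{BilateralRecording}.
#' @export
BilateralRecording <- function(left, right) {
  left@side <- "left"; right@side <- "right"
  new("BilateralRecording", left = left, right = right)
}

#' GeneratorSet: ICA decomposition of a laminar recording
#'
#' Holds the mixing model u_m(t) = sum_n V_mn s_n(t): the voltage loadings
#' (depth profiles, one column per generator), the generator time courses, and
#' the fraction of the recording's variance each generator reconstructs.
#' Profiles are canonicalized to unit Euclidean norm with the
#' largest-magnitude loading positive; amplitude and sign are carried by the
#' time course.
#'
#' @slot mixing channels x generators loading matrix (V_mn).
#' @slot timecourses generators x time matrix (s_n(t)).
#' @slot fs sampling rate of the time courses, Hz.
#' @slot varianceFraction per-generator fraction of total data variance.
#' @slot labels character generator labels.
#' @exportClass GeneratorSet
setClass("GeneratorSet",
  representation(
    mixing = "matrix",
    timecourses = "matrix",
    fs = "numeric",
    varianceFraction = "numeric",
    labels = "character"
  )
)

setValidity("GeneratorSet", function(object) {
  msgs <- character(0)
  ng <- ncol(object@mixing)
  if (nrow(object@timecourses) != ng)
    msgs <- c(msgs, "timecourses must have one row per mixing column")
  if (length(object@varianceFraction) != ng)
    msgs <- c(msgs, "one variance fraction per generator required")
  if (length(object@labels) != ng)
    msgs <- c(msgs, "one label per generator required")
  if (ng > 0) {
    nr <- sqrt(colSums(object@mixing^2))
    if (any(abs(nr - 1) > 1e-6))
      msgs <- c(msgs, "profiles must have unit Euclidean norm")
    for (j in seq_len(ng)) {
      v <- object@mixing[, j]
      if (v[which.max(abs(v))] < 0) {
        msgs <- c(msgs, "largest-magnitude loading must be positive")
        break
      }
    }
    if (any(object@varianceFraction < -1e-9 | object@varianceFraction > 1 + 1e-9))
      msgs <- c(msgs, "variance fractions must lie in [0, 1]")
    if (sum(object@varianceFraction) > 1 + 1e-6)
      msgs <- c(msgs, "variance fractions must sum to <= 1")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a GeneratorSet (canonicalizing profiles)
#'
#' Columns of \code{mixing} are rescaled to unit norm with the
#' largest-magnitude loading positive; the compensating scale/sign moves into
#' the time courses. Generators are ordered by decreasing variance fraction.
#'
#' @param mixing channels x generators loading matrix.
#' @param timecourses generators x time matrix.
#' @param fs sampling rate, Hz.
#' @param varianceFraction per-generator variance fractions (optional; zeros
#'   if missing).
#' @param labels generator labels (optional).
#' @return A \linkS4class{GeneratorSet}.
#' @export
GeneratorSet <- function(mixing, timecourses, fs,
                         varianceFraction = NULL, labels = NULL) {
  mixing <- as.matrix(mixing); timecourses <- as.matrix(timecourses)
  ng <- ncol(mixing)
  if (is.null(varianceFraction)) varianceFraction <- numeric(ng)
  if (is.null(labels)) labels <- paste0("G", seq_len(ng))
  for (j in seq_len(ng)) {
    nr <- sqrt(sum(mixing[, j]^2))
    if (nr == 0) stop("zero profile in mixing column ", j)
    sg <- sign(mixing[which.max(abs(mixing[, j])), j])
    if (sg == 0) sg <- 1
    mixing[, j] <- mixing[, j] / (nr * sg)
    timecourses[j, ] <- timecourses[j, ] * nr * sg
  }
  ord <- order(varianceFraction, decreasing = TRUE)
  new("GeneratorSet", mixing = mixing[, ord, drop = FALSE],
      timecourses = timecourses[ord, , drop = FALSE], fs = as.numeric(fs),
      varianceFraction = as.numeric(varianceFraction[ord]),
      labels = as.character(labels[ord]))
}

#' CSDMap: one-dimensional current-source density along the probe
#'
#' Rows are interior channels only (edge channels are omitted by the
#' second-difference formula); values are in conductivity-scaled units
#' sigma * mV / um^2.
#'
#' @slot values (channels - 2) x time matrix.
#' @slot sigma extracellular conductivity scale (arbitrary units).
#' @slot h inter-site distance, micrometres.
#' @slot fs sampling rate, Hz.
#' @slot depths depths of the interior channels, micrometres.
#' @exportClass CSDMap
setClass("CSDMap",
  representation(
    values = "matrix",
    sigma = "numeric",
    h = "numeric",
    fs = "numeric",
    depths = "numeric"
  )
)

setValidity("CSDMap", function(object) {
  msgs <- character(0)
  if (object@h <= 0) msgs <- c(msgs, "h must be positive")
  if (length(object@depths) != nrow(object@values))
    msgs <- c(msgs, "one depth per interior channel required")
  if (length(msgs)) msgs else TRUE
})
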