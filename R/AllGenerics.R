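#' @include AllClasses.R
NULL

#' Accessors for Recording and GeneratorSet objects
#'
#' \code{samples} returns the channels x time voltage matrix; \code{samplingRate}
#' the rate in Hz; \code{depths} the per-channel depths in micrometres;
#' \code{nChannels} the channel count; \code{recDuration} the duration in
#' seconds; \code{probeSide} the hemisphere label; \code{leftRecording} /
#' \code{rightRecording} the two probes of a bilateral pair; \code{mixing},
#' \code{timecourses}, \code{varianceFraction} and \code{generatorLabels} the
#' slots of a \linkS4class{GeneratorSet}; \code{csdValues} the interior-channel
#' CSD matrix.
#'
#' @param x the object.
#' @return The slot value named by the accessor.
#' @name accessors
#' @aliases samples samplingRate depths nChannels recDuration probeSide
#'   leftRecording rightRecording mixing timecourses varianceFraction
#'   generatorLabels csdValues
NULL

#' @rdname accessors
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("depths", function(x) standardGeneric("depths"))
#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setGeneric("recDuration", function(x) standardGeneric("recDuration"))
#' @rdname accessors
#' @export
setGeneric("probeSide", function(x) standardGeneric("probeSide"))
#' @rdname accessors
#' @export
setGeneric("leftRecording", function(x) standardGeneric("leftRecording"))
#' @rdname accessors
#' @export
setGeneric("rightRecording", function(x) standardGeneric("rightRecording"))
#' @rdname accessors
#' @export
setGeneric("mixing", function(x) standardGeneric("mixing"))
#' @rdname accessors
#' @export
setGeneric("timecourses", function(x) standardGeneric("timecourses"))
#' @rdname accessors
#' @export
setGeneric("varianceFraction", function(x) standardGeneric("varianceFraction"))
#' @rdname accessors
#' @export
setGeneric("generatorLabels", function(x) standardGeneric("generatorLabels"))
#' @rdname accessors
#' @export
setGeneric("csdValues", function(x) standardGeneric("csdValues"))

#' @rdname accessors
setMethod("samples", "Recording", function(x) x@samples)
#' @rdname accessors
setMethod("samplingRate", "Recording", function(x) x@fs)
#' @rdname accessors
setMethod("depths", "Recording", function(x) x@depths)
#' @rdname accessors
setMethod("nChannels", "Recording", function(x) nrow(x@samples))
#' @rdname accessors
setMethod("recDuration", "Recording", function(x) ncol(x@samples) / x@fs)
#' @rdname accessors
setMethod("probeSide", "Recording", function(x) x@side)
#' @rdname accessors
setMethod("leftRecording", "BilateralRecording", function(x) x@left)
#' @rdname accessors
setMethod("rightRecording", "BilateralRecording", function(x) x@right)
#' @rdname accessors
setMethod("samplingRate", "BilateralRecording", function(x) x@left@fs)
#' @rdname accessors
setMethod("nChannels", "BilateralRecording", function(x) nrow(x@left@samples))
#' @rdname accessors
setMethod("recDuration", "BilateralRecording",
          function(x) ncol(x@left@samples) / x@left@fs)
#' @rdname accessors
setMethod("mixing", "GeneratorSet", function(x) x@mixing)
#' @rdname accessors
setMethod("timecourses", "GeneratorSet", function(x) x@timecourses)
#' @rdname accessors
setMethod("samplingRate", "GeneratorSet", function(x) x@fs)
#' @rdname accessors
setMethod("varianceFraction", "GeneratorSet", function(x) x@varianceFraction)
#' @rdname accessors
setMethod("generatorLabels", "GeneratorSet", function(x) x@labels)
#' @rdname accessors
setMethod("csdValues", "CSDMap", function(x) x@values)

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording (%s): %d channels x %d samples at %g Hz (%.2f s)\n",
              object@side, nrow(object@samples), ncol(object@samples),
              object@fs, ncol(object@samples) / object@fs))
  cat(sprintf("  depths %g..%g um (spacing %g um)\n",
              min(object@depths), max(object@depths),
              diff(object@depths)[1]))
  if (length(object@meta))
    cat("  meta:", paste(names(object@meta), collapse = ", "), "\n")
  invisible(NULL)
})

setMethod("show", "BilateralRecording", function(object) {
  cat(sprintf("BilateralRecording: %d channels/side x %d samples at %g Hz\n",
              nrow(object@left@samples), ncol(object@left@samples),
              object@left@fs))
  invisible(NULL)
})

setMethod("show", "GeneratorSet", function(object) {
  ng <- ncol(object@mixing)
  cat(sprintf("GeneratorSet: %d generators on %d channels, %d samples at %g Hz\n",
              ng, nrow(object@mixing), ncol(object@timecourses), object@fs))
  if (ng) {
    cat(sprintf("  %-10s variance\n", "label"))
    for (j in seq_len(ng))
      cat(sprintf("  %-10s %6.2f%%\n", object@labels[j],
                  100 * object@varianceFraction[j]))
  }
  invisible(NULL)
})

setMethod("show", "CSDMap", function(object) {
  cat(sprintf("CSDMap: %d interior channels x %d samples (h = %g um, sigma = %g)\n",
              nrow(object@values), ncol(object@values), object@h, object@sigma))
  invisible(NULL)
})
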