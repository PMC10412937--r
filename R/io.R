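#' Write a Recording to a flat binary container with JSON sidecar
#'
#' The samples are stored column-major as little-endian float64 in
#' \code{<path>.bin}; all metadata (\code{fs}, \code{side}, \code{depths},
#' dimensions, \code{meta}) goes into \code{<path>.json}. The round trip is
#' bit-exact for the samples and lossless for metadata.
#'
#' @param x a \linkS4class{Recording}.
#' @param path file path without extension.
#' @return \code{path}, invisibly.
#' @seealso [readRecording()]
#' @export
writeRecording <- function(x, path) {
  stopifnot(is(x, "Recording"))
  sidecar <- list(
    format = "bilaminar-recording-v1",
    fs = x@fs,
    side = x@side,
    depths = x@depths,
    n_channels = nrow(x@samples),
    n_samples = ncol(x@samples),
    dtype = "float64",
    byte_order = "little",
    meta = x@meta
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(x@samples), con, size = 8L, endian = "little")
  invisible(path)
}

#' Read a Recording written by [writeRecording()]
#'
#' @param path file path without extension (expects \code{<path>.bin} and
#'   \code{<path>.json}).
#' @return A \linkS4class{Recording}.
#' @export
readRecording <- function(path) {
  jpath <- paste0(path, ".json")
  if (!file.exists(jpath)) stop("format error: sidecar not found: ", jpath)
  sc <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  req <- c("fs", "side", "depths", "n_channels", "n_samples")
  missing <- setdiff(req, names(sc))
  if (length(missing))
    stop("format error: sidecar lacks required field(s): ",
         paste(missing, collapse = ", "))
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  n <- sc$n_channels * sc$n_samples
  v <- readBin(con, "double", n = n, size = 8L, endian = "little")
  if (length(v) != n) stop("format error: binary payload truncated")
  meta <- if (is.null(sc$meta)) list() else as.list(sc$meta)
  Recording(matrix(v, sc$n_channels, sc$n_samples), fs = sc$fs,
            depths = sc$depths, side = sc$side, meta = meta)
}

#' Read/write event interval tables
#'
#' CSV with header \code{onset_s,offset_s,label}, as produced by
#' [excludeLargeEvents()].
#'
#' @param x data.frame with columns \code{onset_s}, \code{offset_s},
#'   \code{label}.
#' @param path CSV file path.
#' @return \code{readEventsCSV} returns the data.frame; \code{writeEventsCSV}
#'   returns \code{path} invisibly.
#' @export
writeEventsCSV <- function(x, path) {
  stopifnot(all(c("onset_s", "offset_s", "label") %in% names(x)))
  utils::write.csv(x[, c("onset_s", "offset_s", "label")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname writeEventsCSV
#' @export
readEventsCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("onset_s", "offset_s", "label") %in% names(df)))
    stop("format error: events CSV must have onset_s,offset_s,label header")
  df
}

#' Write/read a GeneratorSet container
#'
#' Same flat-binary-plus-JSON-sidecar layout as [writeRecording()]: the
#' mixing matrix and time courses go to \code{<path>_mixing.bin} and
#' \code{<path>_timecourses.bin} (column-major float64, little-endian);
#' dimensions, \code{fs}, variance fractions and labels go to
#' \code{<path>.json}.
#'
#' @param x a \linkS4class{GeneratorSet}.
#' @param path file path without extension.
#' @return \code{path} invisibly; \code{readGeneratorSet} returns the
#'   \linkS4class{GeneratorSet}.
#' @export
writeGeneratorSet <- function(x, path) {
  stopifnot(is(x, "GeneratorSet"))
  sidecar <- list(
    format = "bilaminar-generatorset-v1",
    fs = x@fs,
    n_channels = nrow(x@mixing),
    n_generators = ncol(x@mixing),
    n_samples = ncol(x@timecourses),
    variance_fraction = x@varianceFraction,
    labels = x@labels,
    dtype = "float64", byte_order = "little"
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  for (part in c("mixing", "timecourses")) {
    con <- file(paste0(path, "_", part, ".bin"), "wb")
    writeBin(as.vector(slot(x, part)), con, size = 8L, endian = "little")
    close(con)
  }
  invisible(path)
}

#' @rdname writeGeneratorSet
#' @export
readGeneratorSet <- function(path) {
  jpath <- paste0(path, ".json")
  if (!file.exists(jpath)) stop("format error: sidecar not found: ", jpath)
  sc <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  req <- c("fs", "n_channels", "n_generators", "n_samples")
  if (!all(req %in% names(sc)))
    stop("format error: sidecar lacks required field(s)")
  rd <- function(part, nr, nc) {
    con <- file(paste0(path, "_", part, ".bin"), "rb")
    on.exit(close(con))
    matrix(readBin(con, "double", nr * nc, size = 8L, endian = "little"),
           nr, nc)
  }
  GeneratorSet(rd("mixing", sc$n_channels, sc$n_generators),
               rd("timecourses", sc$n_generators, sc$n_samples),
               fs = sc$fs, varianceFraction = sc$variance_fraction,
               labels = sc$labels)
}

#' Export generator depth profiles as CSV
#'
#' One row per channel: \code{depth_um} then one loading column per
#' generator label.
#'
#' @param x a \linkS4class{GeneratorSet}.
#' @param depths per-channel depths, micrometres.
#' @param path CSV file path.
#' @return \code{path}, invisibly.
#' @export
writeProfilesCSV <- function(x, depths, path) {
  stopifnot(is(x, "GeneratorSet"), length(depths) == nrow(x@mixing))
  df <- data.frame(depth_um = depths, x@mixing)
  names(df)[-1] <- x@labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write/read a CSDMap container
#'
#' Serialized like a Recording with a \code{kind = "csd"} marker plus the
#' conductivity scale and inter-site distance.
#'
#' @param x a \linkS4class{CSDMap}.
#' @param path file path without extension.
#' @return \code{path} invisibly; \code{readCSDMap} returns the
#'   \linkS4class{CSDMap}.
#' @export
writeCSDMap <- function(x, path) {
  stopifnot(is(x, "CSDMap"))
  sidecar <- list(
    format = "bilaminar-recording-v1", kind = "csd",
    fs = x@fs, sigma = x@sigma, h = x@h, depths = x@depths,
    n_channels = nrow(x@values), n_samples = ncol(x@values),
    dtype = "float64", byte_order = "little"
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(x@values), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname writeCSDMap
#' @export
readCSDMap <- function(path) {
  jpath <- paste0(path, ".json")
  if (!file.exists(jpath)) stop("format error: sidecar not found: ", jpath)
  sc <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  if (is.null(sc$kind) || sc$kind != "csd")
    stop("format error: container is not a CSD map")
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  v <- readBin(con, "double", sc$n_channels * sc$n_samples, size = 8L,
               endian = "little")
  new("CSDMap", values = matrix(v, sc$n_channels, sc$n_samples),
      sigma = sc$sigma, h = sc$h, fs = sc$fs, depths = sc$depths)
}
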