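#' One-dimensional current-source density along the probe axis
#'
#' Discrete second spatial derivative of the voltage distribution:
#' \deqn{CSD_m(t) = -(\sigma/h^2)\,(u_{m-1}(t) - 2 u_m(t) + u_{m+1}(t))}
#' for interior channels m; edge channels are omitted. Channel-constant
#' (volume-conducted) contributions cancel exactly, which is the point of the
#' estimate: it localizes current sinks and sources while removing the
#' influence of sources away from the recording area. The extracellular
#' conductivity \eqn{\sigma} is an overall scale; results are reported in
#' sigma-scaled units.
#'
#' @param x a \linkS4class{Recording} or channels x time matrix (>= 3
#'   channels).
#' @param sigma conductivity scale (default 1).
#' @param h inter-site distance, micrometres (taken from the Recording's
#'   depths when omitted).
#' @param smooth logical; apply 3-point Hamming smoothing across channels
#'   (off by default; the raw second difference is the standard fast check).
#' @param fs sampling rate for matrix input (default 1).
#' @return A \linkS4class{CSDMap}.
#' @examples
#' u <- matrix(c(0, 1, 0), 3, 10)
#' csdValues(csd1d(u, sigma = 1, h = 1))[1, 1]  # 2
#' @export
csd1d <- function(x, sigma = 1, h = NULL, smooth = FALSE, fs = 1) {
  if (is(x, "Recording")) {
    dep <- x@depths
    if (is.null(h)) h <- abs(diff(dep)[1])
    fs <- x@fs
    u <- x@samples
  } else {
    u <- as.matrix(x)
    if (is.null(h)) stop("h required for matrix input")
    dep <- (seq_len(nrow(u)) - 1) * h
  }
  M <- nrow(u)
  if (M < 3) stop("CSD requires at least 3 channels")
  stopifnot(h > 0)
  if (smooth) {
    # 3-point Hamming window across channels (0.54, 0.23, 0.23 normalized)
    w <- c(0.23, 0.54, 0.23); w <- w / sum(w)
    us <- u
    us[2:(M - 1), ] <- w[1] * u[1:(M - 2), ] + w[2] * u[2:(M - 1), ] +
      w[3] * u[3:M, ]
    u <- us
  }
  vals <- -(sigma / h^2) *
    (u[1:(M - 2), , drop = FALSE] - 2 * u[2:(M - 1), , drop = FALSE] +
       u[3:M, , drop = FALSE])
  new("CSDMap", values = vals, sigma = sigma, h = h, fs = fs,
      depths = dep[2:(M - 1)])
}
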