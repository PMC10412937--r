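# PCA + ICA source separation of laminar field potentials.
#
# The decomposition follows the linear mixing model u_m(t) = sum_n V_mn s_n(t):
# PCA pre-reduction of the channel space, then a fixed-point ICA (symmetric
# FastICA with logcosh contrast, multi-restart, fixed seed) in the whitened
# space. Components are canonicalized (unit-norm profile, largest-|loading|
# positive, variance-ordered) so runs are comparable across hemispheres and
# epochs.

#' PCA reduction of a channels x time matrix
#'
#' @param data channels x time numeric matrix (or \linkS4class{Recording}).
#' @param retain either an integer component count, or a variance share in
#'   (0, 1) to be captured.
#' @return list with \code{scores} (k x time), \code{backProjection}
#'   (channels x k, orthonormal columns), \code{eigenvalues},
#'   \code{varianceCaptured}, \code{center}.
#' @export
pcaReduce <- function(data, retain) {
  if (is(data, "Recording")) data <- data@samples
  M <- nrow(data)
  ctr <- rowMeans(data)
  xc <- data - ctr
  cv <- tcrossprod(xc) / (ncol(xc) - 1)
  eg <- eigen(cv, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  tol <- max(ev) * 1e-12
  rank <- sum(ev > tol)
  if (retain >= 1) {
    k <- as.integer(retain)
    if (k > M) stop("parameter error: retain exceeds channel count")
    if (k > rank) stop("parameter error: retain (", k,
                       ") exceeds data rank (", rank, ")")
  } else {
    k <- which(cumsum(ev) / sum(ev) >= retain)[1]
  }
  E <- eg$vectors[, seq_len(k), drop = FALSE]
  list(scores = crossprod(E, xc), backProjection = E,
       eigenvalues = ev, varianceCaptured = sum(ev[seq_len(k)]) / sum(ev),
       center = ctr)
}

# symmetric FastICA on whitened data z (k x n); returns orthogonal W (k x k)
.fastICACore <- function(z, maxit = 500, tol = 1e-7) {
  k <- nrow(z); n <- ncol(z)
  W <- matrix(stats::rnorm(k * k), k)
  sy <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sy(W)
  for (it in seq_len(maxit)) {
    WX <- W %*% z
    G <- tanh(WX)
    gp <- rowMeans(1 - G^2)
    W1 <- tcrossprod(G, z) / n - diag(gp, k) %*% W
    W1 <- sy(W1)
    conv <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (conv < tol) return(list(W = W, converged = TRUE, iterations = it))
  }
  list(W = W, converged = FALSE, iterations = maxit)
}

#' ICA decomposition into field-potential generators
#'
#' Runs PCA whitening to \code{nComponents}, then symmetric FastICA with a
#' logcosh (nonparametric negentropy proxy) contrast; the best of
#' \code{restarts} runs (by summed negentropy proxy) is kept. Deterministic
#' given \code{seed}. In \code{"joint-bilateral"} mode the left and right
#' channel blocks of a \linkS4class{BilateralRecording} are stacked into one
#' data matrix so bilateral generators are separated jointly with a less
#' stringent reduction.
#'
#' @param x channels x time matrix, \linkS4class{Recording}, or
#'   \linkS4class{BilateralRecording}.
#' @param nComponents number of generators to extract.
#' @param mode \code{"per-shank"} (each probe separately; for a bilateral
#'   input returns a list with elements \code{left} and \code{right}) or
#'   \code{"joint-bilateral"}.
#' @param seed integer seed (required).
#' @param fs sampling rate for plain matrix input.
#' @param restarts number of random restarts (default 5).
#' @return A \linkS4class{GeneratorSet} (or a list of two in per-shank
#'   bilateral mode).
#' @export
runICA <- function(x, nComponents, mode = c("per-shank", "joint-bilateral"),
                   seed, fs = NULL, restarts = 5) {
  mode <- match.arg(mode)
  if (missing(seed)) stop("seed is required")
  if (is(x, "BilateralRecording")) {
    if (mode == "per-shank") {
      seeds <- .seedStream(seed, 2)
      return(list(left = runICA(x@left, nComponents, seed = seeds[1],
                                restarts = restarts),
                  right = runICA(x@right, nComponents, seed = seeds[2],
                                 restarts = restarts)))
    }
    data <- rbind(x@left@samples, x@right@samples)
    fs <- x@left@fs
  } else if (is(x, "Recording")) {
    data <- x@samples; fs <- x@fs
  } else {
    data <- as.matrix(x)
    if (is.null(fs)) stop("fs required for plain matrix input")
  }
  n <- ncol(data)
  if (n < 50 * nComponents)
    stop("need at least 50 x nComponents time samples")
  pc <- pcaReduce(data, nComponents)
  d <- pc$eigenvalues[seq_len(nComponents)]
  z <- pc$scores / sqrt(d)        # whitened (k x n)
  set.seed(seed)
  best <- NULL; bestScore <- -Inf; log <- character(0)
  for (r in seq_len(restarts)) {
    fit <- .fastICACore(z)
    s <- fit$W %*% z
    # negentropy proxy: (E[log cosh s] - E[log cosh gauss])^2 summed
    gconst <- 0.3745672  # E[log cosh Z], Z ~ N(0,1)
    score <- sum((rowMeans(log(cosh(s))) - gconst)^2)
    log <- c(log, sprintf("restart %d: converged=%s iter=%d score=%.4g",
                          r, fit$converged, fit$iterations, score))
    if (fit$converged && score > bestScore) {
      bestScore <- score; best <- fit
    }
  }
  if (is.null(best))
    stop("ICA failed to converge in ", restarts, " restarts:\n",
         paste(log, collapse = "\n"))
  W <- best$W
  S <- W %*% z                                    # sources, unit variance
  A <- pc$backProjection %*% (sqrt(d) * t(W))     # channel-space mixing
  # non-identifiability: all sources near-Gaussian
  kurt <- apply(S, 1, function(v) mean(v^4) / mean(v^2)^2 - 3)
  if (all(abs(kurt) < 0.2))
    warning("all components are near-Gaussian: ICA rotation is not ",
            "identifiable for Gaussian sources")
  vf <- .varianceFractions(A, S, data)
  gs <- GeneratorSet(A, S, fs = fs, varianceFraction = vf)
  attr(gs, "restartLog") <- log
  gs
}

# per-generator reconstruction variance / total data variance
.varianceFractions <- function(A, S, data) {
  tot <- sum(apply(data, 1, stats::var))
  vf <- colSums(A^2) * apply(S, 1, stats::var) / tot
  if (sum(vf) > 1) vf <- vf / sum(vf)
  vf
}

#' Drop generators below a relative-variance floor
#'
#' Recomputes each generator's variance fraction (variance of its
#' channel-space reconstruction over the total data variance) and removes
#' generators below \code{minFraction} (default 1\%).
#'
#' @param gs a \linkS4class{GeneratorSet}.
#' @param data the channels x time data (or \linkS4class{Recording}) the set
#'   was derived from.
#' @param minFraction retention threshold (default 0.01).
#' @return The filtered \linkS4class{GeneratorSet}.
#' @export
relativeVarianceFilter <- function(gs, data, minFraction = 0.01) {
  if (is(data, "Recording")) data <- data@samples
  vf <- .varianceFractions(gs@mixing, gs@timecourses, data)
  keep <- vf >= minFraction
  GeneratorSet(gs@mixing[, keep, drop = FALSE],
               gs@timecourses[keep, , drop = FALSE], fs = gs@fs,
               varianceFraction = vf[keep], labels = gs@labels[keep])
}

#' Match generator profiles across hemispheres
#'
#' Distance between two depth profiles is \code{1 - Pearson correlation} of
#' the loading vectors (range [0, 2]). Pairs are accepted best-distance-first
#' while the distance is below \code{threshold}; each generator joins at most
#' one pair. An average-linkage tree over the pooled profiles is returned for
#' inspection.
#'
#' @param profilesA,profilesB channels x generators loading matrices (equal
#'   channel counts), e.g. \code{mixing(gsLeft)}.
#' @param threshold acceptance distance (default 0.2).
#' @return list of class \code{"ProfileMatch"}: \code{pairs} (data.frame
#'   \code{a}, \code{b}, \code{distance}), \code{unmatchedA},
#'   \code{unmatchedB}, \code{tree} (an \code{hclust}).
#' @export
matchProfiles <- function(profilesA, profilesB, threshold = 0.2) {
  profilesA <- as.matrix(profilesA); profilesB <- as.matrix(profilesB)
  if (nrow(profilesA) != nrow(profilesB))
    stop("profile channel counts differ")
  na <- ncol(profilesA); nb <- ncol(profilesB)
  D <- 1 - suppressWarnings(stats::cor(profilesA, profilesB))
  D[is.na(D)] <- 2  # constant (flat) profiles: Pearson undefined, no match
  cand <- expand.grid(a = seq_len(na), b = seq_len(nb))
  cand$distance <- D[cbind(cand$a, cand$b)]
  cand <- cand[cand$distance < threshold, , drop = FALSE]
  cand <- cand[order(cand$distance), , drop = FALSE]
  freeA <- rep(TRUE, na); freeB <- rep(TRUE, nb)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (freeA[cand$a[i]] && freeB[cand$b[i]]) {
      keep[i] <- TRUE
      freeA[cand$a[i]] <- FALSE; freeB[cand$b[i]] <- FALSE
    }
  }
  pairs <- cand[keep, , drop = FALSE]
  rownames(pairs) <- NULL
  pooled <- cbind(profilesA, profilesB)
  colnames(pooled) <- c(paste0("A", seq_len(na)), paste0("B", seq_len(nb)))
  tree <- stats::hclust(stats::as.dist(1 - stats::cor(pooled)),
                        method = "average")
  structure(list(pairs = pairs, unmatchedA = which(freeA),
                 unmatchedB = which(freeB), tree = tree,
                 threshold = threshold), class = "ProfileMatch")
}

#' @export
print.ProfileMatch <- function(x, ...) {
  cat("ProfileMatch:", nrow(x$pairs), "pair(s) at distance <", x$threshold,
      "\n")
  if (nrow(x$pairs)) print(x$pairs)
  if (length(x$unmatchedA)) cat("unmatched A:",
                                paste(x$unmatchedA, collapse = ", "), "\n")
  if (length(x$unmatchedB)) cat("unmatched B:",
                                paste(x$unmatchedB, collapse = ", "), "\n")
  invisible(x)
}

#' Minimal epoch length for a stable bilateral correlation
#'
#' Computes the cross-correlation coefficient between two generator time
#' courses on epochs grown from the start of the record in \code{step}
#' increments, and returns the smallest length from which the coefficient
#' stays within \code{tol} (default 3\%) of the running mean over shorter
#' epochs.
#'
#' @param leftTc,rightTc numeric vectors at the same rate.
#' @param fs sampling rate, Hz.
#' @param step epoch-length increment, seconds (default 5).
#' @param tol relative stability tolerance (default 0.03).
#' @param maxLen maximum epoch length to consider, seconds (default: full
#'   record).
#' @return list: \code{length_s} (NA when not converged), \code{converged},
#'   \code{epochs_s}, \code{cc}.
#' @export
epochStabilityLength <- function(leftTc, rightTc, fs, step = 5, tol = 0.03,
                                 maxLen = NULL) {
  stopifnot(length(leftTc) == length(rightTc))
  if (is.null(maxLen)) maxLen <- length(leftTc) / fs
  stopifnot(length(leftTc) >= round(maxLen * fs))
  lens <- seq(step, maxLen + 1e-9, by = step)
  cc <- vapply(lens, function(L) {
    n <- round(L * fs)
    stats::cor(leftTc[seq_len(n)], rightTc[seq_len(n)])
  }, 0)
  runmean <- c(cc[1], vapply(seq_along(cc)[-1],
                             function(i) mean(cc[seq_len(i - 1)]), 0))
  ok <- abs(cc - runmean) <= tol * abs(runmean)
  stableFrom <- NA_integer_
  for (i in seq_along(ok)) {
    if (all(ok[i:length(ok)])) { stableFrom <- i; break }
  }
  list(length_s = if (is.na(stableFrom)) NA_real_ else lens[stableFrom],
       converged = !is.na(stableFrom), epochs_s = lens, cc = cc)
}

#' Align a recovered GeneratorSet to ground truth
#'
#' Best one-to-one assignment (greedy, best-similarity-first) between
#' recovered and true generators; reports per-pair absolute profile
#' similarity and time-course correlation. Profile similarity is the
#' uncentered correlation (cosine), which stays defined for flat
#' volume-conducted profiles where Pearson degenerates. Used by the
#' recovery benchmarks.
#'
#' @param gs a \linkS4class{GeneratorSet}.
#' @param trueMixing channels x generators true loading matrix.
#' @param trueTc true generators x time matrix.
#' @return data.frame: \code{true} (column index), \code{recovered},
#'   \code{profileR}, \code{tcR}.
#' @export
alignToTruth <- function(gs, trueMixing, trueTc) {
  nrmT <- sqrt(colSums(trueMixing^2)); nrmR <- sqrt(colSums(gs@mixing^2))
  P <- abs(crossprod(trueMixing, gs@mixing) / outer(nrmT, nrmR))
  nt <- ncol(trueMixing); nr <- ncol(gs@mixing)
  cand <- expand.grid(true = seq_len(nt), recovered = seq_len(nr))
  cand$absr <- P[cbind(cand$true, cand$recovered)]
  cand <- cand[order(-cand$absr), ]
  freeT <- rep(TRUE, nt); freeR <- rep(TRUE, nr)
  rows <- list()
  for (i in seq_len(nrow(cand))) {
    a <- cand$true[i]; b <- cand$recovered[i]
    if (freeT[a] && freeR[b]) {
      freeT[a] <- FALSE; freeR[b] <- FALSE
      rows[[length(rows) + 1L]] <- data.frame(
        true = a, recovered = b, profileR = cand$absr[i],
        tcR = abs(stats::cor(trueTc[a, ], gs@timecourses[b, ])))
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$true), ]
}
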