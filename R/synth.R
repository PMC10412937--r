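# Synthetic bilateral laminar scenes with full ground truth.
#
# The generative model is the linear mixing model itself: per-side generator
# time courses (baseline + pulse-like gamma/SPW events + band-limited slow
# waves), mixed into channels through fixed depth-loading profiles, plus iid
# sensor noise. Bilateral coupling is configurable per generator: a shared
# band-limited slow component solving the analytic coherence expression,
# probabilistic gamma-event pairing with onset jitter, and directed lagged
# influences.

#' Depth-loading profile specification
#'
#' \code{bump} is a Gaussian depth bump (a focal synaptic territory);
#' \code{reversing} changes polarity exactly once across the probe (a
#' dipolar source spanning a layer fold); \code{flat} loads all channels
#' identically (a volume-conducted remote contribution).
#'
#' @param kind \code{"bump"}, \code{"reversing"} or \code{"flat"}.
#' @param center centre channel (1-based) for bump profiles.
#' @param width width in channels (Gaussian SD).
#' @param reversal for reversing profiles: the loading changes sign between
#'   channels \code{reversal - 1} and \code{reversal}.
#' @param sign \code{+1} or \code{-1}: sign of the extremal loading.
#' @param asym for reversing profiles: width ratio of the lobe below the
#'   reversal to the lobe above it (default 0.6). Real dipolar profiles are
#'   asymmetric (the folded-layer maximum dominates); an exactly
#'   antisymmetric dipole would make the sign canonicalization of recovered
#'   profiles flip arbitrarily between its two equal lobes.
#' @return A list of class \code{"profileSpec"}.
#' @export
profileSpec <- function(kind = c("bump", "reversing", "flat"), center = NA,
                        width = 3, reversal = NA, sign = 1, asym = 0.6) {
  kind <- match.arg(kind)
  structure(list(kind = kind, center = center, width = width,
                 reversal = reversal, sign = sign, asym = asym),
            class = "profileSpec")
}

#' Build a loading matrix from profile specifications
#'
#' @param specs list of [profileSpec()] objects.
#' @param nChannels number of probe channels (>= 4).
#' @return channels x generators matrix; each column scaled to max |loading|
#'   = 1.
#' @export
makeProfiles <- function(specs, nChannels) {
  stopifnot(nChannels >= 4)
  cols <- lapply(specs, function(sp) {
    ch <- seq_len(nChannels)
    v <- switch(sp$kind,
      bump = {
        if (is.na(sp$center) || sp$center < 1 || sp$center > nChannels)
          stop("bump center out of channel range")
        exp(-(ch - sp$center)^2 / (2 * sp$width^2))
      },
      reversing = {
        if (is.na(sp$reversal) || sp$reversal < 2 || sp$reversal > nChannels)
          stop("reversal channel out of range")
        x0 <- sp$reversal - 0.5
        wch <- ifelse(ch > x0, sp$width, sp$width * sp$asym)
        (ch - x0) * exp(-(ch - x0)^2 / (2 * wch^2))
      },
      flat = rep(1, nChannels)
    )
    sp$sign * v / max(abs(v))
  })
  do.call(cbind, cols)
}

#' Generator dynamics specification
#'
#' @param label generator name.
#' @param baseline constant baseline level (arbitrary activation units).
#' @param gammaRate Poisson rate of pulse-like gamma events, events/s.
#' @param gammaDelta pulse time scale delta, seconds.
#' @param gammaWeight \code{c(meanlog, sdlog)} of the lognormal weight
#'   magnitude.
#' @param slowBand \code{c(low, high)} Hz of the slow-wave band.
#' @param slowPower variance of the slow component (activation units^2).
#' @param slowBouts logical; amplitude-modulate the slow band into bouts
#'   (suitable only for generators with low bilateral coherence targets,
#'   since the per-side envelopes are independent).
#' @param spwRate Poisson rate of sparse large SPW-like events, events/s.
#' @param spwAmp weight scale of SPW events.
#' @param polarity \code{"negative"} (negative-going events, the Schaffer
#'   motif) or \code{"positive"}.
#' @param inheritFrom optional label of a parent generator whose gamma events
#'   are partially inherited (amplitudes redrawn) -- a "noisy copy".
#' @param inheritProb probability that a parent event is inherited.
#' @param inheritJitterSd onset jitter SD of inherited events, seconds
#'   (default 0.01: synaptic transmission jitter, which keeps the inherited
#'   train statistically separable from its parent).
#' @param share target relative variance of this generator in the noiseless
#'   mixture (used by [simulateScene()]).
#' @return list of class \code{"generatorDynamics"}.
#' @export
generatorDynamics <- function(label, baseline = 0, gammaRate = 0,
                              gammaDelta = 0.008,
                              gammaWeight = c(meanlog = 0, sdlog = 0.3),
                              slowBand = c(0.5, 4), slowPower = 1,
                              slowBouts = FALSE,
                              spwRate = 0, spwAmp = 0,
                              polarity = c("negative", "positive"),
                              inheritFrom = NULL, inheritProb = 0.5,
                              inheritJitterSd = 0.01, share = 0.1) {
  polarity <- match.arg(polarity)
  stopifnot(gammaRate >= 0, gammaDelta > 0, spwRate >= 0, slowPower >= 0)
  structure(list(label = label, baseline = baseline, gammaRate = gammaRate,
                 gammaDelta = gammaDelta, gammaWeight = gammaWeight,
                 slowBand = slowBand, slowPower = slowPower,
                 slowBouts = slowBouts, spwRate = spwRate, spwAmp = spwAmp,
                 polarity = polarity, inheritFrom = inheritFrom,
                 inheritProb = inheritProb,
                 inheritJitterSd = inheritJitterSd, share = share),
            class = "generatorDynamics")
}

#' Bilateral coupling specification
#'
#' @param slowCoherence named numeric vector in [0, 1): per-generator target
#'   magnitude-squared coherence of the slow band between hemispheres.
#'   A target of exactly 1 is rejected: every generator carries independent
#'   per-side components (events, sensor noise), so unit coherence is not
#'   constructible.
#' @param gammaPairingProb named or scalar probability in [0, 1] that a gamma
#'   event has a bilateral partner.
#' @param pairingJitterSd SD of the paired-onset jitter, seconds.
#' @param links list of directed lagged influences, each
#'   \code{list(from, fromSide, to, toSide, lagSamples, gain)} with generator
#'   labels and sides \code{"left"}/\code{"right"}.
#' @return list of class \code{"couplingSpec"}.
#' @export
couplingSpec <- function(slowCoherence = numeric(0), gammaPairingProb = 0.5,
                         pairingJitterSd = 0.002, links = list()) {
  stopifnot(all(slowCoherence >= 0), all(gammaPairingProb >= 0),
            all(gammaPairingProb <= 1), pairingJitterSd >= 0)
  if (any(slowCoherence >= 1))
    stop("construction error: coherence target 1 is unattainable with ",
         "nonzero independent per-side components")
  for (lk in links) {
    if (is.null(lk$lagSamples) || lk$lagSamples < 1)
      stop("directed link lags must be >= 1 sample")
  }
  structure(list(slowCoherence = slowCoherence,
                 gammaPairingProb = gammaPairingProb,
                 pairingJitterSd = pairingJitterSd, links = links),
            class = "couplingSpec")
}

# render sum_k w_k f(t - tau_k; delta_k) into a length-n series
.renderPulses <- function(n, fs, w, tau, delta) {
  out <- numeric(n)
  for (k in seq_along(w)) {
    i0 <- floor(tau[k] * fs) + 1L
    i1 <- min(n, ceiling((tau[k] + 5 * delta[k]) * fs) + 1L)
    if (i0 > n || i1 < 1L) next
    i0 <- max(1L, i0)
    tt <- (seq(i0, i1) - 1) / fs - tau[k]
    out[i0:i1] <- out[i0:i1] + w[k] * pulseTemplate(tt, delta[k])
  }
  out
}

.lookupCoupling <- function(v, label, default) {
  if (length(v) == 0) return(default)
  if (is.null(names(v))) return(v[1])
  if (label %in% names(v)) return(unname(v[label]))
  default
}

#' Simulate per-side generator time courses with ground truth
#'
#' Event onsets are Poisson; paired events share onsets up to jitter; the
#' slow band is a shared-plus-independent Gaussian mixture whose shared gain
#' solves the analytic coherence expression
#' \eqn{C = (a^2/(a^2+b^2))^2}; directed links add a lagged, scaled copy of
#' the source time course to the target.
#'
#' @param dyn list of [generatorDynamics()] (parents before inheritors).
#' @param coupling a [couplingSpec()].
#' @param duration seconds; \code{duration * fs} must be >= 1e4 samples.
#' @param fs sampling rate, Hz.
#' @param seed integer seed (required: reproducibility contract).
#' @return list with elements \code{left}, \code{right} (generators x time
#'   matrices), \code{events} (data.frame: side, generator, kind, w, tau_s,
#'   delta_s, pair_id), \code{labels}.
#' @export
simulateTimecourses <- function(dyn, coupling, duration, fs, seed) {
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  n <- round(duration * fs)
  if (n < 1e4) stop("duration * fs must be >= 1e4 samples")
  labels <- vapply(dyn, `[[`, "", "label")
  G <- length(dyn)
  left <- matrix(0, G, n); right <- matrix(0, G, n)
  events <- list()
  motherStore <- list()
  pairCounter <- 0L
  for (g in seq_len(G)) {
    d <- dyn[[g]]
    sgn <- if (d$polarity == "negative") -1 else 1
    pPair <- .lookupCoupling(coupling$gammaPairingProb, d$label, 0.5)
    jit <- coupling$pairingJitterSd
    # --- gamma events -----------------------------------------------------
    mothers <- numeric(0)
    if (!is.null(d$inheritFrom)) {
      par <- motherStore[[d$inheritFrom]]
      if (is.null(par)) stop("inheritFrom generator must precede inheritor")
      mothers <- par[stats::runif(length(par)) < d$inheritProb]
      mothers <- pmin(pmax(
        mothers + stats::rnorm(length(mothers), 0, d$inheritJitterSd), 0),
        duration)
    }
    own <- sort(stats::runif(stats::rpois(1, d$gammaRate * duration),
                             0, duration))
    mothers <- sort(c(mothers, own))
    motherStore[[d$label]] <- mothers
    nm <- length(mothers)
    evL <- evR <- NULL
    if (nm > 0) {
      wL <- sgn * stats::rlnorm(nm, d$gammaWeight[1], d$gammaWeight[2])
      dL <- d$gammaDelta * exp(stats::rnorm(nm, 0, 0.1))
      paired <- stats::runif(nm) < pPair
      pid <- rep(NA_integer_, nm)
      pid[paired] <- pairCounter + seq_len(sum(paired))
      pairCounter <- pairCounter + sum(paired)
      evL <- data.frame(side = "left", generator = d$label, kind = "gamma",
                        w = wL, tau_s = mothers, delta_s = dL, pair_id = pid)
      if (any(paired)) {
        tr <- mothers[paired] + stats::rnorm(sum(paired), 0, jit)
        tr <- pmin(pmax(tr, 0), duration)
        evR <- data.frame(side = "right", generator = d$label, kind = "gamma",
                          w = sgn * stats::rlnorm(sum(paired),
                                                  d$gammaWeight[1],
                                                  d$gammaWeight[2]),
                          tau_s = tr,
                          delta_s = d$gammaDelta *
                            exp(stats::rnorm(sum(paired), 0, 0.1)),
                          pair_id = pid[paired])
      }
      nIndep <- stats::rpois(1, d$gammaRate * duration * (1 - pPair))
      if (nIndep > 0) {
        evR <- rbind(evR, data.frame(
          side = "right", generator = d$label, kind = "gamma",
          w = sgn * stats::rlnorm(nIndep, d$gammaWeight[1], d$gammaWeight[2]),
          tau_s = sort(stats::runif(nIndep, 0, duration)),
          delta_s = d$gammaDelta * exp(stats::rnorm(nIndep, 0, 0.1)),
          pair_id = NA_integer_))
      }
    }
    # --- SPW-like events (always paired, wide and large) ------------------
    if (d$spwRate > 0) {
      ns <- stats::rpois(1, d$spwRate * duration)
      if (ns > 0) {
        ts <- sort(stats::runif(ns, 0, duration))
        ds <- stats::runif(ns, 0.03, 0.06)
        pid <- pairCounter + seq_len(ns); pairCounter <- pairCounter + ns
        mk <- function(side, tau) data.frame(
          side = side, generator = d$label, kind = "spw",
          w = sgn * d$spwAmp * exp(stats::rnorm(ns, 0, 0.2)),
          tau_s = tau, delta_s = ds, pair_id = pid)
        evL <- rbind(evL, mk("left", ts))
        evR <- rbind(evR, mk("right",
                             pmin(pmax(ts + stats::rnorm(ns, 0, jit), 0),
                                  duration)))
      }
    }
    evg <- rbind(evL, evR)
    if (!is.null(evg) && nrow(evg)) {
      events[[length(events) + 1L]] <- evg
      li <- evg$side == "left"
      left[g, ] <- left[g, ] +
        .renderPulses(n, fs, evg$w[li], evg$tau_s[li], evg$delta_s[li])
      right[g, ] <- right[g, ] +
        .renderPulses(n, fs, evg$w[!li], evg$tau_s[!li], evg$delta_s[!li])
    }
    # --- slow band --------------------------------------------------------
    if (d$slowPower > 0) {
      coh <- .lookupCoupling(coupling$slowCoherence, d$label, 0)
      a <- sqrt(sqrt(coh)); b <- sqrt(1 - a^2)
      zs <- .bandNoise(n, fs, d$slowBand)
      zl <- .bandNoise(n, fs, d$slowBand)
      zr <- .bandNoise(n, fs, d$slowBand)
      sl <- a * zs + b * zl
      sr <- a * zs + b * zr
      if (d$slowBouts) {
        envL <- pmax(0, .bandNoise(n, fs, c(0.05, 0.3)))
        envR <- pmax(0, .bandNoise(n, fs, c(0.05, 0.3)))
        sl <- sl * envL / stats::sd(sl * envL)
        sr <- sr * envR / stats::sd(sr * envR)
      }
      left[g, ] <- left[g, ] + sqrt(d$slowPower) * sl
      right[g, ] <- right[g, ] + sqrt(d$slowPower) * sr
    }
    left[g, ] <- left[g, ] + d$baseline
    right[g, ] <- right[g, ] + d$baseline
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(side = character(0), generator = character(0),
               kind = character(0), w = numeric(0), tau_s = numeric(0),
               delta_s = numeric(0), pair_id = integer(0))
  rownames(events) <- NULL
  list(left = left, right = right, events = events, labels = labels)
}

#' Mix time courses into a bilateral recording
#'
#' \code{samples = profiles \%*\% timecourses + noise}; the exact noiseless
#' product, noise SD and all inputs are stored in the returned ground truth.
#'
#' @param profiles channels x generators loading matrix (shared by both
#'   sides).
#' @param tc list with \code{left}, \code{right} generator x time matrices.
#' @param noiseSd iid Gaussian sensor noise SD, mV.
#' @param fs sampling rate, Hz.
#' @param depthSpacing inter-site distance, micrometres (default 65).
#' @return list with \code{recording} (\linkS4class{BilateralRecording}) and
#'   \code{truth} (mixing, timecourses, noiseSd).
#' @export
mixAndRecord <- function(profiles, tc, noiseSd, fs, depthSpacing = 65) {
  stopifnot(ncol(profiles) == nrow(tc$left), nrow(tc$left) == nrow(tc$right))
  M <- nrow(profiles); n <- ncol(tc$left)
  dep <- (seq_len(M) - 1) * depthSpacing
  mkSide <- function(s, side) {
    x <- profiles %*% s
    if (noiseSd > 0) x <- x + matrix(stats::rnorm(M * n, 0, noiseSd), M, n)
    Recording(x, fs = fs, depths = dep, side = side)
  }
  rec <- BilateralRecording(mkSide(tc$left, "left"), mkSide(tc$right, "right"))
  list(recording = rec,
       truth = list(mixing = profiles, timecourses = tc, noiseSd = noiseSd))
}

#' Default six-generator bilateral scene
#'
#' Emulates the canonical laminar decomposition of CA1/dentate recordings:
#' Schaffer (st. radiatum bump, negative-going gamma on a stable baseline,
#' sparse SPWs, strong bilateral gamma pairing), lacunosum-moleculare (slow
#' coherent waves), medial perforant path (polarity-reversing profile,
#' strongly coherent slow band), lateral perforant path (alpha-band bouts,
#' weakly coherent -- the lateralized input), granule-cell somatic generator
#' (a noisy copy of LPP's events), and a flat volume-conducted remote
#' generator.
#'
#' @param nChannels probe channels per side (default 32).
#' @param duration seconds (default 60).
#' @param fs sampling rate, Hz (default 1000: the analysis rate of the
#'   recovery benchmark).
#' @param noiseSd sensor noise SD, mV (default 0.04).
#' @return list of class \code{"sceneSpec"} with \code{profiles}, \code{dyn},
#'   \code{coupling} and the scalars above.
#' @export
defaultScene <- function(nChannels = 32, duration = 60, fs = 1000,
                         noiseSd = 0.04) {
  profiles <- list(
    Sch    = profileSpec("bump", center = round(nChannels * 0.25), width = 2.5),
    LM     = profileSpec("bump", center = round(nChannels * 0.41), width = 3),
    MPP    = profileSpec("reversing", reversal = round(nChannels * 0.69),
                         width = 3),
    LPP    = profileSpec("bump", center = round(nChannels * 0.81), width = 3),
    GCsom  = profileSpec("bump", center = round(nChannels * 0.625), width = 2),
    remote = profileSpec("flat")
  )
  dyn <- list(
    generatorDynamics("Sch", baseline = 0.5, gammaRate = 20,
                      gammaDelta = 0.008, slowBand = c(0.5, 4),
                      slowPower = 0.4, spwRate = 0.3, spwAmp = 4,
                      polarity = "negative", share = 0.30),
    generatorDynamics("LM", gammaRate = 10, gammaDelta = 0.010,
                      slowBand = c(1, 8), slowPower = 1.2,
                      polarity = "negative", share = 0.25),
    generatorDynamics("MPP", gammaRate = 12, gammaDelta = 0.008,
                      slowBand = c(0.5, 4), slowPower = 1,
                      polarity = "positive", share = 0.15),
    generatorDynamics("LPP", gammaRate = 12, gammaDelta = 0.008,
                      slowBand = c(8, 12), slowPower = 1, slowBouts = TRUE,
                      polarity = "positive", share = 0.12),
    generatorDynamics("GCsom", gammaRate = 6, gammaDelta = 0.009,
                      slowBand = c(1, 5), slowPower = 0.5,
                      polarity = "negative",
                      inheritFrom = "LPP", inheritProb = 0.5, share = 0.08),
    generatorDynamics("remote", gammaRate = 0, slowBand = c(0.5, 2),
                      slowPower = 1, polarity = "positive", share = 0.05)
  )
  # LPP dynamics must precede GCsom (inheritance); reorder accordingly
  ord <- c("Sch", "LM", "MPP", "LPP", "GCsom", "remote")
  dyn <- dyn[match(ord, vapply(dyn, `[[`, "", "label"))]
  coupling <- couplingSpec(
    slowCoherence = c(Sch = 0.6, LM = 0.7, MPP = 0.8, LPP = 0.05,
                      GCsom = 0.3, remote = 0.5),
    gammaPairingProb = c(Sch = 0.8, LM = 0.2, MPP = 0.3, LPP = 0.1,
                         GCsom = 0.1, remote = 0),
    pairingJitterSd = 0.002
  )
  structure(list(profiles = profiles[ord], dyn = dyn, coupling = coupling,
                 nChannels = nChannels, duration = duration, fs = fs,
                 noiseSd = noiseSd), class = "sceneSpec")
}

#' Simulate a scene into a bilateral recording with ground truth
#'
#' Time courses are rescaled so that each generator's relative variance in
#' the noiseless mixture equals its configured \code{share} exactly (event
#' weights are rescaled consistently); directed links are applied after
#' scaling.
#'
#' @param scene a scene list as from [defaultScene()].
#' @param seed integer seed; the same seed reproduces the scene bit-exactly.
#' @return list with \code{recording} (\linkS4class{BilateralRecording}) and
#'   \code{truth}: mixing matrix, per-side time courses, event table,
#'   realized pairing, links, noise SD, configured shares.
#' @export
simulateScene <- function(scene, seed) {
  if (missing(seed)) stop("seed is required")
  profiles <- makeProfiles(scene$profiles, scene$nChannels)
  colnames(profiles) <- names(scene$profiles)
  sim <- simulateTimecourses(scene$dyn, scene$coupling, scene$duration,
                             scene$fs, seed)
  shares <- vapply(scene$dyn, `[[`, 0, "share")
  pn2 <- colSums(profiles^2)
  for (g in seq_along(scene$dyn)) {
    for (side in c("left", "right")) {
      tcg <- sim[[side]][g, ]
      q <- pn2[g] * stats::var(tcg)
      lam <- if (q > 0) sqrt(shares[g] / q) else 1
      sim[[side]][g, ] <- tcg * lam
      sel <- sim$events$generator == sim$labels[g] & sim$events$side == side
      sim$events$w[sel] <- sim$events$w[sel] * lam
    }
  }
  # directed lagged influences, applied on the scaled time courses
  for (lk in scene$coupling$links) {
    gi <- match(lk$from, sim$labels); gj <- match(lk$to, sim$labels)
    src <- sim[[lk$fromSide]][gi, ]
    lag <- lk$lagSamples
    shifted <- c(rep(0, lag), src[seq_len(length(src) - lag)])
    sim[[lk$toSide]][gj, ] <- sim[[lk$toSide]][gj, ] +
      lk$gain * (shifted - mean(shifted))
  }
  mr <- mixAndRecord(profiles, list(left = sim$left, right = sim$right),
                     scene$noiseSd, scene$fs)
  pairing <- stats::na.omit(unique(sim$events[, c("pair_id", "generator")]))
  mr$truth$events <- sim$events
  mr$truth$pairing <- pairing
  mr$truth$links <- scene$coupling$links
  mr$truth$labels <- sim$labels
  mr$truth$shares <- shares
  mr$truth$scene <- scene
  mr
}

#' Export / import a scene specification as JSON
#'
#' @param scene a \code{"sceneSpec"} list.
#' @param path JSON file path.
#' @return \code{importScene} returns the scene; \code{exportScene} the path,
#'   invisibly.
#' @export
exportScene <- function(scene, path) {
  out <- unclass(scene)
  # named atomic vectors must become JSON objects, not bare arrays
  asObj <- function(v) if (is.null(names(v))) v else as.list(v)
  out$coupling <- unclass(out$coupling)
  out$coupling$slowCoherence <- asObj(out$coupling$slowCoherence)
  out$coupling$gammaPairingProb <- asObj(out$coupling$gammaPairingProb)
  out$dyn <- lapply(out$dyn, function(d) {
    d <- unclass(d)
    d$gammaWeight <- asObj(d$gammaWeight)
    d
  })
  out$profiles <- lapply(out$profiles, unclass)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}

#' @rdname exportScene
#' @export
importScene <- function(path) {
  sc <- jsonlite::read_json(path, simplifyVector = FALSE)
  sc$profiles <- lapply(sc$profiles, function(p) {
    p <- lapply(p, function(v) if (is.null(v)) NA else v)
    do.call(profileSpec, p)
  })
  sc$dyn <- lapply(sc$dyn, function(d) {
    d$gammaWeight <- unlist(d$gammaWeight)
    d$slowBand <- unlist(d$slowBand)
    d$slowBouts <- isTRUE(d$slowBouts)
    # NULL round-trips through JSON as an empty container
    if (length(d$inheritFrom) == 0) d$inheritFrom <- NULL else
      d$inheritFrom <- as.character(d$inheritFrom)
    do.call(generatorDynamics, d)
  })
  cp <- sc$coupling
  sc$coupling <- couplingSpec(unlist(cp$slowCoherence),
                              unlist(cp$gammaPairingProb),
                              as.numeric(cp$pairingJitterSd),
                              if (is.null(cp$links)) list() else
                                lapply(cp$links, as.list))
  for (f in c("nChannels", "duration", "fs", "noiseSd"))
    sc[[f]] <- as.numeric(sc[[f]])
  structure(sc, class = "sceneSpec")
}
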