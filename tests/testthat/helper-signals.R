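# Shared fixtures, all generated in code.

sineWave <- function(freqHz, durS, fs, phase = 0) {
  sin(2 * pi * freqHz * (0:(round(durS * fs) - 1)) / fs + phase)
}

ar1Series <- function(n, phi = 0.5) {
  as.numeric(stats::arima.sim(list(ar = phi), n))
}

# Laplacian (super-Gaussian) iid source
rlaplace <- function(n) {
  u <- stats::runif(n, -0.5, 0.5)
  -sign(u) * log(1 - 2 * abs(u)) / sqrt(2)
}

# tiny two-generator bilateral scene for fast end-to-end runs
smallScene <- function(duration = 60, fs = 250, nChannels = 16,
                       cohA = 0.8, cohB = 0.0) {
  sc <- defaultScene(nChannels = nChannels, duration = duration, fs = fs,
                     noiseSd = 0.02)
  keep <- c("MPP", "LPP")
  sc$profiles <- list(
    MPP = profileSpec("bump", center = round(nChannels * 0.3), width = 2.5),
    LPP = profileSpec("bump", center = round(nChannels * 0.7), width = 2.5)
  )
  sc$dyn <- list(
    generatorDynamics("MPP", gammaRate = 10, gammaDelta = 0.01,
                      slowBand = c(0.5, 4), slowPower = 1,
                      polarity = "positive", share = 0.5),
    generatorDynamics("LPP", gammaRate = 10, gammaDelta = 0.01,
                      slowBand = c(0.5, 4), slowPower = 1,
                      polarity = "positive", share = 0.45)
  )
  sc$coupling <- couplingSpec(
    slowCoherence = c(MPP = cohA, LPP = cohB),
    gammaPairingProb = c(MPP = 0.5, LPP = 0.1),
    pairingJitterSd = 0.002
  )
  sc
}

# brute-force maximum-overlap assignment oracle for event pairing
# (independent of the package's component-wise branch and bound)
bruteForcePairs <- function(eventsLeft, eventsRight, minOverlap = 0.7) {
  supp <- function(df) cbind(df$tau_s, df$tau_s + 3 * df$delta_s)
  sl <- supp(eventsLeft); sr <- supp(eventsRight)
  nl <- nrow(sl); nr <- nrow(sr)
  frac <- matrix(0, max(nl, 1), max(nr, 1))
  for (i in seq_len(nl)) for (j in seq_len(nr)) {
    inter <- max(0, min(sl[i, 2], sr[j, 2]) - max(sl[i, 1], sr[j, 1]))
    frac[i, j] <- inter / min(sl[i, 2] - sl[i, 1], sr[j, 2] - sr[j, 1])
  }
  best <- list(score = -1, tie = Inf, pairs = NULL)
  assign1 <- function(i, usedR, acc, score, tie) {
    if (i > nl) {
      if (score > best$score ||
          (score == best$score && tie < best$tie)) {
        best <<- list(score = score, tie = tie, pairs = acc)
      }
      return(invisible(NULL))
    }
    assign1(i + 1, usedR, acc, score, tie)
    for (j in setdiff(which(frac[i, ] >= minOverlap), usedR)) {
      assign1(i + 1, c(usedR, j), rbind(acc, c(i, j)),
              score + frac[i, j],
              tie + abs(eventsLeft$tau_s[i] - eventsRight$tau_s[j]))
    }
  }
  if (nl && nr) assign1(1, integer(0), NULL, 0, 0)
  best
}

randomEventList <- function(n, durS = 1) {
  data.frame(tau_s = sort(stats::runif(n, 0, durS)),
             delta_s = stats::runif(n, 0.004, 0.012))
}
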