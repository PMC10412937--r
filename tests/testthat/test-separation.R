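test_that("PCA reduction captures the requested variance", {
  set.seed(1)
  # exact rank-2 data
  A <- matrix(rnorm(8 * 2), 8)
  S <- matrix(rnorm(2 * 5000), 2)
  pc <- pcaReduce(A %*% S, retain = 2)
  expect_gt(pc$varianceCaptured, 0.9999)
  # white noise, retain 90% variance: count near 0.9 * channels
  X <- matrix(rnorm(32 * 20000), 32)
  pc2 <- pcaReduce(X, retain = 0.9)
  expect_true(nrow(pc2$scores) >= 24 && nrow(pc2$scores) <= 32)
  expect_error(pcaReduce(X, retain = 64), "retain")
  expect_error(pcaReduce(A %*% S, retain = 5), "rank")
})

test_that("ICA recovers identity mixing of Laplacian sources", {
  set.seed(2)
  S <- rbind(rlaplace(6000), rlaplace(6000))
  gs <- runICA(S, 2, seed = 3, fs = 1000)
  al <- alignToTruth(gs, diag(2), S)
  expect_true(all(al$profileR >= 0.99))
  expect_true(all(al$tcR >= 0.99))
})

test_that("ICA recovers a known 4x4 mixing of super-Gaussian sources", {
  set.seed(4)
  n <- 60 * 1000
  S <- matrix(rlaplace(4 * n), 4)
  A <- matrix(rnorm(16), 4)
  gs <- runICA(A %*% S, 4, seed = 5, fs = 1000)
  al <- alignToTruth(gs, A, S)
  expect_true(all(al$profileR >= 0.95))
  expect_true(all(al$tcR >= 0.90))
})

test_that("Gaussian sources trigger the non-identifiability warning", {
  set.seed(6)
  S <- matrix(rnorm(2 * 8000), 2)
  expect_warning(runICA(S, 2, seed = 7, fs = 1000), "Gaussian")
})

test_that("run_ica is invariant to channel permutation after alignment", {
  set.seed(8)
  n <- 20000
  S <- matrix(rlaplace(3 * n), 3)
  A <- matrix(rnorm(18), 6)
  X <- A %*% S
  gs1 <- runICA(X, 3, seed = 9, fs = 1000)
  perm <- c(4, 2, 6, 1, 3, 5)
  gs2 <- runICA(X[perm, ], 3, seed = 9, fs = 1000)
  al1 <- alignToTruth(gs1, A, S)
  al2 <- alignToTruth(gs2, A[perm, ], S)
  expect_equal(al1$tcR, al2$tcR, tolerance = 0.05)
  expect_true(all(al2$profileR >= 0.95))
})

test_that("variance fractions follow reconstruction power and the 1% filter", {
  set.seed(10)
  n <- 20000
  # single noiseless source: fraction 1
  s <- rlaplace(n)
  A1 <- matrix(c(1, 2, -1, 0.5), 4)
  gs <- GeneratorSet(A1, matrix(s, 1), fs = 1000)
  gs1 <- relativeVarianceFilter(gs, A1 %*% matrix(s, 1), minFraction = 0)
  expect_equal(varianceFraction(gs1), 1, tolerance = 1e-9)
  # two orthogonal-profile sources of equal reconstructed power: 0.5 each
  P <- cbind(c(1, 1, 0, 0), c(0, 0, 1, -1)) / sqrt(2)
  S2 <- rbind(rlaplace(n), rlaplace(n))
  S2 <- S2 / apply(S2, 1, sd)
  gs2 <- relativeVarianceFilter(GeneratorSet(P, S2, fs = 1000), P %*% S2,
                                minFraction = 0)
  expect_equal(varianceFraction(gs2), c(0.5, 0.5), tolerance = 0.03)
  # a 0.5%-variance source is removed at the default 1% threshold
  w <- sqrt(0.005 / 0.995)
  P3 <- cbind(P, c(1, -1, 1, 1) / 2)
  S3 <- rbind(S2 / sqrt(2), w * rlaplace(n) / 1)
  S3[3, ] <- S3[3, ] / sd(S3[3, ]) * sqrt(0.005)
  S3[1, ] <- S3[1, ] / sd(S3[1, ]) * sqrt(0.4975)
  S3[2, ] <- S3[2, ] / sd(S3[2, ]) * sqrt(0.4975)
  gs3 <- relativeVarianceFilter(GeneratorSet(P3, S3, fs = 1000), P3 %*% S3)
  expect_equal(ncol(mixing(gs3)), 2)
})

test_that("reconstruction captures the variance the fractions claim", {
  set.seed(11)
  sc <- defaultScene(nChannels = 16, duration = 20, fs = 500)
  sim <- simulateScene(sc, seed = 12)
  X <- samples(leftRecording(sim$recording))
  gs <- runICA(X, 6, seed = 13, fs = 500)
  recon <- mixing(gs) %*% timecourses(gs)
  Xc <- X - rowMeans(X)
  relResid <- sum((Xc - recon)^2) / sum(Xc^2)
  expect_lte(relResid, 1 - sum(varianceFraction(gs)) + 0.02)
})

test_that("profile matching pairs by 1 - Pearson with the 0.2 rule", {
  set.seed(14)
  P <- makeProfiles(list(profileSpec("bump", center = 8, width = 3),
                         profileSpec("bump", center = 20, width = 3)), 32)
  m <- matchProfiles(P, P)
  expect_equal(nrow(m$pairs), 2)
  expect_true(all(m$pairs$distance < 1e-12))
  # constructed pair at correlation exactly 0.85: distance 0.15, matched
  v <- P[, 1]
  vc <- (v - mean(v)) / sd(v)
  e <- residuals(lm(rnorm(32) ~ v))
  ec <- e / sd(e)
  u <- 0.85 * vc + sqrt(1 - 0.85^2) * ec
  m2 <- matchProfiles(cbind(v), cbind(u))
  expect_equal(m2$pairs$distance, 0.15, tolerance = 1e-9)
  # orthogonal profiles: distance 1, unmatched
  a <- c(1, 1, -1, -1, 1, 1, -1, -1)
  b <- c(1, -1, 1, -1, 1, -1, 1, -1)
  m3 <- matchProfiles(cbind(a), cbind(b))
  expect_equal(nrow(m3$pairs), 0)
  expect_equal(m3$unmatchedA, 1L)
})

test_that("epoch stability length behaves on constant, stationary and switching coupling", {
  fs <- 200
  set.seed(15)
  # identical signals: CC = 1 at every length, returns the first step
  x <- rnorm(120 * fs)
  st <- epochStabilityLength(x, x, fs, step = 5)
  expect_equal(st$length_s, 5)
  expect_true(st$converged)
  # stationary coupled pair: converges, and CC at the returned length is
  # within 3% of the long-run value
  z <- rnorm(120 * fs)
  l <- sqrt(0.5) * z + sqrt(0.5) * rnorm(120 * fs)
  r <- sqrt(0.5) * z + sqrt(0.5) * rnorm(120 * fs)
  st2 <- epochStabilityLength(l, r, fs, step = 5)
  expect_true(st2$converged)
  longRun <- cor(l, r)
  ccAtT <- st2$cc[which(st2$epochs_s == st2$length_s)]
  expect_lt(abs(ccAtT - longRun) / abs(longRun), 0.05)
  # coupling switched off halfway: either no convergence or T past the switch
  l2 <- c(l[1:(60 * fs)], rnorm(60 * fs))
  r2 <- r
  st3 <- epochStabilityLength(l2, r2, fs, step = 5)
  expect_true(!st3$converged || st3$length_s > 60)
})

test_that("joint-bilateral mode separates stacked left/right channel blocks", {
  sc <- smallScene(duration = 50, fs = 250)
  sim <- simulateScene(sc, seed = 16)
  gs <- runICA(sim$recording, 4, mode = "joint-bilateral", seed = 17)
  expect_equal(nrow(mixing(gs)), 2 * nChannels(sim$recording))
  # each joint component reconstructs one side's generator: its loading mass
  # concentrates on one channel block
  blockShare <- apply(mixing(gs)^2, 2, function(v) {
    top <- sum(v[seq_len(16)]); max(top, 1 - top)
  })
  expect_true(all(blockShare > 0.8))
  # per-shank mode on the same bilateral input returns one set per side
  both <- runICA(sim$recording, 2, mode = "per-shank", seed = 18)
  expect_named(both, c("left", "right"))
  expect_s4_class(both$left, "GeneratorSet")
})
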