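test_that("profile construction matches the specified shapes", {
  P <- makeProfiles(list(profileSpec("bump", center = 10, width = 3),
                         profileSpec("flat"),
                         profileSpec("reversing", reversal = 12)), 32)
  expect_equal(which.max(abs(P[, 1])), 10)
  expect_equal(max(P[, 1]), 1)
  expect_true(all(P[, 2] == P[1, 2]))
  sgn <- sign(P[, 3])
  flips <- which(diff(sgn) != 0)
  expect_equal(flips, 11)          # sign change between channels 11 and 12
  expect_equal(max(abs(P[, 3])), 1)
  expect_error(makeProfiles(list(profileSpec("bump", center = 40)), 32),
               "range")
})

test_that("event counts are Poisson at the configured rate", {
  dyn <- list(generatorDynamics("A", gammaRate = 2, slowPower = 0))
  cp <- couplingSpec(gammaPairingProb = 0.5)
  sim <- simulateTimecourses(dyn, cp, 60, 1000, seed = 41)
  nL <- sum(sim$events$side == "left")
  expect_true(abs(nL - 120) <= 33)   # 3 sigma of Poisson(120)
})

test_that("pairing probability 1 with zero jitter pairs every event", {
  dyn <- list(generatorDynamics("A", gammaRate = 3, slowPower = 0))
  cp <- couplingSpec(gammaPairingProb = 1, pairingJitterSd = 0)
  sim <- simulateTimecourses(dyn, cp, 30, 1000, seed = 7)
  ev <- sim$events
  L <- ev[ev$side == "left", ]; R <- ev[ev$side == "right", ]
  expect_equal(nrow(L), nrow(R))
  pr <- pairEvents(L, R, minOverlap = 0.7)
  expect_equal(nrow(pr$pairs), nrow(L))
  expect_length(pr$unpairedLeft, 0)
})

test_that("slow-band coherence construction hits its analytic target", {
  dyn <- list(generatorDynamics("A", gammaRate = 0, slowBand = c(1, 4),
                                slowPower = 1))
  cp <- couplingSpec(slowCoherence = c(A = 0.8), gammaPairingProb = 0)
  sim <- simulateTimecourses(dyn, cp, 60, 250, seed = 5)
  co <- coherenceWithSignificance(sim$left[1, ], sim$right[1, ], 250,
                                  nSurrogates = 20)
  inband <- co$freqs_hz >= 1 & co$freqs_hz <= 4
  expect_lt(abs(mean(co$coherence[inband]) - 0.8), 0.1)
  expect_error(couplingSpec(slowCoherence = c(A = 1)), "construction error")
})

test_that("mixing is the exact linear model plus configured noise", {
  set.seed(8)
  P <- makeProfiles(list(profileSpec("bump", center = 3, width = 1.5),
                         profileSpec("bump", center = 7, width = 1.5)), 10)
  tc <- list(left = matrix(rnorm(2 * 11000), 2),
             right = matrix(rnorm(2 * 11000), 2))
  mr0 <- mixAndRecord(P, tc, noiseSd = 0, fs = 1000)
  expect_equal(samples(leftRecording(mr0$recording)), P %*% tc$left)
  mr1 <- mixAndRecord(P, tc, noiseSd = 0.1, fs = 1000)
  resid <- samples(leftRecording(mr1$recording)) - P %*% tc$left
  expect_lt(abs(mean(resid^2) - 0.01) / 0.01, 0.10)
  # flat remote generator alone: identical waveform on every channel
  Pf <- makeProfiles(list(profileSpec("flat")), 6)
  mrf <- mixAndRecord(Pf, list(left = matrix(rnorm(11000), 1),
                               right = matrix(rnorm(11000), 1)),
                      noiseSd = 0, fs = 1000)
  sf <- samples(leftRecording(mrf$recording))
  expect_equal(sf[1, ], sf[5, ])
})

test_that("the same seed reproduces a scene bit-exactly", {
  sc <- defaultScene(nChannels = 8, duration = 12, fs = 1000)
  a <- simulateScene(sc, seed = 99)
  b <- simulateScene(sc, seed = 99)
  expect_identical(samples(leftRecording(a$recording)),
                   samples(leftRecording(b$recording)))
  expect_identical(a$truth$events, b$truth$events)
  c <- simulateScene(sc, seed = 100)
  expect_false(identical(samples(leftRecording(a$recording)),
                         samples(leftRecording(c$recording))))
})

test_that("generated recordings honour container invariants and shares", {
  sc <- defaultScene(nChannels = 16, duration = 30, fs = 500)
  sim <- simulateScene(sc, seed = 3)
  expect_true(validObject(sim$recording))
  # empirical relative variance equals the configured share by construction
  P <- sim$truth$mixing
  tc <- sim$truth$timecourses$left
  q <- colSums(P^2) * apply(tc, 1, var)
  expect_equal(unname(q), unname(sim$truth$shares), tolerance = 1e-6)
})

test_that("scene specs survive a JSON round trip", {
  sc <- defaultScene(nChannels = 8, duration = 12, fs = 1000)
  path <- file.path(tempdir(), "scene.json")
  exportScene(sc, path)
  back <- importScene(path)
  a <- simulateScene(sc, seed = 5)
  b <- simulateScene(back, seed = 5)
  expect_equal(samples(leftRecording(a$recording)),
               samples(leftRecording(b$recording)))
})
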