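test_that("pulse template closed forms hold", {
  # peak value e^{-1/2}/delta at t = delta
  for (d in c(0.002, 0.005, 0.03)) {
    expect_equal(pulseTemplate(d, d), exp(-0.5) / d, tolerance = 1e-12)
    expect_equal(pulseTemplate(0, d), 0)
    expect_equal(pulseTemplate(-d, d), 0)
    # unit area for every delta
    ar <- integrate(pulseTemplate, 0, Inf, delta = d, rel.tol = 1e-10)
    expect_lt(abs(ar$value - 1), 1e-6)
  }
  expect_equal(pulseTemplate(0.005, 0.005), 121.3061, tolerance = 1e-4)
  expect_error(pulseTemplate(0.01, -1))
})

test_that("single and double pulses are recovered to grid accuracy", {
  fs <- 1000
  tt <- (0:(fs - 1)) / fs
  s <- 2 * pulseTemplate(tt - 0.1, 0.005)
  d <- deconvolveEvents(s, fs)
  expect_equal(nrow(d$events), 1)
  expect_lt(abs(d$events$tau_s - 0.1), 0.002)
  expect_lt(abs(d$events$w - 2) / 2, 0.05)
  expect_lt(abs(d$events$delta_s - 0.005) / 0.005, 0.10)
  # two pulses separated by 10 delta
  s2 <- s + 1.5 * pulseTemplate(tt - 0.15, 0.005)
  d2 <- deconvolveEvents(s2, fs)
  expect_equal(nrow(d2$events), 2)
  expect_lt(abs(d2$events$tau_s[2] - 0.15), 0.002)
  expect_lt(abs(d2$events$w[2] - 1.5) / 1.5, 0.05)
  # derived fields
  expect_equal(d$events$peak_s, d$events$tau_s + d$events$delta_s)
  expect_equal(d$events$support_off_s - d$events$support_on_s,
               3 * d$events$delta_s)
})

test_that("white noise alone yields no events at the 4-SD threshold", {
  set.seed(1)
  hits <- replicate(10, nrow(deconvolveEvents(rnorm(5000), 1000)$events))
  expect_gte(mean(hits == 0), 0.9)
})

test_that("residual decreases monotonically as events are added", {
  set.seed(2)
  fs <- 1000
  tt <- (0:(4 * fs - 1)) / fs
  s <- rnorm(4 * fs, 0, 0.05)
  for (tk in c(0.5, 1.2, 2.1, 3.0))
    s <- s + 1.5 * pulseTemplate(tt - tk, 0.006)
  # track residual via successive prefix fits at increasing event caps
  rs <- vapply(1:4, function(k) {
    sd(deconvolveEvents(s, fs, maxEvents = k)$residual)
  }, 0)
  expect_true(all(diff(rs) < 1e-9))
})

test_that("fluctuating baselines raise the quality warning", {
  fs <- 1000
  tt <- (0:(10 * fs - 1)) / fs
  drifting <- 3 * sin(2 * pi * 0.5 * tt) +
    0.02 * pulseTemplate(tt - 5, 0.005)
  expect_warning(deconvolveEvents(drifting, fs), "fluctuating baseline")
})

test_that("event pairing follows the 70% overlap rule on interval arithmetic", {
  # L support [100,130] ms vs R [106,136]: overlap 24/30 = 0.8 -> paired
  L <- data.frame(tau_s = 0.100, delta_s = 0.010)
  R <- data.frame(tau_s = 0.106, delta_s = 0.010)
  pr <- pairEvents(L, R)
  expect_equal(nrow(pr$pairs), 1)
  expect_equal(pr$pairs$overlap_frac, 0.8, tolerance = 1e-9)
  # L [100,130] vs R [125,155]: overlap 5/30 ~ 0.17 -> unpaired
  R2 <- data.frame(tau_s = 0.125, delta_s = 0.010)
  pr2 <- pairEvents(L, R2)
  expect_equal(nrow(pr2$pairs), 0)
  expect_equal(pr2$unpairedLeft, 1L)
  expect_equal(pr2$unpairedRight, 1L)
})

test_that("pairing equals the brute-force assignment and is symmetric", {
  set.seed(3)
  for (rep in 1:40) {
    L <- randomEventList(sample(2:6, 1), durS = 0.3)
    R <- randomEventList(sample(2:6, 1), durS = 0.3)
    pr <- pairEvents(L, R)
    bf <- bruteForcePairs(L, R)
    expect_equal(sum(pr$pairs$overlap_frac),
                 max(bf$score, 0), tolerance = 1e-9)
    # symmetry
    prs <- pairEvents(R, L)
    expect_equal(nrow(prs$pairs), nrow(pr$pairs))
    expect_equal(sort(prs$pairs$right_idx), sort(pr$pairs$left_idx))
  }
})

test_that("amplitude covariation separates diagonal, noisy and independent pairs", {
  mk <- function(aL, aR) {
    n <- length(aL)
    L <- data.frame(tau_s = seq_len(n) * 0.1, delta_s = 0.005,
                    peak_amp = aL)
    R <- data.frame(tau_s = seq_len(n) * 0.1 + 0.001, delta_s = 0.005,
                    peak_amp = aR)
    pairEvents(L, R)
  }
  a <- seq(1, 3, length.out = 50)
  ident <- amplitudeCovariation(mk(a, a))
  expect_equal(ident$r, 1, tolerance = 1e-9)
  expect_equal(ident$dispersion, 0, tolerance = 1e-12)
  expect_equal(ident$slope, 1, tolerance = 1e-9)
  set.seed(4)
  noisy <- amplitudeCovariation(mk(a, a * (1 + 0.05 * rnorm(50))))
  expect_gte(noisy$r, 0.95)
  rIndep <- replicate(20, {
    amplitudeCovariation(mk(rlnorm(100), rlnorm(100)))$r
  })
  expect_gte(mean(abs(rIndep) < 0.2), 0.95)
  expect_error(amplitudeCovariation(mk(a[1:2], a[1:2])), "3 pairs")
})
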