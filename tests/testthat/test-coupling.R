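test_that("lagged cross-correlation peaks where the delay is", {
  fs <- 250
  t <- (0:(10 * fs - 1)) / fs
  x <- sin(2 * pi * 5 * t)
  cc <- crossCorrLagged(x, x, fs, 0.2)
  expect_equal(cc$cc_max, 1, tolerance = 1e-6)
  expect_equal(cc$tau_max_s, 0)
  # y = x delayed by 10 ms: tau_max = +10 ms (positive means y lags x)
  set.seed(1)
  fs2 <- 500
  a <- rnorm(20 * fs2)
  d <- round(0.01 * fs2)
  b <- c(rep(0, d), a[1:(length(a) - d)])
  cc2 <- crossCorrLagged(a, b, fs2, 0.1)
  expect_equal(cc2$tau_max_s, 0.01, tolerance = 1e-9)
  expect_error(crossCorrLagged(a, rep(1, length(a)), fs2, 0.1), "zero-variance")
})

test_that("independent noise rarely yields a large CC peak", {
  fs <- 250
  set.seed(2)
  peaks <- replicate(20, {
    abs(crossCorrLagged(rnorm(60 * fs), rnorm(60 * fs), fs, 0.1)$cc_max)
  })
  expect_gte(mean(peaks < 0.05), 0.95)
})

test_that("cross-correlation is symmetric under input swap with lag negation", {
  fs <- 100
  set.seed(3)
  x <- rnorm(30 * fs); y <- 0.4 * x + rnorm(30 * fs)
  ab <- crossCorrLagged(x, y, fs, 0.1)
  ba <- crossCorrLagged(y, x, fs, 0.1)
  expect_equal(ab$R, rev(ba$R), tolerance = 1e-10)
})

test_that("phase randomization preserves the spectrum and breaks correlation", {
  fs <- 250
  t <- (0:(4 * fs - 1)) / fs
  s <- sin(2 * pi * 10 * t)
  sr <- phaseRandomize(s, seed = 4)
  # a pure tone stays a pure tone of the same amplitude
  expect_equal(max(Mod(fft(sr))), max(Mod(fft(s))), tolerance = 1e-9)
  expect_equal(sd(sr), sd(s), tolerance = 1e-9)
  # any series: amplitude spectrum identical to near machine precision
  set.seed(5)
  x <- rnorm(60 * fs)
  xs <- phaseRandomize(x)
  expect_lt(max(abs(Mod(fft(xs)) - Mod(fft(x)))) / max(Mod(fft(x))), 1e-10)
  expect_equal(mean(xs), mean(x), tolerance = 1e-12)
  # surrogate decorrelates from the original
  rs <- replicate(20, abs(cor(x, phaseRandomize(x))))
  expect_gte(mean(rs < 0.05), 0.95)
})

test_that("coherence: self-coherence ~1 and SNR-derived level is recovered", {
  fs <- 250
  set.seed(6)
  x <- rnorm(120 * fs)
  co <- coherenceWithSignificance(x, x + 1e-8 * rnorm(length(x)), fs,
                                  nSurrogates = 20)
  expect_true(all(co$coherence > 0.99))
  # y = band-limited x + equal-power in-band noise: C ~ 0.5 in the band
  xb <- filterSignal(rnorm(120 * fs), "bandpass", c(5, 20), fs)
  nb <- filterSignal(rnorm(120 * fs), "bandpass", c(5, 20), fs)
  y <- xb + nb * sd(xb) / sd(nb)
  co2 <- coherenceWithSignificance(xb, y, fs, nSurrogates = 20)
  inband <- co2$freqs_hz >= 7 & co2$freqs_hz <= 18
  expect_lt(abs(mean(co2$coherence[inband]) - 0.5), 0.05)
  expect_error(coherenceWithSignificance(x[1:500], x[1:500], fs,
                                         nSurrogates = 5),
               "estimator error")
})

test_that("masked intervals are honoured by coherence and windowed Pearson", {
  fs <- 250
  set.seed(7)
  x <- rnorm(60 * fs); y <- rnorm(60 * fs)
  mask <- rep(FALSE, length(x)); mask[2000:2500] <- TRUE
  co <- coherenceWithSignificance(x, y, fs, nSurrogates = 10, mask = mask)
  expect_lt(co$nSegments, 119)
  wp <- windowedPearson(x, y, fs, 1, mask = mask)
  expect_true(anyNA(wp$r))
  full <- windowedPearson(x, y, fs, 1)
  expect_equal(sum(is.na(wp$r)), sum(mask[seq_len(60 * fs)] |> matrix(fs) |>
                                       colSums() > 0))
  expect_gt(full$nWindows, wp$nWindows)
})

test_that("windowed Pearson matches identity, sign flip and the null SD", {
  fs <- 100
  set.seed(8)
  x <- rnorm(40 * fs)
  wi <- windowedPearson(x, x, fs, 0.5)
  expect_equal(wi$chi, 1, tolerance = 1e-9)
  expect_equal(wi$sigma, 0, tolerance = 1e-9)
  wn <- windowedPearson(x, -x, fs, 0.5)
  expect_equal(wn$chi, -1, tolerance = 1e-9)
  # null at 40 samples/window: sigma ~ 1/sqrt(39) = 0.160
  fs2 <- 4000
  set.seed(9)
  a <- rnorm(30 * fs2); b <- rnorm(30 * fs2)
  w <- windowedPearson(a, b, fs2, 0.01)
  expect_lt(abs(w$chi), 0.01)
  expect_lt(abs(w$sigma - 0.160), 0.01)
  # zero-variance window recorded as missing, not zero
  a2 <- rnorm(30 * fs)
  a2[1:(0.5 * fs)] <- 1
  w2 <- windowedPearson(a2, rnorm(30 * fs), fs, 0.5)
  expect_true(is.na(w2$r[1]))
  # histogram density integrates to 1
  expect_equal(sum(w$density * diff(w$edges)), 1, tolerance = 1e-9)
})

test_that("windowed-Pearson histograms flatten as the window shrinks", {
  fs <- 4000
  set.seed(10)
  x <- rnorm(30 * fs); y <- rnorm(30 * fs)
  s1 <- windowedPearson(x, y, fs, 1)$sigma
  s01 <- windowedPearson(x, y, fs, 0.1)$sigma
  s001 <- windowedPearson(x, y, fs, 0.01)$sigma
  expect_true(s001 > s01 && s01 > s1)
})

test_that("autocorrelation mean frequency finds tones, pulse trains and stays in band", {
  fs <- 1000
  t <- (0:(20 * fs - 1)) / fs
  expect_equal(meanFrequencyAutocorr(sin(2 * pi * 40 * t), fs), 40,
               tolerance = 0.05)
  # pulse train at 28 ms mean interval: ~35.7 Hz
  dur <- 30
  tau <- seq(0.1, dur - 0.2, by = 0.028)
  s <- numeric(dur * fs); tt <- (0:(dur * fs - 1)) / fs
  for (tk in tau) {
    i <- floor(tk * fs):min(dur * fs, ceiling((tk + 0.04) * fs))
    s[i] <- s[i] - pulseTemplate(tt[i] - tk, 0.006)
  }
  expect_equal(meanFrequencyAutocorr(s, fs), 35.7, tolerance = 2)
  # band-passed white noise: estimate inside the band
  set.seed(11)
  f <- meanFrequencyAutocorr(rnorm(20 * fs), fs)
  expect_true(f >= 30 && f <= 100)
  expect_error(meanFrequencyAutocorr(rnorm(1000), fs), "100 cycles")
})
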