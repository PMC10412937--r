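test_that("container round trip is bit-exact and metadata-lossless", {
  set.seed(1)
  rec <- Recording(matrix(rnorm(400), 4, 100), fs = 4000,
                   meta = list(subject = "r01", epoch = 3L))
  path <- file.path(tempdir(), "rt_rec")
  writeRecording(rec, path)
  back <- readRecording(path)
  expect_identical(samples(back), samples(rec))
  expect_identical(samplingRate(back), 4000)
  expect_identical(depths(back), depths(rec))
  expect_equal(back@meta$subject, "r01")
  expect_equal(back@meta$epoch, 3L)
})

test_that("malformed containers and mismatched pairs are rejected", {
  set.seed(2)
  rec <- Recording(matrix(rnorm(40), 4, 10), fs = 1000)
  path <- file.path(tempdir(), "bad_rec")
  writeRecording(rec, path)
  sc <- jsonlite::read_json(paste0(path, ".json"))
  sc$fs <- NULL
  jsonlite::write_json(sc, paste0(path, ".json"), auto_unbox = TRUE)
  expect_error(readRecording(path), "format error")

  l <- Recording(matrix(rnorm(320), 32, 10), fs = 1000)
  r <- Recording(matrix(rnorm(310), 31, 10), fs = 1000)
  expect_error(BilateralRecording(l, r), "pairing error")
})

test_that("events CSV round trips with the standard header", {
  ev <- data.frame(onset_s = c(0.1, 2.5), offset_s = c(0.2, 2.8),
                   label = c("large_event", "large_event"))
  path <- file.path(tempdir(), "events.csv")
  writeEventsCSV(ev, path)
  expect_equal(readEventsCSV(path), ev)
  writeLines("a,b", path)
  expect_error(readEventsCSV(path), "format error")
})

test_that("Recording validity enforces geometry and finiteness", {
  expect_error(Recording(matrix(1:10, 1), fs = 100), "2 channels")
  expect_error(Recording(matrix(1, 3, 4), fs = 100,
                         depths = c(0, 65, 140.1)), "spacing")
  bad <- matrix(1, 3, 4); bad[2, 2] <- NA
  expect_error(Recording(bad, fs = 100), "non-finite")
})

test_that("high-pass removes DC and preserves/rejects bands as designed", {
  fs <- 1000
  # constant input: output ~ 0
  y <- filterSignal(rep(5, 4 * fs), "highpass", 0.5, fs)
  expect_lt(max(abs(y)), 1e-3 * 5)
  # 10 Hz passband tone preserved within 1%
  x <- sineWave(10, 20, fs)
  y <- filterSignal(x, "highpass", 0.5, fs)
  mid <- 5000:15000
  expect_lt(abs(max(abs(y[mid])) - 1), 0.01)
  # one decade below cutoff: attenuated >= 99%
  x <- sineWave(0.05, 60, fs)
  y <- filterSignal(x, "highpass", 0.5, fs)
  expect_lt(max(abs(y[(20 * fs):(40 * fs)])), 0.01)
  # band edge at/above Nyquist rejected
  expect_error(filterSignal(x, "highpass", 500, fs), "Nyquist")
})

test_that("bandpass filtering is idempotent on passband content", {
  fs <- 1000
  x <- sineWave(55, 10, fs)  # near the band centre sqrt(30 * 100)
  y1 <- filterSignal(x, "bandpass", c(30, 100), fs)
  y2 <- filterSignal(y1, "bandpass", c(30, 100), fs)
  mid <- 3000:7000
  expect_lt(max(abs(y2[mid] - y1[mid])) / max(abs(y1[mid])), 0.02)
})

test_that("downsampling preserves passband tones and rejects aliases", {
  fs <- 50000
  x <- sineWave(100, 1, fs)
  y <- downsampleRecording(x, 4000, fs = fs)
  expect_length(y, 4000)
  expect_lt(abs(max(abs(y[1000:3000])) - 1), 0.01)
  # a 3 kHz tone is above the 2 kHz output Nyquist: alias power < 1%
  x3 <- sineWave(3000, 1, fs)
  y3 <- downsampleRecording(x3, 4000, fs = fs)
  expect_lt(mean(y3^2) / mean(x3^2), 0.01)
  # non-rational ratios rejected; upsampling rejected
  expect_error(downsampleRecording(x[1:49999], 4000, fs = fs),
               "non-rational")
  expect_error(downsampleRecording(x, 60000, fs = fs), "below fs")
})

test_that("downsampling cascades consistently", {
  fs <- 8000
  set.seed(3)
  x <- filterSignal(rnorm(8 * fs), "bandpass", c(1, 80), fs)
  a <- downsampleRecording(downsampleRecording(x, 2000, fs = fs), 500,
                           fs = 2000)
  b <- downsampleRecording(x, 500, fs = fs)
  expect_lt(sqrt(mean((a - b)^2)) / sqrt(mean(b^2)), 0.02)
})

test_that("interior channel interpolation averages neighbours, outer rejected", {
  rec <- Recording(matrix(c(1, 9, 3), 3, 5), fs = 100)
  out <- interpolateChannel(rec, 2)
  expect_equal(samples(out)[2, ], rep(2, 5))
  expect_error(interpolateChannel(rec, 1), "rejection error")
  expect_error(interpolateChannel(rec, 3), "rejection error")
  # idempotence when the channel already equals the neighbour mean
  expect_equal(samples(interpolateChannel(out, 2)), samples(out))
})

test_that("large-event exclusion flags the transient and honours k = Inf", {
  set.seed(4)
  fs <- 1000
  x <- rnorm(10 * fs)
  x[5000:5050] <- x[5000:5050] + 8
  ex <- excludeLargeEvents(x, fs, k = 5)
  expect_equal(nrow(ex$intervals), 1)
  expect_true(ex$intervals$onset_s[1] < 5.0 && ex$intervals$offset_s[1] > 5.05)
  exInf <- excludeLargeEvents(x, fs, k = Inf)
  expect_equal(nrow(exInf$intervals), 0)
  expect_identical(exInf$masked, x)
  # pure white noise at k = 5: expected excluded fraction < 0.1%
  set.seed(5)
  w <- rnorm(10 * fs)
  exw <- excludeLargeEvents(w, fs, k = 5, pad = 0)
  expect_lt(mean(exw$mask), 0.001)
})

test_that("GeneratorSet and CSDMap containers round trip", {
  set.seed(6)
  gs <- GeneratorSet(matrix(rnorm(8), 4), matrix(rnorm(40), 2), fs = 500,
                     varianceFraction = c(0.6, 0.3),
                     labels = c("Sch", "LM"))
  p <- file.path(tempdir(), "gs")
  writeGeneratorSet(gs, p)
  back <- readGeneratorSet(p)
  # payload is bit-exact; the constructor re-canonicalizes, so compare
  # at numerical identity
  expect_equal(mixing(back), mixing(gs), tolerance = 1e-14)
  expect_equal(timecourses(back), timecourses(gs), tolerance = 1e-14)
  expect_equal(varianceFraction(back), varianceFraction(gs))
  expect_equal(generatorLabels(back), generatorLabels(gs))

  csvp <- file.path(tempdir(), "profiles.csv")
  writeProfilesCSV(gs, depths = c(0, 65, 130, 195), csvp)
  df <- read.csv(csvp)
  expect_equal(names(df), c("depth_um", "Sch", "LM"))
  expect_equal(df$Sch, mixing(gs)[, 1])

  cm <- csd1d(matrix(rnorm(40), 4), sigma = 2, h = 65, fs = 100)
  cp <- file.path(tempdir(), "csd")
  writeCSDMap(cm, cp)
  cback <- readCSDMap(cp)
  expect_identical(csdValues(cback), csdValues(cm))
  expect_equal(cback@sigma, 2)
  # a plain recording container is rejected as a CSD map
  writeRecording(Recording(matrix(rnorm(40), 4), fs = 100), cp)
  expect_error(readCSDMap(cp), "not a CSD map")
})
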