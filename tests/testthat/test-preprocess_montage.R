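test_that("pass-band signals survive filtering and downsampling unchanged", {
  rec <- sineRecording(10, amp = 1, duration = 10)
  out <- preprocessRecording(rec)
  expect_equal(samplingRate(out), 128)
  expect_identical(channelLabels(out), electrodes1020())
  x <- samples(out)["Cz", ]
  mid <- seq(round(length(x) * 0.2), round(length(x) * 0.8))
  expect_equal(sqrt(mean(x[mid]^2)), 1 / sqrt(2), tolerance = 0.02)
})

test_that("stop-band attenuation matches the filter's magnitude response", {
  rec <- sineRecording(50, amp = 1, duration = 10)
  out <- preprocessRecording(rec)
  x <- samples(out)["Cz", ]
  mid <- seq(round(length(x) * 0.2), round(length(x) * 0.8))
  ratio <- sqrt(mean(x[mid]^2)) / (1 / sqrt(2))
  expect_lt(ratio, 0.05)
  # oracle: zero-phase 6th-order low-pass magnitude response at 50 Hz
  lp <- signal::butter(6, 30 / 256, "low")
  H <- signal::freqz(lp, n = 4096, Fs = 512)
  expected <- approx(H$f, Mod(H$h)^2, 50)$y   # |H|^2: forward-backward pass
  expect_equal(ratio, expected, tolerance = expected)
})

test_that("the high-pass removes a DC offset", {
  rec <- makeRecording(function(t, i) rep(100, length(t)), duration = 10)
  out <- preprocessRecording(rec)
  x <- samples(out)["O1", ]
  mid <- seq(round(length(x) * 0.2), round(length(x) * 0.8))
  expect_lt(abs(mean(x[mid])), 1)
})

test_that("preprocessing is nearly idempotent for in-band content", {
  rec <- sineRecording(10, duration = 10)
  once <- preprocessRecording(rec)
  twice <- preprocessRecording(once, targetFs = 128)
  r1 <- sqrt(mean(samples(once)["Cz", ]^2))
  r2 <- sqrt(mean(samples(twice)["Cz", ]^2))
  expect_lt(abs(r2 - r1) / r1, 0.01)
})

test_that("preprocessing rejects impossible rates", {
  rec <- sineRecording(10, duration = 2, fs = 128)
  expect_error(preprocessRecording(rec, targetFs = 128, band = c(0.5, 70)),
               "Nyquist")
  rec2 <- sineRecording(10, duration = 2, fs = 512)
  expect_error(preprocessRecording(rec2, targetFs = 100), "evenly")
})

test_that("recordings with non-finite samples are rejected at construction", {
  x <- matrix(0, 19, 100, dimnames = list(electrodes1020(), NULL))
  x[3, 50] <- NaN
  expect_error(monopolarRecording(x, fs = 512), "non-finite")
})

test_that("artifact-free chunks concatenate with duration bookkeeping", {
  one <- noiseRecording(duration = 180, fs = 128)
  expect_silent(joined <- concatenateChunks(list(one)))
  expect_equal(duration(joined), 180)

  chunks <- lapply(1:3, function(i) noiseRecording(duration = 30, fs = 128,
                                                   seed = i))
  expect_warning(joined <- concatenateChunks(chunks), "120")
  expect_equal(duration(joined), 90)

  expect_error(concatenateChunks(list()), "no chunks")
  slow <- noiseRecording(duration = 30, fs = 256)
  expect_error(suppressWarnings(concatenateChunks(list(chunks[[1]], slow))),
               "sampling rates")
})

test_that("double-banana derivation is exact elementwise subtraction", {
  set.seed(42)
  x <- matrix(rnorm(19 * 256), 19, 256, dimnames = list(electrodes1020(), NULL))
  rec <- monopolarRecording(x, fs = 128)
  bip <- doubleBanana(rec)
  expect_identical(channelLabels(bip), bananaChannels())
  # brute-force subtraction oracle per channel
  for (i in seq_len(18)) {
    pr <- bananaPairs()[i, ]
    expect_equal(samples(bip)[i, ], unname(x[pr[1], ] - x[pr[2], ]),
                 tolerance = 1e-12)
  }
})

test_that("common-mode signals cancel and simple differences pass through", {
  t <- seq_len(512) / 512
  x <- matrix(rep(sin(2 * pi * 7 * t), each = 19), 19,
              dimnames = list(electrodes1020(), NULL))
  bip <- doubleBanana(monopolarRecording(x, fs = 512))
  expect_true(all(abs(samples(bip)) < 1e-12))

  x2 <- matrix(0, 19, 512, dimnames = list(electrodes1020(), NULL))
  x2["Fp1", ] <- t
  bip2 <- doubleBanana(monopolarRecording(x2, fs = 512))
  expect_equal(samples(bip2)["Fp1-F3", ], t, tolerance = 1e-12)
})

test_that("montage derivation is linear and reference-invariant", {
  set.seed(7)
  mk <- function() matrix(rnorm(19 * 128), 19, 128,
                          dimnames = list(electrodes1020(), NULL))
  X <- mk(); Y <- mk()
  a <- 2.5; b <- -1.3
  lhs <- samples(doubleBanana(monopolarRecording(a * X + b * Y, fs = 128)))
  rhs <- a * samples(doubleBanana(monopolarRecording(X, fs = 128))) +
         b * samples(doubleBanana(monopolarRecording(Y, fs = 128)))
  expect_equal(lhs, rhs, tolerance = 1e-12)

  ref <- matrix(rep(rnorm(128), each = 19), 19)   # common reference shift
  rereferenced <- samples(doubleBanana(monopolarRecording(X + ref, fs = 128)))
  expect_equal(rereferenced,
               samples(doubleBanana(monopolarRecording(X, fs = 128))),
               tolerance = 1e-12)
})

test_that("a missing electrode is reported by name", {
  x <- matrix(0, 18, 10,
              dimnames = list(setdiff(electrodes1020(), "T5"), NULL))
  expect_error(monopolarRecording(x, fs = 512), "T5")
})
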