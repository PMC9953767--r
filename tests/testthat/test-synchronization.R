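test_that("identical channels are fully coherent at every frequency", {
  set.seed(3)
  x <- matrix(rnorm(18 * 10 * 128), nrow = 18)
  x[2, ] <- x[1, ]
  cs <- coherenceSpectrum(makeWindows(directBipolar(x)),
                          pairs = rbind(bananaChannels()[1:2]))
  expect_true(all(abs(cs@coh - 1) < 1e-9))
})

test_that("a pure delay preserves magnitude coherence in band", {
  set.seed(4)
  n <- 20 * 128
  base <- rnorm(n + 3)
  x <- matrix(rnorm(18 * n), nrow = 18)
  x[1, ] <- base[4:(n + 3)]
  x[2, ] <- base[1:n]                      # 3-sample delayed copy
  cs <- coherenceSpectrum(makeWindows(directBipolar(x)),
                          pairs = rbind(bananaChannels()[1:2]))
  inBand <- cs@freqs >= 0.5 & cs@freqs <= 30
  expect_gt(mean(cs@coh[1, inBand]), 0.95)
})

test_that("independent channels show the 1/n coherence bias", {
  set.seed(5)
  n <- ceiling((1 + 198 * 0.9) * 128)      # enough samples for 199 windows
  x <- matrix(rnorm(18 * n), nrow = 18)
  ws <- makeWindows(directBipolar(x))
  expect_equal(nWindows(ws), 199)
  cs <- coherenceSpectrum(ws, pairs = rbind(bananaChannels()[1:2]))
  inBand <- cs@freqs >= 0.5 & cs@freqs <= 30
  vals <- cs@coh[1, inBand]
  expect_equal(mean(vals), 1 / 199, tolerance = 0.5 / 199 * 10)
  expect_gt(mean(vals < 0.05), 0.95)
})

test_that("coherence needs at least two windows", {
  expect_error(coherenceSpectrum(makeWindows(noiseBipolar(duration = 1))),
               "2 windows")
})

test_that("coherence is invariant to channel rescaling and common shifts", {
  set.seed(6)
  n <- 10 * 128
  shared <- rnorm(n)
  x <- matrix(rnorm(18 * n), nrow = 18)
  x[1, ] <- x[1, ] + shared
  x[2, ] <- x[2, ] + shared
  pair <- rbind(bananaChannels()[1:2])
  c1 <- coherenceSpectrum(makeWindows(directBipolar(x)), pairs = pair)
  x2 <- x; x2[1, ] <- 17 * x2[1, ]; x2[2, ] <- 0.04 * x2[2, ]
  c2 <- coherenceSpectrum(makeWindows(directBipolar(x2)), pairs = pair)
  expect_equal(c1@coh, c2@coh, tolerance = 1e-9)
})

test_that("band coherence reduces the spectrum by unweighted bin means", {
  freqs <- seq(0, 64, by = 0.5)
  mkcs <- function(vals) new("CoherenceSpectrum",
                             coh = matrix(vals, nrow = 1),
                             pairs = rbind(c("C3-P3", "P3-O1")),
                             freqs = freqs, nWindows = 10)
  bc <- bandCoherence(mkcs(rep(0.42, length(freqs))))
  expect_true(all(abs(bc - 0.42) < 1e-12))

  ind <- as.numeric(freqs > 8 & freqs <= 13)
  bc2 <- bandCoherence(mkcs(ind))
  expect_equal(unname(bc2[1, ]), c(0, 0, 1, 0))
})

test_that("a shared alpha source raises alpha coherence above other bands", {
  set.seed(8)
  n <- 30 * 128
  hp <- signal::butter(4, 9 / 64, "high"); lp <- signal::butter(4, 12 / 64, "low")
  alphaSrc <- signal::filtfilt(lp, signal::filtfilt(hp, rnorm(n)))
  alphaSrc <- alphaSrc / sd(alphaSrc)
  x <- matrix(rnorm(18 * n), nrow = 18)
  x[1, ] <- x[1, ] + 2 * alphaSrc
  x[2, ] <- x[2, ] + 2 * alphaSrc
  bc <- bandCoherence(coherenceSpectrum(makeWindows(directBipolar(x)),
                                        pairs = rbind(bananaChannels()[1:2])))
  expect_gt(bc[1, "alpha"], max(bc[1, c("delta", "theta", "beta")]))
})

test_that("pair counts follow Nch(Nch-1)/2", {
  expect_equal(nPairs(3), 3L)
  expect_equal(nPairs(9), 36L)
  # brute-force enumeration oracle
  for (nch in c(3, 9)) {
    labels <- paste0("ch", seq_len(nch))
    expect_equal(nrow(t(combn(labels, 2))), nPairs(nch))
  }
  # lobes contribute 3 pairs; 9 hemisphere slots give 36 slot pairs of
  # which one is the duplicated channel against itself
  keys <- qeegnorm:::.regionPairKeys(lobeGrouping("lobes")$T_left)
  expect_length(keys, 3L)
  hkeys <- qeegnorm:::.regionPairKeys(lobeGrouping("hemispheres")$H_left)
  expect_length(hkeys, 35L)                 # 36 minus the self-pair
  expect_length(unique(qeegnorm:::.regionPairKeys(
    lobeGrouping("hemispheres")$H_left, "unique")), 28L)
})

test_that("grouped coherence averages its constituent pairs", {
  bands <- c("delta", "theta", "alpha", "beta")
  keys <- qeegnorm:::.pairKey(
    c("F7-T3", "F7-T3", "T3-T5"), c("T3-T5", "T5-O1", "T5-O1"))
  bc <- matrix(0.5, nrow = 3, ncol = 4, dimnames = list(keys, bands))
  bc[, "alpha"] <- c(0.3, 0.2, 0.1)
  allKeys <- unique(unlist(lapply(names(lobeGrouping("all")), function(r)
    qeegnorm:::.regionPairKeys(lobeGrouping("all")[[r]]))))
  full <- matrix(0.5, nrow = length(allKeys), ncol = 4,
                 dimnames = list(allKeys, bands))
  full[rownames(bc), ] <- bc
  g <- groupCoherence(full, "all")
  expect_equal(unname(g["T_left", "alpha"]), 0.2)
  expect_true(all(abs(g[, "delta"] - 0.5) < 1e-12))
  # grouped value stays within [min, max] of constituents
  expect_gte(g["T_left", "alpha"], 0.1)
  expect_lte(g["T_left", "alpha"], 0.3)
})

test_that("grouping rejects unknown channels", {
  bc <- matrix(0.5, 1, 4,
               dimnames = list("A|B",
                               c("delta", "theta", "alpha", "beta")))
  expect_error(groupCoherence(bc, "lobes"), "missing")
})
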