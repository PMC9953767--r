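test_that("regional grouping averages channel triplets and hemisphere slots", {
  v <- setNames(rep(2.5, 18), bananaChannels())
  g <- groupFeatures(v)
  expect_true(all(abs(g - 2.5) < 1e-12))

  v2 <- v
  v2[c("Fp1-F3", "F3-C3", "Fp1-F7")] <- c(0.9, 1.2, 1.5)
  expect_equal(unname(groupFeatures(v2)["F_left"]), 1.2)

  # duplicated posterior channel: slot mean counts it twice
  v3 <- setNames(rep(1, 18), bananaChannels())
  v3["T5-O1"] <- 10
  slots <- groupFeatures(v3, hemispherePolicy = "slots")["H_left"]
  uniq <- groupFeatures(v3, hemispherePolicy = "unique")["H_left"]
  expect_equal(unname(slots), (7 + 2 * 10) / 9)
  expect_equal(unname(uniq), (7 + 10) / 8)
  expect_gt(slots, uniq)

  expect_error(groupFeatures(v[-1]), "missing channel")
})

test_that("age groups partition the age axis with closed 20-50 interval", {
  expect_equal(as.character(assignAgeGroup(10)), "<20")
  expect_equal(as.character(assignAgeGroup(35)), "20-50")
  expect_equal(as.character(assignAgeGroup(20)), "20-50")
  expect_equal(as.character(assignAgeGroup(50)), "20-50")
  expect_equal(as.character(assignAgeGroup(50.5)), ">50")
  expect_equal(as.character(assignAgeGroup(19.99)), "<20")
  expect_error(assignAgeGroup(-3), "non-negative")
  expect_warning(assignAgeGroup(80), "normative range")
})

test_that("structure orderings rank bands with explicit ties", {
  # parieto-occipital >50 reference cells
  po <- c(alpha = 1.57, beta = 1.13, delta = 1.00, theta = 0.87)
  expect_equal(structureOrdering(po), c("alpha", "beta", "delta", "theta"))
  # temporal <20 reference cells carry an exact beta/theta tie
  t20 <- c(alpha = 1.79, delta = 1.71, beta = 1.27, theta = 1.27)
  expect_equal(structureOrdering(t20), c("alpha", "delta", "beta/theta"))
  allEq <- c(delta = 1, theta = 1, alpha = 1, beta = 1)
  expect_equal(structureOrdering(allEq), "delta/theta/alpha/beta")
})

test_that("orderings reproduce the reference group-mean table rows", {
  tab <- logPSGroupMeans()
  # two right-hemisphere cells order differently from the table's shared
  # label column, which follows the left hemisphere; the numeric cells win
  exceptions <- list(
    "T.<20.right" = c("alpha", "delta", "theta", "beta"),
    "PO.>50.right" = c("alpha", "delta", "beta", "theta"))
  for (lb in unique(tab$lobe)) for (g in unique(tab$age_group))
    for (h in c("left", "right")) {
      rows <- tab[tab$lobe == lb & tab$age_group == g & tab$hemisphere == h, ]
      ord <- unlist(strsplit(structureOrdering(setNames(rows$mean, rows$band)),
                             "/"))
      key <- paste(lb, g, h, sep = ".")
      expected <- if (key %in% names(exceptions)) exceptions[[key]]
                  else rows$band
      expect_equal(ord, expected, info = key)
    }
})

test_that("printed-form normative equations evaluate correctly", {
  b <- normativeBundle()
  # cubic at an interior age: direct polynomial arithmetic
  expect_equal(evaluateNormative(b$pdr.freq.left, 35),
               9.77 + 0.03 * 35 - 0.0004 * 35^2 - 0.000002 * 35^3,
               tolerance = 1e-12)
  expect_equal(evaluateNormative(b$pdr.freq.left, 35), 10.244,
               tolerance = 1e-3)
  # decaying exponential at 20 years
  expect_equal(evaluateNormative(b$pdr.amp.left, 20),
               14.62 + 99.31 * exp(-0.127 * 20), tolerance = 1e-12)
  expect_equal(evaluateNormative(b$pdr.amp.left, 20), 22.5, tolerance = 0.05)
  # any polynomial at age zero returns its intercept
  for (f in names(b))
    if (b[[f]]@kind == "polynomial")
      expect_equal(suppressWarnings(evaluateNormative(b[[f]], 0)),
                   b[[f]]@coefficients[1])
  expect_warning(evaluateNormative(b$pdr.freq.left, 95), "validity")
})

test_that("the amplitude fits decay toward their printed offset", {
  b <- normativeBundle()
  expect_equal(suppressWarnings(evaluateNormative(b$pdr.amp.left, 1e6)),
               14.62, tolerance = 1e-9)
  expect_gt(suppressWarnings(evaluateNormative(b$pdr.amp.left, 10)),
            suppressWarnings(evaluateNormative(b$pdr.amp.left, 70)))
})

test_that("fitNormative recovers noiseless polynomials exactly", {
  age <- seq(10, 74, length.out = 20)
  co <- c(3.1, 0.05, -0.002)
  y <- co[1] + co[2] * age + co[3] * age^2
  eq <- fitNormative(age, y, degree = 2)
  expect_equal(eq@coefficients, co, tolerance = 1e-8)
  expect_equal(eq@r, 1, tolerance = 1e-9)
  # round trip: evaluate o fit is the identity on the training ages
  expect_equal(evaluateNormative(eq, age), y, tolerance = 1e-8)
})

test_that("degenerate fits are handled: constants and rank deficiency", {
  age <- seq(20, 60, length.out = 10)
  eq <- fitNormative(age, rep(4.2, 10), degree = 0)
  expect_equal(eq@coefficients, 4.2)
  expect_equal(eq@r, 0)
  expect_error(fitNormative(rep(30, 10), rnorm(10), degree = 2),
               "rank-deficient")
  expect_error(fitNormative(c(20, 30), c(1, 2), degree = 2), "at least")
})

test_that("exponential fits recover decaying amplitude curves", {
  set.seed(12)
  age <- runif(60, 10, 74)
  y <- 14.62 + 99.31 * exp(-0.127 * age) + rnorm(60, sd = 1)
  eq <- fitNormative(age, y, kind = "exp_decay")
  expect_equal(eq@coefficients[1], 14.62, tolerance = 0.15 * 14.62)
  expect_equal(eq@coefficients[3], 0.127, tolerance = 0.3 * 0.127)
})

test_that("whole-cohort means reconstruct from group means by size weights", {
  g <- logPSGroupMeans()
  t1 <- logPSCohortMeans()
  w <- normativeGroupSizes()
  for (i in seq_len(nrow(t1))) {
    for (h in c("left", "right")) {
      parts <- g[g$lobe == t1$lobe[i] & g$band == t1$band[i] &
                 g$hemisphere == h, ]
      stopifnot(nrow(parts) == 3)
      recon <- sum(w[parts$age_group] * parts$mean) / sum(w)
      printed <- t1[[paste0("mean_", h)]][i]
      expect_lte(abs(round(recon, 2) - printed), 0.01 + 1e-9)
    }
  }
})

test_that("deviation reports compare features against the bundle", {
  feats <- new("SubjectFeatures", age = 30,
               logPS = matrix(1, 8, 4,
                              dimnames = list(names(lobeGrouping("all")),
                                              names(eegBands()))),
               sse = setNames(rep(4.5, 8), names(lobeGrouping("all"))),
               coh = matrix(0.2, 8, 4,
                            dimnames = list(names(lobeGrouping("all")),
                                            names(eegBands()))),
               pdrFreq = c(left = 10, right = 10),
               pdrAmp = c(left = 20, right = 20))
  rep_ <- deviationReport(feats)
  expect_true(all(c("pdr.freq.left", "sse.PO_right") %in% rep_$feature))
  row <- rep_[rep_$feature == "pdr.freq.left", ]
  expect_equal(row$deviation, 10 - evaluateNormative(
    normativeBundle()$pdr.freq.left, 30), tolerance = 1e-9)
})
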