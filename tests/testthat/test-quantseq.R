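test_that("signal ratio uses only the segregating peaks and is scale invariant", {
  expect_equal(signalRatio(c(G = 800, A = 0), "G", "A"), 0)
  expect_equal(signalRatio(c(G = 400, A = 400, C = 90, T = 3), "G", "A"), 50)
  h <- c(A = 120, C = 7, G = 260, T = 2)
  r1 <- signalRatio(h, "G", "A")
  for (k in c(0.01, 3, 1e6)) {
    expect_equal(signalRatio(k * h, "G", "A"), r1, tolerance = 1e-12)
  }
  expect_error(signalRatio(c(G = 0, A = 0, C = 50, T = 0), "G", "A"),
               "unquantifiable")
  expect_error(signalRatio(c(G = 10), "G", "A"), "both segregating")
})

test_that("identity calibration gives a=1, b=0, r2=1 and limits 0/100", {
  fr <- c(0, 10, 30, 50, 70, 90, 100)
  cur <- fitCalibration(fr, fr, mutation = "identity")
  expect_equal(cur@slope, 1, tolerance = 1e-12)
  expect_equal(cur@intercept, 0, tolerance = 1e-10)
  expect_equal(cur@r2, 1, tolerance = 1e-12)
  expect_identical(detectionLimits(cur), c(lower = 0, upper = 100))
})

test_that("calibration rejects degenerate designs", {
  expect_error(fitCalibration(c(0, 50, 100), c(0, 50, 100)), "5 distinct")
  expect_error(fitCalibration(rep(50, 6), rnorm(6, 50)), "5 distinct")
  fr <- c(0, 10, 30, 50, 70, 90, 100)
  expect_error(fitCalibration(fr, rep(40, 7)), "slope")
})

test_that("detection limits are monotone in the calibration noise level", {
  fr <- c(0, 10, 30, 50, 70, 90, 100)
  set.seed(14)
  z <- rnorm(7)  # one fixed noise shape, scaled
  lastLo <- -Inf; lastUp <- Inf
  for (sd in c(1, 2, 4, 8)) {
    cur <- fitCalibration(fr, fr + sd * z)
    dl <- detectionLimits(cur)
    expect_gt(dl["lower"], lastLo)
    expect_lt(dl["upper"], lastUp)
    lastLo <- dl["lower"]; lastUp <- dl["upper"]
  }
})

test_that("inverse prediction round-trips simulated pools within detection limits", {
  set.seed(52)
  std <- simulateStandards(noiseSd = 0.03)
  cur <- fitCalibration(std$resistant_fraction, std$signal_ratio, "m")
  for (p in c(0.3, 0.7)) {
    est <- replicate(50, {
      h <- simulateChromatogram(p, noiseSd = 0.03)
      predictFrequency(signalRatio(h, "G", "A"), cur)$frequency
    })
    expect_lt(abs(mean(est) - 100 * p), 3)
  }
})

test_that("estimates are clipped to [0,100] and censoring status is deterministic", {
  fr <- c(0, 10, 30, 50, 70, 90, 100)
  set.seed(6)
  cur <- fitCalibration(fr, fr + rnorm(7, sd = 3))
  dl <- detectionLimits(cur)
  est <- predictFrequency(c(-20, 2, 50, 99, 130), cur)
  expect_true(all(est$frequency >= 0 & est$frequency <= 100))
  expect_identical(est$status,
                   ifelse(est$frequency < dl["lower"], "below_detection",
                          ifelse(est$frequency > dl["upper"],
                                 "above_detection", "quantified")))
  # ratio at the intercept inverts to 0%
  at_b <- predictFrequency(cur@intercept, cur)
  expect_equal(at_b$frequency, 0)
  expect_identical(at_b$status, "below_detection")
})

test_that("detection limits of a simulated panel sit in the field-observed range", {
  set.seed(503)
  dls <- replicate(12, {
    s <- simulateStandards(noiseSd = 0.03)
    detectionLimits(fitCalibration(s$resistant_fraction, s$signal_ratio))
  })
  # published panels report lower limits 4.5-21.9% and upper 89.1-97.5%
  expect_gt(mean(dls["lower", ]), 4.5)
  expect_lt(mean(dls["lower", ]), 21.9)
  expect_gt(mean(dls["upper", ]), 100 - 21.9)
  expect_lt(mean(dls["upper", ]), 100 - 4.5)
})

test_that("pure-susceptible and pure-resistant pools land at the scale ends", {
  set.seed(77)
  std <- simulateStandards(noiseSd = 0.02)
  cur <- fitCalibration(std$resistant_fraction, std$signal_ratio, "m")
  sus <- replicate(20, predictFrequency(
    signalRatio(simulateChromatogram(0, noiseSd = 0.02), "G", "A"),
    cur)$frequency)
  res <- replicate(20, predictFrequency(
    signalRatio(simulateChromatogram(1, noiseSd = 0.02), "G", "A"),
    cur)$frequency)
  expect_lt(mean(sus), 5)
  expect_gt(mean(res), 95)
})

test_that("batchPanel fills a complete matrix, marks absent assays nd, and is order invariant", {
  set.seed(31)
  panel <- suppressWarnings(loadMutationPanel())
  muts <- head(panel$abbreviation, 3)
  strains <- paste0("S", 1:4)
  curves <- list()
  peaks <- list()
  for (m in muts) {
    def <- panel[panel$abbreviation == m, ][1, ]
    std <- simulateStandards(noiseSd = 0.02, wild_nt = def$wild_nt,
                             mutant_nt = def$mutant_nt)
    curves[[m]] <- fitCalibration(std$resistant_fraction, std$signal_ratio, m)
    for (s in strains) {
      h <- simulateChromatogram(runif(1), noiseSd = 0.02,
                                wild_nt = def$wild_nt,
                                mutant_nt = def$mutant_nt)
      peaks[[length(peaks) + 1L]] <- data.frame(
        sample = s, mutation = m, height_A = h[["A"]], height_C = h[["C"]],
        height_G = h[["G"]], height_T = h[["T"]])
    }
  }
  peaks <- do.call(rbind, peaks)
  peaks <- peaks[-2, ]  # one absent assay
  got <- batchPanel(peaks, curves, panel)
  expect_identical(dim(got$frequency), c(4L, 3L))
  expect_identical(sum(is.na(got$frequency)), 1L)
  # shuffled rows give the same matrix up to row order
  shuffled <- peaks[sample(nrow(peaks)), ]
  got2 <- batchPanel(shuffled, curves, panel)
  expect_equal(got2$frequency[rownames(got$frequency), colnames(got$frequency)],
               got$frequency)
  # missing curve: nd column plus warning, not failure
  expect_warning(got3 <- batchPanel(peaks, curves[muts[-1]], panel),
                 "no curve")
  expect_true(all(is.na(got3$frequency[, muts[1]])))
})
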