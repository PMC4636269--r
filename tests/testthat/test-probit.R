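test_that("MLE equals the exhaustive grid-search maximizer on small assays", {
  cases <- list(
    list(dose = c(0.5, 1, 2, 4), n = rep(80L, 4), y = c(8L, 30L, 55L, 74L)),
    list(dose = c(0.01, 0.05, 0.2, 1), n = rep(60L, 4), y = c(5L, 20L, 41L, 58L)),
    list(dose = c(1, 3, 9), n = rep(100L, 3), y = c(20L, 52L, 85L))
  )
  for (cs in cases) {
    d <- bioassayDataset("s", "a", cs$dose, cs$n, cs$y)
    fit <- fitProbit(d)
    gs <- gridSearchProbit(cs$dose, cs$n, cs$y)
    expect_lt(abs(fit@coef[["alpha"]] - gs$alpha), 1e-3 + gs$resolution[1])
    expect_lt(abs(fit@coef[["beta"]] - gs$beta), 1e-3 + gs$resolution[2])
  }
})

test_that("symmetric three-dose toy puts the LD50 at the middle dose", {
  d <- bioassayDataset("s", "a", dose = c(1, 10, 100),
                       n_treated = rep(100L, 3), n_dead = c(0L, 50L, 100L))
  fit <- suppressWarnings(fitProbit(d))
  expect_equal(unname(ldP(fit, 0.5)["dose"]), 10, tolerance = 0.01)
})

test_that("parameter recovery: slope within 3 SE of truth on a large assay", {
  # truth alpha = -2, beta = 2 on log10 ppm => LD50 = 10 ppm
  d <- simulateBioassay(ld50 = 10, slope = 2, doses = 10^seq(0, 2.5, 0.5),
                        nPerDose = 500, doseUnit = "ppm", seed = 11)
  fit <- fitProbit(d)
  expect_lt(abs(fit@coef[["beta"]] - 2) / fit@se[["beta"]], 3)
  expect_equal(unname(ldP(fit, 0.5)["dose"]), 10, tolerance = 0.1)
})

test_that("LDp quantiles obey the probit closed form and monotonicity", {
  d <- simulateBioassay(ld50 = 0.2, slope = 2.5, seed = 5)
  fit <- fitProbit(d)
  beta <- fit@coef[["beta"]]
  l50 <- unname(ldP(fit, 0.5)["dose"])
  l90 <- unname(ldP(fit, 0.9)["dose"])
  expect_equal(l50 * 10^(qnorm(0.9) / beta), l90, tolerance = 1e-12)
  # ld_p(0.5) = 10^(-alpha/beta) when c = 0
  expect_equal(l50, 10^(-fit@coef[["alpha"]] / beta), tolerance = 1e-12)
  ps <- c(0.1, 0.3, 0.5, 0.7, 0.9, 0.99)
  lds <- vapply(ps, function(p) ldP(fit, p)[["dose"]], numeric(1))
  expect_true(all(diff(lds) > 0))
  # intervals bracket the point estimate, both CI methods
  for (m in c("delta", "fieller")) {
    q <- ldP(fit, 0.9, ci = m)
    expect_true(q["lower"] < q["dose"] && q["dose"] < q["upper"])
  }
})

test_that("diagnostic dose is exactly two-fold the unrounded LD90", {
  fit <- fitProbit(simulateBioassay(ld50 = 0.05, slope = 1.8, seed = 8))
  dd <- diagnosticDose(fit)
  expect_identical(dd@value, 2 * unname(ldP(fit, 0.9)["dose"]))
  expect_identical(dd@factor, 2)
  # unit case: LD90 = 1 => D/D = 2
  unitFit <- probitFitFromParams(ld50 = 10^(-qnorm(0.9) / 2), slope = 2)
  expect_equal(diagnosticDose(unitFit)@value, 2, tolerance = 1e-12)
})

test_that("Pearson chi2 has the nominal type-I rate under the true model", {
  set.seed(401)
  reject <- logical(1000)
  for (i in seq_along(reject)) {
    d <- simulateBioassay(ld50 = 0.1, slope = 2, nPerDose = 50)
    fit <- suppressWarnings(fitProbit(d))
    reject[i] <- fit@chi2 > qchisq(0.95, fit@df)
  }
  expect_gte(mean(reject), 0.02)
  expect_lte(mean(reject), 0.09)
})

test_that("significant lack of fit triggers heterogeneity scaling and wider CIs", {
  # systematically non-probit mortality pattern
  d <- bioassayDataset("s", "a", dose = c(0.1, 0.3, 1, 3, 10, 30),
                       n_treated = rep(100L, 6),
                       n_dead = c(5L, 60L, 20L, 90L, 40L, 99L))
  fit <- fitProbit(d)
  expect_gt(fit@chi2, qchisq(0.95, fit@df))
  expect_gt(fit@heterogeneity, 1)
  expect_true(fit@useT)
  # an on-model fit of the same size is not scaled
  fit0 <- fitProbit(simulateBioassay(ld50 = 1, slope = 2, seed = 2,
                                     nPerDose = 100))
  expect_identical(fit0@heterogeneity, 1)
})

test_that("natural response is recovered when control correction is on", {
  d <- simulateBioassay(ld50 = 0.1, slope = 2, nPerDose = 200,
                        naturalResponse = 0.12, nControls = 5, seed = 21)
  fit <- fitProbit(d, controlCorrection = TRUE)
  expect_lt(abs(fit@naturalResponse - 0.12), 0.06)
  expect_equal(unname(ldP(fit, 0.5)["dose"]), 0.1, tolerance = 0.25)
  # without correction c stays 0 and control rows are ignored
  fit0 <- fitProbit(d)
  expect_identical(fit0@naturalResponse, 0)
})

test_that("degenerate and underdetermined inputs error; negative slope is flagged", {
  expect_error(fitProbit(bioassayDataset("s", "a", c(1, 10), c(50L, 50L),
                                         c(10L, 40L))),
               "3 distinct")
  expect_error(fitProbit(bioassayDataset("s", "a", c(1, 10, 100), rep(50L, 3),
                                         rep(0L, 3))),
               "non-identifiable")
  decreasing <- bioassayDataset("s", "a", c(1, 10, 100), rep(100L, 3),
                                c(90L, 50L, 10L))
  fit <- suppressWarnings(fitProbit(decreasing))
  expect_false(fit@validSlope)
  expect_error(ldP(fit, 0.9), "slope")
})

test_that("ppm-to-surface conversion matches the vial geometry", {
  expect_equal(ppmToSurfaceDose(0), 0)
  expect_equal(ppmToSurfaceDose(500, volume_ul = 200, vial_area_cm2 = 20),
               500 * 200 * 1e-3 / 20)
  expect_error(ppmToSurfaceDose(1, vial_area_cm2 = 0), "positive")
  expect_error(ppmToSurfaceDose(-1), "non-negative")
})

test_that("diagnostic-dose mortality uses the Wilson interval", {
  for (cs in list(c(0L, 17L), c(15L, 15L), c(7L, 16L))) {
    got <- mortalityAtDD(cs[1], cs[2])
    expect_equal(unname(got["mortality"]), 100 * cs[1] / cs[2])
    expect_equal(unname(got[c("lower", "upper")]),
                 100 * wilsonInterval(cs[1], cs[2]), tolerance = 1e-9)
  }
  expect_error(mortalityAtDD(1, 0), "positive")
  expect_equal(unname(mortalityAtDD(3, 17, threshold = 90)["resistant"]), 1)
})

test_that("a susceptible strain at its own diagnostic dose dies almost completely", {
  fit <- fitProbit(simulateBioassay(ld50 = 0.1, slope = 2, nPerDose = 200,
                                    seed = 33))
  dd <- diagnosticDose(fit)@value
  pAtDD <- pnorm(fit@coef[["alpha"]] + fit@coef[["beta"]] * log10(dd))
  expect_gt(pAtDD, 0.97)
})

test_that("batch fitting never fails and marks unfittable assays nd", {
  good <- simulateBioassay(ld50 = 0.1, slope = 2, seed = 3)
  bad <- bioassayDataset("s2", "a", c(1, 10, 100), rep(50L, 3), rep(50L, 3))
  rep <- fitProbitBatch(list(good, bad))
  expect_identical(rep$status, c("ok", "nd"))
  expect_true(is.na(rep$ld50[2]))
  expect_equal(rep$dd[1], 2 * rep$ld90[1])
})
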