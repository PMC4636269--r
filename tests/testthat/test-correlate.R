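test_that("Spearman rho matches the rank-formula oracle, ties included", {
  set.seed(19)
  for (i in 1:20) {
    n <- sample(4:8, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    if (i %% 3 == 0) x[2] <- x[1]  # force ties
    got <- spearmanCor(x, y)
    expect_equal(got$rho, spearmanRhoOracle(x, y), tolerance = 1e-12)
    expect_identical(got$n_used, n)
  }
})

test_that("exact p-value equals the permutation-enumeration oracle at n = 6", {
  set.seed(23)
  x <- rnorm(6); y <- rnorm(6)
  got <- spearmanCor(x, y, exact = TRUE)
  rx <- rank(x); ry <- rank(y)
  obs <- spearmanRhoOracle(x, y)
  rhos <- vapply(allPerms(6), function(p) cor(rx, ry[p]), numeric(1))
  pTwoSided <- min(1, 2 * min(mean(rhos >= obs - 1e-12),
                              mean(rhos <= obs + 1e-12)))
  expect_equal(got$p_value, pTwoSided, tolerance = 1e-10)
})

test_that("rho is invariant under strictly monotone transforms", {
  set.seed(40)
  x <- runif(10); y <- runif(10)
  base <- spearmanCor(x, y)$rho
  expect_equal(spearmanCor(exp(5 * x), y)$rho, base)
  expect_equal(spearmanCor(x, log(y + 1))$rho, base)
  expect_equal(spearmanCor(rank(x), y^3)$rho, base)
})

test_that("nd pairs are deleted pairwise and degenerate inputs return nd rho", {
  x <- c(1, 2, NA, 4, 5, 6)
  y <- c(2, 4, 6, NA, 10, 12)
  got <- spearmanCor(x, y)
  expect_identical(got$n_used, 4L)
  expect_equal(got$rho, 1)
  expect_true(is.na(spearmanCor(rep(3, 5), 1:5)$rho))
  expect_true(is.na(spearmanCor(c(1, 2, NA, NA, NA), c(5, 4, 1, 2, 3))$rho))
})

test_that("monotone identity gives rho = 1", {
  x <- sort(runif(8))
  expect_equal(spearmanCor(x, x)$rho, 1)
})

test_that("correlation matrix: diagonal, symmetry, flags and permutation invariance", {
  set.seed(71)
  n <- 12
  f <- matrix(runif(n * 3, 0, 100), n,
              dimnames = list(sprintf("S%02d", 1:n), c("m1", "m2", "m3")))
  f[, 3] <- f[, 1]  # duplicated locus
  m <- matrix(runif(n * 2, 0, 100), n,
              dimnames = list(rownames(f), c("a1", "a2")))
  m[3, 1] <- NA  # nd cell
  panel <- resistancePanel(m, f)

  ff <- correlationMatrix(panel, "frequency_vs_frequency")
  expect_equal(unname(diag(ff$rho)), rep(1, 3))
  expect_equal(ff$rho, t(ff$rho))
  expect_equal(ff$rho["m1", "m3"], 1)

  mf <- correlationMatrix(panel, "mortality_vs_frequency")
  expect_identical(dim(mf$rho), c(3L, 2L))
  expect_identical(unname(mf$n["m1", "a1"]), 11)  # nd row dropped pairwise
  expect_identical(unname(mf$flags[!is.na(mf$p) & mf$p < 0.01]),
                   rep("**", sum(!is.na(mf$p) & mf$p < 0.01)))
  expect_true(all(mf$flags[!is.na(mf$p) & mf$p >= 0.05] == ""))

  # shuffling strains of both matrices together changes nothing
  ix <- sample(n)
  panel2 <- resistancePanel(m[ix, ], f[ix, ])
  mf2 <- correlationMatrix(panel2, "mortality_vs_frequency")
  expect_equal(mf2$rho, mf$rho)
  expect_equal(mf2$p, mf$p)
})

test_that("linked loci in a simulated panel show strong cross-correlation", {
  set.seed(90)
  p <- runif(12)
  freq2 <- cbind(locusA = p, locusB = pmin(pmax(p + rnorm(12, 0, 0.02), 0), 1))
  lp <- simulateLinkedPanel(trueFreq = freq2, RRmax = c(50, 50),
                            noiseSd = 0.02, seed = 91)
  ff <- correlationMatrix(lp$panel, "frequency_vs_frequency")
  expect_gt(ff$rho["locusA", "locusB"], 0.9)
})

test_that("heat map writer annotates every cell, renders nd, and is deterministic", {
  m <- matrix(c(10.24, NA, 99.95, 0), 2, 2,
              dimnames = list(c("S1", "S2"), c("a", "b")))
  labels <- renderHeatmap(m, file = NULL, tableFile = NULL)
  expect_identical(dim(labels), dim(m))
  expect_identical(labels["S2", "a"], "nd")
  expect_identical(labels["S1", "a"], "10.2")
  t1 <- tempfile(fileext = ".tsv"); t2 <- tempfile(fileext = ".tsv")
  png1 <- tempfile(fileext = ".png")
  renderHeatmap(m, file = png1, tableFile = t1)
  renderHeatmap(m, file = NULL, tableFile = t2)
  expect_identical(readBin(t1, "raw", file.size(t1)),
                   readBin(t2, "raw", file.size(t2)))
  expect_true(file.size(png1) > 0)
  expect_error(renderHeatmap(matrix(numeric(0), 0, 0)), "empty")
})
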