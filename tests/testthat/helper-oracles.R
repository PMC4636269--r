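# Independent oracles, kept free of the implementation paths they check.

# Binomial-probit log-likelihood, written directly from the model
probitLogLik <- function(alpha, beta, dose, n, y) {
  p <- pmin(pmax(pnorm(alpha + beta * log10(dose)), 1e-12), 1 - 1e-12)
  sum(y * log(p) + (n - y) * log1p(-p))
}

# Exhaustive grid-search maximizer with successive refinement; the final
# grid step bounds the resolution of the oracle.
gridSearchProbit <- function(dose, n, y, alphaRange = c(-10, 10),
                             betaRange = c(0.05, 10), steps = 5, width = 51) {
  ar <- alphaRange; br <- betaRange
  best <- c(NA, NA); da <- NA; db <- NA
  for (s in seq_len(steps)) {
    as <- seq(ar[1], ar[2], length.out = width)
    bs <- seq(br[1], br[2], length.out = width)
    ll <- outer(as, bs, Vectorize(function(a, b) probitLogLik(a, b, dose, n, y)))
    ix <- which(ll == max(ll), arr.ind = TRUE)[1, ]
    best <- c(as[ix[1]], bs[ix[2]])
    da <- diff(ar) / (width - 1); db <- diff(br) / (width - 1)
    # wide re-centred window so the joint maximum of the (possibly ridged)
    # likelihood stays inside at every refinement
    ar <- best[1] + c(-5, 5) * da
    br <- best[2] + c(-5, 5) * db
  }
  list(alpha = best[1], beta = best[2], resolution = c(da, db))
}

# Wilson score interval written from the closed form
wilsonInterval <- function(x, n, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  phat <- x / n
  centre <- (phat + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(centre - half, centre + half)
}

# Spearman rho from the rank definition (average ranks, Pearson on ranks)
spearmanRhoOracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# All permutations of 1..n (n small)
allPerms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in allPerms(n - 1)) {
    for (i in 0:(n - 1)) {
      out[[length(out) + 1L]] <- append(p, n, after = i)
    }
  }
  out
}
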