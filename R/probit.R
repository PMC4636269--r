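#' Construct a BioassayDataset
#'
#' @param strain,acaricide labels.
#' @param dose numeric vector of doses (0 marks control vials).
#' @param n_treated,n_dead integer vectors, per vial.
#' @param doseUnit `"ug/cm2"` (default) or `"ppm"`.
#' @param exposure_h exposure time in hours (default 8, the RCV endpoint).
#' @param replicate optional replicate labels.
#' @return a [BioassayDataset-class].
#' @examples
#' d <- bioassayDataset("PyriF", "bifenazate",
#'                      dose = c(0.02, 0.06, 0.2, 0.6),
#'                      n_treated = rep(48, 4), n_dead = c(3, 14, 38, 47))
#' d
#' @export
bioassayDataset <- function(strain, acaricide, dose, n_treated, n_dead,
                            doseUnit = "ug/cm2", exposure_h = 8,
                            replicate = seq_along(dose)) {
  obs <- data.frame(
    dose = as.numeric(dose),
    n_treated = as.integer(n_treated),
    n_dead = as.integer(n_dead),
    exposure_h = rep_len(as.numeric(exposure_h), length(dose)),
    replicate = rep_len(replicate, length(dose))
  )
  new("BioassayDataset", strain = as.character(strain),
      acaricide = as.character(acaricide),
      doseUnit = doseUnit, observations = obs)
}

setMethod("show", "BioassayDataset", function(object) {
  obs <- object@observations
  trt <- obs[obs$dose > 0, , drop = FALSE]
  cat("BioassayDataset:", object@strain, "x", object@acaricide, "\n")
  cat("  ", length(unique(trt$dose)), "distinct doses (", object@doseUnit,
      "), ", sum(trt$n_treated), "mites treated,",
      sum(obs$dose == 0), "control vials\n")
})

negLogLikProbit <- function(par, l10d, n, y, isControl, estimateC) {
  alpha <- par[1]; beta <- par[2]
  cc <- if (estimateC) stats::plogis(par[3]) else 0
  p <- cc + (1 - cc) * stats::pnorm(alpha + beta * l10d)
  p[isControl] <- cc
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(y * log(p) + (n - y) * log1p(-p))
}

#' Fit a probit dose-mortality model by maximum likelihood
#'
#' Fits `P(death | d) = c + (1 - c) * Phi(alpha + beta * log10 d)` to
#' vial-level binomial counts. With `controlCorrection = FALSE` (the
#' default, matching assays without an explicit solvent control) `c = 0`
#' and the fit is the exact binomial-probit MLE via [stats::glm()]. With
#' `controlCorrection = TRUE` and dose-0 control rows present, the natural
#' response `c` is estimated jointly by direct likelihood maximisation.
#'
#' Goodness of fit is the Pearson chi-square over distinct positive doses
#' (replicates pooled) with `df = k - `(number of fitted parameters). When
#' the chi-square exceeds its 0.05 critical value, the Finney heterogeneity
#' convention is applied: the parameter covariance is inflated by chi2/df
#' and interval quantiles switch from normal to t(df).
#'
#' @param data a [BioassayDataset-class] (or a data.frame with columns
#'   `dose`, `n_treated`, `n_dead`).
#' @param controlCorrection estimate natural response from dose-0 rows?
#' @return a [ProbitFit-class]. A fitted slope <= 0 is flagged (with a
#'   warning) via the `validSlope` slot rather than an error, so batch
#'   runs can carry a structured not-determined result.
#' @examples
#' d <- simulateBioassay(ld50 = 0.1, slope = 2, doses = 10^seq(-2, 0.5, 0.5),
#'                       nPerDose = 60, seed = 1)
#' fit <- fitProbit(d)
#' fit
#' ldP(fit, 0.9)
#' @export
fitProbit <- function(data, controlCorrection = FALSE) {
  if (is(data, "BioassayDataset")) {
    obs <- data@observations
    strain <- data@strain; acaricide <- data@acaricide; unit <- data@doseUnit
  } else {
    obs <- as.data.frame(data)
    strain <- if (!is.null(obs$strain)) as.character(obs$strain[1]) else NA_character_
    acaricide <- if (!is.null(obs$acaricide)) as.character(obs$acaricide[1]) else NA_character_
    unit <- if (!is.null(obs$dose_unit)) as.character(obs$dose_unit[1]) else "ug/cm2"
  }
  trt <- obs[obs$dose > 0, , drop = FALSE]
  ctl <- obs[obs$dose == 0, , drop = FALSE]
  k <- length(unique(trt$dose))
  if (k < 3L) stop("at least 3 distinct positive doses are required")
  totDead <- sum(trt$n_dead); totN <- sum(trt$n_treated)
  if (totDead == 0L || totDead == totN) {
    stop("non-identifiable fit: all-alive or all-dead across every dose")
  }

  l10d <- log10(trt$dose)
  estimateC <- controlCorrection && nrow(ctl) > 0

  if (!estimateC) {
    gfit <- stats::glm(cbind(n_dead, n_treated - n_dead) ~ l10d,
                       family = stats::binomial(link = "probit"), data = trt)
    cf <- unname(stats::coef(gfit))
    alpha <- cf[1]; beta <- cf[2]
    V <- unname(stats::vcov(gfit))
    cc <- 0
    npar <- 2L
  } else {
    g0 <- stats::glm(cbind(n_dead, n_treated - n_dead) ~ l10d,
                     family = stats::binomial(link = "probit"), data = trt)
    c0 <- max(sum(ctl$n_dead) / sum(ctl$n_treated), 1e-3)
    start <- c(stats::coef(g0), stats::qlogis(min(c0, 0.5)))
    ll10 <- c(l10d, rep(0, nrow(ctl)))
    nn <- c(trt$n_treated, ctl$n_treated)
    yy <- c(trt$n_dead, ctl$n_dead)
    isC <- c(rep(FALSE, nrow(trt)), rep(TRUE, nrow(ctl)))
    opt <- stats::optim(unname(start), negLogLikProbit, l10d = ll10, n = nn, y = yy,
                        isControl = isC, estimateC = TRUE,
                        method = "BFGS", hessian = TRUE,
                        control = list(maxit = 500, reltol = 1e-12))
    alpha <- opt$par[1]; beta <- opt$par[2]
    cc <- stats::plogis(opt$par[3])
    Vfull <- tryCatch(solve(opt$hessian), error = function(e) {
      matrix(NA_real_, 3, 3)
    })
    V <- Vfull[1:2, 1:2, drop = FALSE]
    npar <- 3L
  }

  validSlope <- beta > 0
  if (!validSlope) warning("fitted probit slope is not positive; LDp undefined")

  # Pearson GOF over distinct doses, replicates pooled
  agg <- stats::aggregate(cbind(n_dead, n_treated) ~ dose, data = trt, FUN = sum)
  phat <- cc + (1 - cc) * stats::pnorm(alpha + beta * log10(agg$dose))
  phat <- pmin(pmax(phat, 1e-12), 1 - 1e-12)
  ex <- agg$n_treated * phat
  chi2 <- sum((agg$n_dead - ex)^2 / (agg$n_treated * phat * (1 - phat)))
  df <- as.integer(k - npar)

  het <- 1; useT <- FALSE
  if (df > 0 && chi2 > stats::qchisq(0.95, df)) {
    het <- chi2 / df
    V <- V * het
    useT <- TRUE
  }

  new("ProbitFit",
      strain = strain, acaricide = acaricide, doseUnit = unit,
      coef = c(alpha = alpha, beta = beta),
      se = c(alpha = sqrt(V[1, 1]), beta = sqrt(V[2, 2])),
      vcov = V, naturalResponse = cc,
      chi2 = chi2, df = df, heterogeneity = het, useT = useT,
      nTotal = as.integer(totN), validSlope = validSlope)
}

#' Build a ProbitFit from published summary parameters
#'
#' Reconstructs the deterministic part of a probit fit from an LD50 and a
#' slope as printed in a toxicity table, so quantile operations
#' ([ldP()], [diagnosticDose()]) can be applied to published parameters.
#' No covariance is available from such summaries, so interval estimates
#' are reported as NA.
#'
#' @param ld50 median lethal dose (same unit as `doseUnit`).
#' @param slope probit slope per log10 dose.
#' @param slopeSE optional slope standard error (stored, not used for CIs
#'   without the full covariance).
#' @param strain,acaricide,doseUnit labels.
#' @return a [ProbitFit-class] with NA covariance.
#' @examples
#' fit <- probitFitFromParams(ld50 = 0.083, slope = 2.9,
#'                            acaricide = "bifenazate")
#' ldP(fit, 0.9)["dose"]   # implied LD90
#' @export
probitFitFromParams <- function(ld50, slope, slopeSE = NA_real_,
                                strain = "reference", acaricide = NA_character_,
                                doseUnit = "ug/cm2") {
  stopifnot(ld50 > 0, slope > 0)
  alpha <- -slope * log10(ld50)
  new("ProbitFit",
      strain = strain, acaricide = acaricide, doseUnit = doseUnit,
      coef = c(alpha = alpha, beta = slope),
      se = c(alpha = NA_real_, beta = slopeSE),
      vcov = matrix(NA_real_, 2, 2), naturalResponse = 0,
      chi2 = NA_real_, df = NA_integer_, heterogeneity = 1, useT = FALSE,
      nTotal = NA_integer_, validSlope = TRUE)
}

#' @describeIn ldP delta-method (default) or Fieller 95% limits on the
#'   log10-dose scale; quantiles from t(df) when heterogeneity scaling is
#'   in force, else normal.
#' @param ci `"delta"` or `"fieller"`.
#' @param level confidence level (default 0.95).
#' @export
setMethod("ldP", "ProbitFit", function(fit, p, ci = c("delta", "fieller"),
                                       level = 0.95) {
  ci <- match.arg(ci)
  stopifnot(length(p) == 1L, p > 0, p < 1)
  beta <- fit@coef[["beta"]]; alpha <- fit@coef[["alpha"]]
  if (!fit@validSlope || beta <= 0) {
    stop("undefined quantile: fitted slope is not positive")
  }
  cc <- fit@naturalResponse
  if (p <= cc) stop("target mortality does not exceed the natural response")
  padj <- (p - cc) / (1 - cc)
  z <- stats::qnorm(padj)
  g <- (z - alpha) / beta
  dose <- 10^g
  V <- fit@vcov
  out <- c(dose = dose, lower = NA_real_, upper = NA_real_)
  if (!anyNA(V)) {
    q <- if (fit@useT) stats::qt(1 - (1 - level) / 2, fit@df)
         else stats::qnorm(1 - (1 - level) / 2)
    if (ci == "delta") {
      varg <- (V[1, 1] + 2 * g * V[1, 2] + g^2 * V[2, 2]) / beta^2
      half <- q * sqrt(varg)
      out["lower"] <- 10^(g - half)
      out["upper"] <- 10^(g + half)
    } else {
      A <- beta^2 - q^2 * V[2, 2]
      B <- -2 * (beta * (z - alpha) + q^2 * V[1, 2])
      C <- (z - alpha)^2 - q^2 * V[1, 1]
      disc <- B^2 - 4 * A * C
      if (A > 0 && disc >= 0) {
        m <- sort((-B + c(-1, 1) * sqrt(disc)) / (2 * A))
        out["lower"] <- 10^m[1]
        out["upper"] <- 10^m[2]
      } else {
        warning("Fieller interval is unbounded; returning NA limits")
      }
    }
  }
  out
})

#' @describeIn diagnosticDose exactly two-fold the (unrounded) LD90.
#' @export
setMethod("diagnosticDose", "ProbitFit", function(fit, ...) {
  ld90 <- unname(ldP(fit, 0.9)["dose"])
  new("DiagnosticDose", value = 2 * ld90, unit = fit@doseUnit,
      basis = ld90, factor = 2)
})

setMethod("show", "ProbitFit", function(object) {
  cat("ProbitFit:", object@strain, "x", object@acaricide, "\n")
  cat(sprintf("  slope = %.3g +/- %.2g, alpha = %.3g, natural response = %.3g\n",
              object@coef[["beta"]], object@se[["beta"]],
              object@coef[["alpha"]], object@naturalResponse))
  cat(sprintf("  Pearson chi2 = %.3g on %s df (heterogeneity %.3g%s)\n",
              object@chi2, object@df, object@heterogeneity,
              if (object@useT) ", t quantiles" else ""))
  if (object@validSlope) {
    l50 <- ldP(object, 0.5); l90 <- ldP(object, 0.9)
    cat(sprintf("  LD50 = %.3g (%.3g-%.3g) %s\n", l50["dose"], l50["lower"],
                l50["upper"], object@doseUnit))
    cat(sprintf("  LD90 = %.3g (%.3g-%.3g); D/D = %.3g\n", l90["dose"],
                l90["lower"], l90["upper"], 2 * l90["dose"]))
  } else {
    cat("  slope not positive: LDp not determined\n")
  }
})

setMethod("show", "DiagnosticDose", function(object) {
  cat(sprintf("DiagnosticDose: %.4g %s (= %d x LD90 %.4g)\n",
              object@value, object@unit, as.integer(object@factor),
              object@basis))
})

#' Convert a vial stock concentration (ppm) to a surface dose
#'
#' In the RCV bioassay a fixed aliquot of acaricide stock coats the inner
#' surface of a glass vial; the deposited mass per unit area is
#' `ppm * volume_ul * 1e-3 / vial_area_cm2` (ppm = ug/ml of stock). With
#' the defaults (100 ul aliquot, 16.39 cm2 of 5-ml vial wall) 1000 ppm
#' converts to 6.1 ug/cm2 and 0.3 ppm to 1.83e-3 ug/cm2.
#'
#' @param conc_ppm stock concentration(s), ppm (>= 0).
#' @param volume_ul aliquot volume in microlitres (default 100).
#' @param vial_area_cm2 coated surface area in cm2 (default 16.39).
#' @return dose(s) in ug/cm2.
#' @examples
#' ppmToSurfaceDose(c(0.3, 1000))
#' @export
ppmToSurfaceDose <- function(conc_ppm, volume_ul = 100, vial_area_cm2 = 16.39) {
  if (vial_area_cm2 <= 0) stop("vial_area_cm2 must be positive")
  if (volume_ul <= 0) stop("volume_ul must be positive")
  if (any(conc_ppm < 0)) stop("conc_ppm must be non-negative")
  conc_ppm * volume_ul * 1e-3 / vial_area_cm2
}

#' Mortality at the diagnostic dose, with a Wilson binomial interval
#'
#' @param n_dead,n_treated counts for the vial(s) run at the diagnostic
#'   dose (summed if vectors).
#' @param level confidence level (default 0.95).
#' @param threshold optional mortality threshold (%); when supplied the
#'   result carries a `resistant` flag (TRUE when mortality < threshold).
#' @return named numeric: `mortality`, `lower`, `upper` (%), `n`, and
#'   optionally `resistant` (0/1).
#' @examples
#' mortalityAtDD(15, 15)
#' mortalityAtDD(3, 17, threshold = 90)
#' @export
mortalityAtDD <- function(n_dead, n_treated, level = 0.95, threshold = NULL) {
  x <- sum(n_dead); n <- sum(n_treated)
  if (n <= 0) stop("n_treated must be positive")
  if (x < 0 || x > n) stop("n_dead must satisfy 0 <= n_dead <= n_treated")
  # prop.test without continuity correction is the Wilson score interval
  wi <- suppressWarnings(
    stats::prop.test(x, n, conf.level = level, correct = FALSE)$conf.int
  )
  out <- c(mortality = 100 * x / n, lower = 100 * wi[1], upper = 100 * wi[2],
           n = n)
  if (!is.null(threshold)) {
    out <- c(out, resistant = as.numeric(100 * x / n < threshold))
  }
  out
}

#' Fit probit models to a batch of assays, never failing the batch
#'
#' Applies [fitProbit()] to each strain x acaricide dataset; assays that
#' cannot be fitted (too few doses, degenerate mortality, non-positive
#' slope) yield a structured not-determined row instead of an error.
#'
#' @param datasets list of [BioassayDataset-class].
#' @param ... passed to [fitProbit()].
#' @return data.frame with one row per assay: labels, N, slope, slope_se,
#'   chi2, df, ld50/ld90 with limits, dd (diagnostic dose) and a `status`
#'   column (`"ok"` or `"nd"`).
#' @export
fitProbitBatch <- function(datasets, ...) {
  rows <- lapply(datasets, function(d) {
    base <- data.frame(strain = d@strain, acaricide = d@acaricide,
                       dose_unit = d@doseUnit,
                       N = sum(d@observations$n_treated[d@observations$dose > 0]),
                       slope = NA_real_, slope_se = NA_real_,
                       chi2 = NA_real_, df = NA_integer_,
                       ld50 = NA_real_, ld50_lo = NA_real_, ld50_hi = NA_real_,
                       ld90 = NA_real_, ld90_lo = NA_real_, ld90_hi = NA_real_,
                       dd = NA_real_, status = "nd",
                       stringsAsFactors = FALSE)
    fit <- tryCatch(suppressWarnings(fitProbit(d, ...)),
                    error = function(e) NULL)
    if (is.null(fit) || !fit@validSlope) return(base)
    l50 <- ldP(fit, 0.5); l90 <- ldP(fit, 0.9)
    base$slope <- fit@coef[["beta"]]; base$slope_se <- fit@se[["beta"]]
    base$chi2 <- fit@chi2; base$df <- fit@df
    base$ld50 <- l50[["dose"]]; base$ld50_lo <- l50[["lower"]]; base$ld50_hi <- l50[["upper"]]
    base$ld90 <- l90[["dose"]]; base$ld90_lo <- l90[["lower"]]; base$ld90_hi <- l90[["upper"]]
    base$dd <- 2 * l90[["dose"]]
    base$status <- "ok"
    base
  })
  do.call(rbind, rows)
}
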