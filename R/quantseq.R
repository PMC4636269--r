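#' Resistant-nucleotide signal ratio from chromatogram peak heights
#'
#' For a two-allele SNP the resistant signal ratio is
#' `100 * H_mut / (H_mut + H_wild)` using only the two segregating
#' nucleotides' peak heights at the substituted position; heights of the
#' other two nucleotides (background) are ignored. The ratio is invariant
#' to rescaling all heights by a positive constant.
#'
#' @param heights named numeric of peak intensities, names among
#'   `c("A","C","G","T")` (a full four-channel vector is fine).
#' @param wild_nt,mutant_nt the segregating nucleotides.
#' @return signal ratio in percent.
#' @examples
#' signalRatio(c(A = 800, C = 5, G = 0, T = 3), wild_nt = "A", mutant_nt = "G")
#' signalRatio(c(G = 400, A = 400), wild_nt = "G", mutant_nt = "A")
#' @export
signalRatio <- function(heights, wild_nt, mutant_nt) {
  if (!all(c(wild_nt, mutant_nt) %in% names(heights))) {
    stop("heights must carry entries for both segregating nucleotides")
  }
  hw <- as.numeric(heights[[wild_nt]])
  hm <- as.numeric(heights[[mutant_nt]])
  if (hw < 0 || hm < 0) stop("peak heights must be non-negative")
  if (hw + hm <= 0) stop("unquantifiable signal: both segregating peaks are zero")
  100 * hm / (hm + hw)
}

# Fixed-point solver for the detection limits: the half-width of the 95%
# inverse-prediction band on the frequency scale is
#   hw(x) = t * (s/|a|) * sqrt(1 + 1/n + (x - xbar)^2 / Sxx);
# the lower limit solves x = hw(x) (band separates from 0%), the upper
# solves x = 100 - hw(x).
dlHalfwidth <- function(x, tcrit, s, a, n, xbar, sxx) {
  tcrit * (s / abs(a)) * sqrt(1 + 1 / n + (x - xbar)^2 / sxx)
}

#' Fit a QS calibration curve for one mutation site
#'
#' Ordinary least-squares regression of observed signal ratio (%) on known
#' resistant-allele fraction (%) across the mixing standards, as used to
#' calibrate quantitative sequencing. Detection limits are where the 95%
#' inverse-prediction band separates from 0% and 100%: below the lower
#' limit an estimated frequency cannot be distinguished from pure
#' susceptible, above the upper limit not from pure resistant.
#'
#' @param resistant_fraction known resistant-allele fractions (%), at
#'   least 5 distinct values; the default mixing design is
#'   `c(0, 10, 30, 50, 70, 90, 100)`.
#' @param signal_ratio observed ratios (%) for the standards.
#' @param mutation mutation label.
#' @return a [CalibrationCurve-class].
#' @examples
#' fr <- c(0, 10, 30, 50, 70, 90, 100)
#' fitCalibration(fr, fr, mutation = "identity")  # noiseless: a=1, b=0, r2=1
#' @export
fitCalibration <- function(resistant_fraction, signal_ratio,
                           mutation = NA_character_) {
  x <- as.numeric(resistant_fraction); y <- as.numeric(signal_ratio)
  stopifnot(length(x) == length(y))
  if (length(unique(x)) < 5L) {
    stop("at least 5 distinct resistant fractions are required")
  }
  if (stats::var(x) == 0) stop("rank-deficient calibration: all fractions equal")
  fit <- stats::lm(y ~ x)
  a <- unname(stats::coef(fit)[2]); b <- unname(stats::coef(fit)[1])
  if (abs(a) < 1e-8) stop("non-informative calibration: slope is ~0")
  n <- length(x)
  sse <- sum(stats::residuals(fit)^2)
  s <- sqrt(sse / (n - 2))
  r2 <- 1 - sse / sum((y - mean(y))^2)
  xbar <- mean(x); sxx <- sum((x - xbar)^2)
  tc <- stats::qt(0.975, n - 2)

  if (s == 0) {
    lower <- 0; upper <- 100
  } else {
    fl <- function(x0) x0 - dlHalfwidth(x0, tc, s, a, n, xbar, sxx)
    fu <- function(x0) (100 - x0) - dlHalfwidth(x0, tc, s, a, n, xbar, sxx)
    lower <- if (fl(100) < 0) 100 else stats::uniroot(fl, c(0, 100))$root
    upper <- if (fu(0) < 0) 0 else stats::uniroot(fu, c(0, 100))$root
    lower <- min(max(lower, 0), 100)
    upper <- min(max(upper, 0), 100)
    if (!(lower < upper)) { # noise so large the bands overlap everywhere
      warning("detection bands overlap; curve is uninformative across [0,100]")
      lower <- 50 - 1e-6; upper <- 50 + 1e-6
    }
  }
  new("CalibrationCurve", mutation = as.character(mutation),
      slope = a, intercept = b, r2 = r2, residualSd = s,
      nPoints = as.integer(n), xbar = xbar, sxx = sxx,
      lowerDL = lower, upperDL = upper)
}

#' @describeIn detectionLimits lower/upper 95% detection limits (%).
#' @export
setMethod("detectionLimits", "CalibrationCurve", function(object) {
  c(lower = object@lowerDL, upper = object@upperDL)
})

setMethod("show", "CalibrationCurve", function(object) {
  cat("CalibrationCurve:", object@mutation, "\n")
  cat(sprintf("  ratio = %.4g * fraction + %.4g  (r2 = %.4f, s = %.3g, n = %d)\n",
              object@slope, object@intercept, object@r2, object@residualSd,
              object@nPoints))
  cat(sprintf("  95%% detection limits: %.1f%% - %.1f%%\n",
              object@lowerDL, object@upperDL))
})

#' Inverse-predict a resistance-allele frequency from a signal ratio
#'
#' Classical calibration: the point estimate is `(ratio - b) / a`, clipped
#' to [0, 100]; the 95% interval is the inverse-prediction interval of the
#' calibration regression. The censoring status is `below_detection` when
#' the point estimate falls under the lower detection limit,
#' `above_detection` when above the upper limit, else `quantified`.
#'
#' @param ratio observed signal ratio(s), %.
#' @param curve a [CalibrationCurve-class].
#' @param sample optional sample label(s).
#' @return data.frame with columns `sample`, `mutation`, `frequency`,
#'   `ci_lo`, `ci_hi`, `status`.
#' @examples
#' fr <- c(0, 10, 30, 50, 70, 90, 100)
#' set.seed(7)
#' cur <- fitCalibration(fr, fr + rnorm(7, sd = 2))
#' predictFrequency(c(1, 48, 99), cur)
#' @export
predictFrequency <- function(ratio, curve, sample = NA_character_) {
  stopifnot(is(curve, "CalibrationCurve"))
  a <- curve@slope; b <- curve@intercept
  if (abs(a) < 1e-8) stop("non-informative calibration: slope is ~0")
  raw <- (as.numeric(ratio) - b) / a
  freq <- pmin(pmax(raw, 0), 100)
  n <- curve@nPoints; s <- curve@residualSd
  tc <- stats::qt(0.975, n - 2L)
  half <- dlHalfwidth(freq, tc, s, a, n, curve@xbar, curve@sxx)
  lo <- pmin(pmax(freq - half, 0), 100)
  hi <- pmin(pmax(freq + half, 0), 100)
  status <- ifelse(freq < curve@lowerDL, "below_detection",
                   ifelse(freq > curve@upperDL, "above_detection", "quantified"))
  data.frame(sample = rep_len(as.character(sample), length(freq)),
             mutation = curve@mutation, frequency = freq,
             ci_lo = lo, ci_hi = hi, status = status,
             stringsAsFactors = FALSE)
}

#' Estimate allele frequencies for a panel of samples and mutations
#'
#' Applies [signalRatio()] + [predictFrequency()] across a peak table,
#' assembling the strains x mutations frequency matrix. Missing assays,
#' missing curves or unquantifiable signals become NA ('nd') cells with a
#' warning, never a batch failure. Duplicate sample x mutation rows (e.g.
#' both sequencing directions) are averaged on the ratio scale.
#'
#' @param peaks data.frame with columns `sample`, `mutation`, `height_A`,
#'   `height_C`, `height_G`, `height_T`.
#' @param curves named list of [CalibrationCurve-class], names = mutation
#'   abbreviations.
#' @param panel mutation panel data.frame (see [loadMutationPanel()])
#'   supplying `wild_nt`/`mutant_nt` per mutation.
#' @return list with `frequency` (matrix, % with NA for nd) and `details`
#'   (long data.frame of per-cell estimates).
#' @export
batchPanel <- function(peaks, curves, panel = loadMutationPanel()) {
  need <- c("sample", "mutation", "height_A", "height_C", "height_G", "height_T")
  if (!all(need %in% names(peaks))) {
    stop("peak table must have columns: ", paste(need, collapse = ", "))
  }
  samples <- unique(peaks$sample)
  muts <- unique(peaks$mutation)
  freq <- matrix(NA_real_, length(samples), length(muts),
                 dimnames = list(samples, muts))
  details <- list()
  for (m in muts) {
    def <- panel[panel$abbreviation == m, , drop = FALSE]
    cur <- curves[[m]]
    if (nrow(def) == 0 || is.null(cur)) {
      warning("no curve or panel definition for mutation '", m, "'; marked nd")
      next
    }
    sub <- peaks[peaks$mutation == m, , drop = FALSE]
    for (sm in unique(sub$sample)) {
      rows <- sub[sub$sample == sm, , drop = FALSE]
      ratios <- vapply(seq_len(nrow(rows)), function(i) {
        h <- c(A = rows$height_A[i], C = rows$height_C[i],
               G = rows$height_G[i], T = rows$height_T[i])
        tryCatch(signalRatio(h, def$wild_nt[1], def$mutant_nt[1]),
                 error = function(e) NA_real_)
      }, numeric(1))
      r <- mean(ratios, na.rm = TRUE)
      if (!is.finite(r)) {
        warning("unquantifiable signal for ", sm, " x ", m, "; marked nd")
        next
      }
      est <- predictFrequency(r, cur, sample = sm)
      freq[sm, m] <- est$frequency
      details[[length(details) + 1L]] <- est
    }
  }
  list(frequency = freq,
       details = if (length(details)) do.call(rbind, details) else NULL)
}
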