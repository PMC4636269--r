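#' @import methods
NULL

#' BioassayDataset: one strain x acaricide dose-mortality assay
#'
#' Container for the dose-mortality records of a single residual contact
#' vial (or leaf-dip) bioassay: one strain exposed to one acaricide over a
#' series of doses, with vial-level treated/dead counts.
#'
#' @slot strain character(1), strain label.
#' @slot acaricide character(1), acaricide label.
#' @slot doseUnit character(1), `"ug/cm2"` or `"ppm"`.
#' @slot observations data.frame with columns `dose` (>= 0; 0 marks control
#'   vials), `n_treated` (positive integer), `n_dead` (0 <= n_dead <=
#'   n_treated), `exposure_h` (positive, default 8) and `replicate`.
#'
#' @seealso [bioassayDataset()], [fitProbit()]
#' @export
setClass("BioassayDataset",
  slots = c(
    strain = "character",
    acaricide = "character",
    doseUnit = "character",
    observations = "data.frame"
  )
)

setValidity("BioassayDataset", function(object) {
  obs <- object@observations
  msg <- character()
  need <- c("dose", "n_treated", "n_dead", "exposure_h", "replicate")
  if (!all(need %in% names(obs))) {
    return(paste("observations must have columns:", paste(need, collapse = ", ")))
  }
  if (length(object@strain) != 1L || length(object@acaricide) != 1L) {
    msg <- c(msg, "strain and acaricide must be length-1 labels")
  }
  if (!object@doseUnit %in% c("ug/cm2", "ppm")) {
    msg <- c(msg, "doseUnit must be 'ug/cm2' or 'ppm'")
  }
  if (nrow(obs) > 0) {
    if (any(!is.finite(obs$dose)) || any(obs$dose < 0)) {
      msg <- c(msg, "doses must be finite and non-negative (0 only for controls)")
    }
    if (any(obs$n_treated <= 0)) msg <- c(msg, "n_treated must be positive")
    if (any(obs$n_dead < 0 | obs$n_dead > obs$n_treated)) {
      msg <- c(msg, "n_dead must satisfy 0 <= n_dead <= n_treated")
    }
    if (any(obs$exposure_h <= 0)) msg <- c(msg, "exposure_h must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' ProbitFit: fitted probit dose-mortality model
#'
#' Result of [fitProbit()]: maximum-likelihood estimates of the probit
#' regression of mortality on log10 dose, `P(death | d) = c + (1 - c) *
#' Phi(alpha + beta * log10 d)`, with Pearson goodness-of-fit and the
#' Finney/heterogeneity bookkeeping used for confidence intervals.
#'
#' @slot strain,acaricide,doseUnit labels carried from the input data.
#' @slot coef named numeric, `alpha` (intercept on the probit scale at
#'   log10 dose 0) and `beta` (slope per log10 dose).
#' @slot se named numeric, standard errors of `coef` (heterogeneity-scaled
#'   when invoked).
#' @slot vcov 2x2 variance-covariance matrix of `(alpha, beta)`
#'   (heterogeneity-scaled when invoked).
#' @slot naturalResponse numeric(1) in [0, 1): natural (control) mortality
#'   `c`; 0 unless control correction was requested and control rows exist.
#' @slot chi2 Pearson goodness-of-fit statistic over distinct doses.
#' @slot df residual degrees of freedom (distinct doses minus fitted
#'   parameters).
#' @slot heterogeneity chi2/df when lack of fit is significant at 0.05,
#'   else 1.
#' @slot useT logical; TRUE when heterogeneity scaling is in force, in which
#'   case interval quantiles come from t(df) instead of the normal.
#' @slot nTotal total mites treated (positive doses).
#' @slot validSlope logical; FALSE flags a non-positive fitted slope.
#'
#' @seealso [ldP()], [diagnosticDose()]
#' @export
setClass("ProbitFit",
  slots = c(
    strain = "character",
    acaricide = "character",
    doseUnit = "character",
    coef = "numeric",
    se = "numeric",
    vcov = "matrix",
    naturalResponse = "numeric",
    chi2 = "numeric",
    df = "integer",
    heterogeneity = "numeric",
    useT = "logical",
    nTotal = "integer",
    validSlope = "logical"
  )
)

setValidity("ProbitFit", function(object) {
  msg <- character()
  if (!identical(names(object@coef), c("alpha", "beta"))) {
    msg <- c(msg, "coef must be named c(alpha, beta)")
  }
  if (object@naturalResponse < 0 || object@naturalResponse >= 1) {
    msg <- c(msg, "naturalResponse must lie in [0, 1)")
  }
  if (!all(dim(object@vcov) == c(2L, 2L))) msg <- c(msg, "vcov must be 2x2")
  if (object@heterogeneity < 1) msg <- c(msg, "heterogeneity factor must be >= 1")
  if (length(msg)) msg else TRUE
})

#' DiagnosticDose: discriminating dose derived from a probit fit
#'
#' The diagnostic dose (D/D) used for single-dose resistance screening:
#' a fixed multiple (2) of the LD90 of the susceptible reference fit.
#'
#' @slot value positive dose, exactly `factor * basis`.
#' @slot unit dose unit.
#' @slot basis the (unrounded) LD90 the dose was derived from.
#' @slot factor the multiplier, fixed at 2.
#' @export
setClass("DiagnosticDose",
  slots = c(value = "numeric", unit = "character",
            basis = "numeric", factor = "numeric")
)

setValidity("DiagnosticDose", function(object) {
  if (!isTRUE(all.equal(object@value, object@factor * object@basis))) {
    return("value must equal factor * basis")
  }
  if (object@value <= 0) return("value must be positive")
  TRUE
})

#' CalibrationCurve: QS calibration regression for one mutation site
#'
#' Ordinary least-squares regression of resistant-nucleotide signal ratio
#' (%) on known resistant-allele fraction (%), with the sufficient
#' statistics needed for inverse prediction and the 95% detection limits.
#'
#' @slot mutation character(1), mutation abbreviation (e.g. "G228S").
#' @slot slope,intercept regression coefficients (ratio = slope * fraction
#'   + intercept).
#' @slot r2 coefficient of determination in [0, 1].
#' @slot residualSd residual standard deviation of the calibration (ratio
#'   scale, percentage points).
#' @slot nPoints number of calibration standards.
#' @slot xbar,sxx mean and centred sum of squares of the standard
#'   fractions (for prediction intervals).
#' @slot lowerDL,upperDL detection limits (%) at 95% confidence: below
#'   `lowerDL` an estimate cannot be distinguished from 0%, above
#'   `upperDL` not from 100%.
#' @seealso [fitCalibration()], [predictFrequency()]
#' @export
setClass("CalibrationCurve",
  slots = c(
    mutation = "character",
    slope = "numeric",
    intercept = "numeric",
    r2 = "numeric",
    residualSd = "numeric",
    nPoints = "integer",
    xbar = "numeric",
    sxx = "numeric",
    lowerDL = "numeric",
    upperDL = "numeric"
  )
)

setValidity("CalibrationCurve", function(object) {
  msg <- character()
  if (object@r2 < 0 || object@r2 > 1 + 1e-12) msg <- c(msg, "r2 must lie in [0, 1]")
  if (object@residualSd < 0) msg <- c(msg, "residualSd must be >= 0")
  if (object@nPoints < 3L) msg <- c(msg, "at least 3 calibration points required")
  if (!(object@lowerDL < object@upperDL)) msg <- c(msg, "lowerDL must be < upperDL")
  if (object@lowerDL < 0 || object@upperDL > 100) {
    msg <- c(msg, "detection limits must lie within [0, 100]")
  }
  if (length(msg)) msg else TRUE
})

#' ResistancePanel: paired phenotype and genotype matrices
#'
#' Strains x acaricides mortality matrix (% at the diagnostic dose) paired
#' with a strains x mutations resistance-allele frequency matrix (%), on a
#' shared strain axis. `NA` encodes not-determined ('nd') cells.
#'
#' @slot mortality numeric matrix, strains x acaricides, values in
#'   [0, 100] or NA.
#' @slot frequency numeric matrix, strains x mutations, values in
#'   [0, 100] or NA.
#' @seealso [resistancePanel()], [correlationMatrix()]
#' @export
setClass("ResistancePanel",
  slots = c(mortality = "matrix", frequency = "matrix")
)

setValidity("ResistancePanel", function(object) {
  msg <- character()
  m <- object@mortality; f <- object@frequency
  if (is.null(rownames(m)) || is.null(rownames(f))) {
    msg <- c(msg, "both matrices need strain rownames")
  } else if (!identical(rownames(m), rownames(f))) {
    msg <- c(msg, "mortality and frequency must share the same strain rownames")
  }
  rng <- range(c(m, f), na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 100)) {
    msg <- c(msg, "values must lie in [0, 100] (NA for nd)")
  }
  if (length(msg)) msg else TRUE
})
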