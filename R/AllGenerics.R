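#' Dose at which the fitted model predicts a given mortality
#'
#' @param fit a [ProbitFit-class] object.
#' @param p target mortality probability, 0 < p < 1.
#' @param ... further arguments (`ci`, `level`).
#' @return named numeric: `dose`, `lower`, `upper` (same unit as the fit).
#' @export
setGeneric("ldP", function(fit, p, ...) standardGeneric("ldP"))

#' Diagnostic (discriminating) dose: two-fold the LD90
#'
#' @param fit a [ProbitFit-class] object.
#' @param ... further arguments passed to methods.
#' @return a [DiagnosticDose-class] object.
#' @export
setGeneric("diagnosticDose", function(fit, ...) standardGeneric("diagnosticDose"))

#' @describeIn ResistancePanel-class mortality matrix accessor
#' @param x a `ResistancePanel`.
#' @export
setGeneric("mortality", function(x) standardGeneric("mortality"))

#' @describeIn ResistancePanel-class allele-frequency matrix accessor
#' @export
setGeneric("alleleFrequencies", function(x) standardGeneric("alleleFrequencies"))

#' @describeIn CalibrationCurve-class detection limits accessor
#' @param object a `CalibrationCurve`.
#' @export
setGeneric("detectionLimits", function(object) standardGeneric("detectionLimits"))
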