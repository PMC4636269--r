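#' Read a dose-mortality CSV into BioassayDatasets
#'
#' Expects the header `strain,acaricide,dose,dose_unit,n_treated,n_dead,
#' exposure_h,replicate` (column order free; `exposure_h`/`replicate`
#' optional). Rows are grouped by strain x acaricide. Malformed rows
#' (`n_dead > n_treated`, negative dose, non-numeric fields) are dropped
#' into an error report with their line numbers instead of aborting.
#'
#' @param path CSV path (UTF-8, decimal point).
#' @return list with `datasets` (list of [BioassayDataset-class]) and
#'   `errors` (data.frame `line`, `message`; zero rows when clean).
#' @export
readBioassayCSV <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("strain", "acaricide", "dose", "dose_unit", "n_treated", "n_dead")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (is.null(raw$exposure_h)) raw$exposure_h <- 8
  if (is.null(raw$replicate)) raw$replicate <- 1L

  bad <- rep(NA_character_, nrow(raw))
  bad[!is.finite(raw$dose) | raw$dose < 0] <- "invalid dose"
  bad[is.na(bad) & (!is.finite(raw$n_treated) | raw$n_treated <= 0)] <- "invalid n_treated"
  bad[is.na(bad) & (!is.finite(raw$n_dead) | raw$n_dead < 0 |
                      raw$n_dead > raw$n_treated)] <- "n_dead outside [0, n_treated]"
  errors <- data.frame(line = which(!is.na(bad)) + 1L,  # +1 for the header
                       message = bad[!is.na(bad)], stringsAsFactors = FALSE)
  ok <- raw[is.na(bad), , drop = FALSE]

  datasets <- lapply(split(ok, list(ok$strain, ok$acaricide), drop = TRUE),
                     function(g) {
                       bioassayDataset(g$strain[1], g$acaricide[1],
                                       dose = g$dose, n_treated = g$n_treated,
                                       n_dead = g$n_dead,
                                       doseUnit = g$dose_unit[1],
                                       exposure_h = g$exposure_h,
                                       replicate = g$replicate)
                     })
  list(datasets = unname(datasets), errors = errors)
}

#' Write BioassayDatasets back to the dose-mortality CSV dialect
#'
#' @param datasets list of [BioassayDataset-class].
#' @param path output CSV path.
#' @export
writeBioassayCSV <- function(datasets, path) {
  rows <- lapply(datasets, function(d) {
    cbind(data.frame(strain = d@strain, acaricide = d@acaricide,
                     stringsAsFactors = FALSE),
          d@observations[c("dose")],
          data.frame(dose_unit = d@doseUnit),
          d@observations[c("n_treated", "n_dead", "exposure_h", "replicate")])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

purine <- c("A", "G")

#' Load the target-site mutation panel
#'
#' Loads a mutation panel (default: the packaged 18-row T. urticae panel of
#' target-site resistance substitutions across Tuace/AChE, Tuvssc/VSSC,
#' TuGluCl1, TuGluCl3, TuCHS1 and TuCytB) and validates every row:
#' wild/mutant codons must differ exactly at the stated substituted
#' position(s) with the stated nucleotides, and the substitution class must
#' match the purine/pyrimidine identities (transition = within class,
#' transversion = across). The wild amino acid implied by the wild codon
#' must match the abbreviation; a mutant-codon translation that disagrees
#' with the abbreviation only warns, since published panels contain such
#' rows.
#'
#' @param path CSV path; default the packaged panel.
#' @return data.frame, one row per mutation definition.
#' @examples
#' panel <- loadMutationPanel()
#' nrow(panel)            # 18 definitions
#' length(unique(panel$gene))  # 6 genes
#' @export
loadMutationPanel <- function(path = system.file("extdata",
                                                 "mutation_panel.csv",
                                                 package = "acariscan")) {
  panel <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(panel))) {
    row <- panel[i, ]
    wc <- strsplit(row$wild_codon, "")[[1]]
    mc <- strsplit(row$mutant_codon, "")[[1]]
    pos <- as.integer(strsplit(as.character(row$substituted_positions), ";")[[1]])
    lab <- paste0("row ", i, " (", row$abbreviation, ")")
    if (length(wc) != 3L || length(mc) != 3L) {
      stop(lab, ": codons must be 3 nt")
    }
    if (!identical(which(wc != mc), pos)) {
      stop(lab, ": codons must differ exactly at substituted position(s) ",
           paste(pos, collapse = ","))
    }
    if (!all(wc[pos] == row$wild_nt) || !all(mc[pos] == row$mutant_nt)) {
      stop(lab, ": substituted nucleotides disagree with the codons")
    }
    isTransition <- (row$wild_nt %in% purine) == (row$mutant_nt %in% purine)
    if (isTransition != (row$substitution_class == "transition")) {
      stop(lab, ": substitution class inconsistent with ",
           row$wild_nt, "->", row$mutant_nt)
    }
    wildAA <- seqinr::translate(seqinr::s2c(row$wild_codon))
    mutAA <- seqinr::translate(seqinr::s2c(row$mutant_codon))
    abWild <- substr(row$abbreviation, 1, 1)
    abPos <- gsub("[^0-9]", "", row$abbreviation)
    abMut <- substr(row$abbreviation, nchar(row$abbreviation),
                    nchar(row$abbreviation))
    if (wildAA != abWild || abPos != as.character(row$codon_position)) {
      stop(lab, ": abbreviation does not encode the wild codon/position")
    }
    if (mutAA != abMut) {
      warning(lab, ": mutant codon ", row$mutant_codon, " translates to ",
              mutAA, ", not ", abMut, " (kept as published)")
    }
  }
  panel
}

#' Packaged reference toxicity parameters (susceptible PyriF strain)
#'
#' Published probit toxicity parameters (N, slope +/- SE, chi-square, LD50
#' and LD90 with 95% limits, diagnostic dose) of the susceptible reference
#' strain for 19 acaricides, as determined by the 8-h residual contact
#' vial bioassay (etoxazole by leaf dip, in ppm). 'nd' cells (flufenoxuron,
#' RCV etoxazole) are returned as NA.
#'
#' @return data.frame, one row per acaricide.
#' @export
referenceToxicity <- function() {
  path <- system.file("extdata", "reference_toxicity_pyrif.csv",
                      package = "acariscan")
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "nd")
}

#' Write a publication-style probit toxicity report
#'
#' @param report data.frame from [fitProbitBatch()].
#' @param path TSV output path.
#' @param jsonPath optional machine-readable JSON path.
#' @export
writeProbitReport <- function(report, path, jsonPath = NULL) {
  disp <- report
  numcols <- vapply(disp, is.numeric, logical(1))
  disp[numcols] <- lapply(disp[numcols], signif, digits = 3)
  disp[] <- lapply(disp, function(col) ifelse(is.na(col), "nd", as.character(col)))
  utils::write.table(disp, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(jsonPath)) {
    jsonlite::write_json(report, jsonPath, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Serialize / restore calibration curves as JSON
#'
#' @param curves named list of [CalibrationCurve-class].
#' @param path JSON path.
#' @return `writeCurvesJSON` the path; `readCurvesJSON` the restored list.
#' @export
writeCurvesJSON <- function(curves, path) {
  lst <- lapply(curves, function(cu) list(
    mutation = cu@mutation, slope = cu@slope, intercept = cu@intercept,
    r2 = cu@r2, residual_sd = cu@residualSd, n_points = cu@nPoints,
    xbar = cu@xbar, sxx = cu@sxx,
    lower_dl = cu@lowerDL, upper_dl = cu@upperDL))
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeCurvesJSON
#' @export
readCurvesJSON <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(lst, function(e) new("CalibrationCurve",
    mutation = e$mutation, slope = e$slope, intercept = e$intercept,
    r2 = e$r2, residualSd = e$residual_sd, nPoints = as.integer(e$n_points),
    xbar = e$xbar, sxx = e$sxx, lowerDL = e$lower_dl, upperDL = e$upper_dl))
}

#' Read / write a strains x columns percentage matrix TSV
#'
#' Tabular dialect used for mortality and frequency matrices: first column
#' `strain`, remaining columns numeric percentages with the literal `nd`
#' for not-determined cells.
#'
#' @param path TSV path.
#' @return numeric matrix with strain rownames (NA for nd).
#' @export
readMatrixTSV <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "nd",
                           check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- tab[[1]]
  m
}

#' @rdname readMatrixTSV
#' @param m numeric matrix with rownames.
#' @param digits formatting digits (default 1, matching the display convention).
#' @export
writeMatrixTSV <- function(m, path, digits = 1) {
  out <- cbind(strain = rownames(m),
               as.data.frame(ifelse(is.na(m), "nd",
                                    formatC(m, format = "f", digits = digits)),
                             check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fit calibration curves for every mutation in a standards table
#'
#' @param standards data.frame with columns `mutation`,
#'   `resistant_fraction` and either `signal_ratio` or raw peak columns
#'   (`height_A` ... `height_T`, resolved against the mutation panel).
#' @param panel mutation panel (for raw peak columns).
#' @return named list of [CalibrationCurve-class].
#' @export
calibrateStandards <- function(standards, panel = loadMutationPanel()) {
  if (!"signal_ratio" %in% names(standards)) {
    standards$signal_ratio <- vapply(seq_len(nrow(standards)), function(i) {
      def <- panel[panel$abbreviation == standards$mutation[i], ][1, ]
      h <- c(A = standards$height_A[i], C = standards$height_C[i],
             G = standards$height_G[i], T = standards$height_T[i])
      signalRatio(h, def$wild_nt, def$mutant_nt)
    }, numeric(1))
  }
  curves <- lapply(split(standards, standards$mutation), function(g) {
    fitCalibration(g$resistant_fraction, g$signal_ratio,
                   mutation = g$mutation[1])
  })
  curves
}

#' Run the full monitoring pipeline
#'
#' Orchestrates the whole workflow on file inputs: probit fits and
#' diagnostic doses from a bioassay CSV; QS calibration from a standards
#' CSV and frequency prediction from a peak table; Spearman
#' phenotype-genotype correlation from the mortality matrix plus predicted
#' frequencies; annotated heat maps of both matrices. Stages whose inputs
#' are absent are recorded as skipped, never as errors.
#'
#' @param config named list (or path to a YAML file) with any of:
#'   `bioassay_csv`, `standards_csv`, `peaks_csv`, `mortality_tsv`,
#'   `out_dir` (required), `seed`, `ci` ("delta"/"fieller"), `exact`
#'   (logical), `control_correction` (logical).
#' @return invisibly, a list describing the stages run and output paths;
#'   also written to `out_dir/run_log.json`.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(!is.null(config$out_dir))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(config$seed)) set.seed(as.integer(config$seed))
  log <- list(seed = config$seed,
              package_version = as.character(utils::packageVersion("acariscan")),
              r_version = R.version.string,
              config = config[setdiff(names(config), "out_dir")],
              stages = list())
  paths <- list()

  # --- probit stage ---------------------------------------------------
  if (!is.null(config$bioassay_csv) && file.exists(config$bioassay_csv)) {
    rd <- readBioassayCSV(config$bioassay_csv)
    rep <- fitProbitBatch(rd$datasets,
                          controlCorrection = isTRUE(config$control_correction))
    paths$probit_report <- file.path(out, "probit_report.tsv")
    writeProbitReport(rep, paths$probit_report,
                      jsonPath = file.path(out, "probit_report.json"))
    log$stages$probit <- list(status = "run", assays = nrow(rep),
                              bad_rows = nrow(rd$errors))
  } else {
    log$stages$probit <- list(status = "skipped")
  }

  # --- QS stage --------------------------------------------------------
  curves <- NULL; freq <- NULL
  if (!is.null(config$standards_csv) && file.exists(config$standards_csv)) {
    std <- utils::read.csv(config$standards_csv, stringsAsFactors = FALSE)
    curves <- calibrateStandards(std)
    paths$curves <- file.path(out, "curves.json")
    writeCurvesJSON(curves, paths$curves)
    log$stages$qs_calibrate <- list(status = "run", curves = length(curves))
  } else {
    log$stages$qs_calibrate <- list(status = "skipped")
  }
  if (!is.null(curves) && !is.null(config$peaks_csv) &&
      file.exists(config$peaks_csv)) {
    peaks <- utils::read.csv(config$peaks_csv, stringsAsFactors = FALSE)
    bp <- suppressWarnings(batchPanel(peaks, curves))
    freq <- bp$frequency
    paths$frequencies <- file.path(out, "frequencies.tsv")
    writeMatrixTSV(freq, paths$frequencies)
    paths$frequency_heatmap <- file.path(out, "frequency_heatmap.png")
    renderHeatmap(freq, file = paths$frequency_heatmap,
                  main = "QS resistance-allele frequency (%)")
    log$stages$qs_predict <- list(status = "run", nd_cells = sum(is.na(freq)))
  } else {
    log$stages$qs_predict <- list(status = "skipped")
  }

  # --- correlation stage ----------------------------------------------
  if (!is.null(freq) && !is.null(config$mortality_tsv) &&
      file.exists(config$mortality_tsv)) {
    mort <- readMatrixTSV(config$mortality_tsv)
    shared <- intersect(rownames(mort), rownames(freq))
    panel <- resistancePanel(mort[shared, , drop = FALSE],
                             freq[shared, , drop = FALSE])
    cm <- correlationMatrix(panel, "mortality_vs_frequency",
                            exact = !isFALSE(config$exact))
    paths$correlations <- file.path(out, "correlations.tsv")
    utils::write.table(cm$table, paths$correlations, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths$mortality_heatmap <- file.path(out, "mortality_heatmap.png")
    renderHeatmap(mortality(panel), file = paths$mortality_heatmap,
                  main = "Mortality at diagnostic dose (%)")
    log$stages$correlate <- list(status = "run", strains = length(shared))
  } else {
    log$stages$correlate <- list(status = "skipped")
  }

  log$outputs <- paths
  jsonlite::write_json(log, file.path(out, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(log)
}

#' Write a fully synthetic input bundle for the pipeline
#'
#' Generates a seeded, ground-truthed bundle in the CSV/TSV dialects the
#' analysis readers consume: a susceptible-strain dose-response assay per
#' acaricide (`bioassay.csv`), QS mixing standards per mutation
#' (`standards.csv`), a strain x mutation peak table (`peaks.csv`, with a
#' few assays deliberately absent to exercise nd propagation) and a
#' strain x acaricide mortality matrix at the diagnostic doses
#' (`mortality.tsv`, one nd cell).
#'
#' @param outDir directory to write into (created if needed).
#' @param nStrains,nMutations,nAcaricides bundle dimensions (defaults: the
#'   12 x 12 x 4 monitoring layout).
#' @param noiseSd chromatogram noise level.
#' @param seed integer seed governing every random draw.
#' @return invisibly, list with the file paths and the ground truth.
#' @export
simulateBundle <- function(outDir, nStrains = 12, nMutations = 12,
                           nAcaricides = 4, noiseSd = 0.03, seed = 1) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  panel <- suppressWarnings(loadMutationPanel())
  muts <- utils::head(panel$abbreviation, nMutations)
  panel <- panel[panel$abbreviation %in% muts, ]
  strains <- sprintf("ST%02d", seq_len(nStrains))
  acaricides <- paste0("acaricide", seq_len(nAcaricides))
  ld50S <- stats::runif(nAcaricides, 0.02, 0.5)
  slope <- stats::runif(nAcaricides, 1.5, 3)
  RRmax <- stats::runif(nAcaricides, 20, 80)

  # true allele frequencies; first two strains are susceptible references
  truth <- matrix(stats::runif(nStrains * nMutations), nStrains, nMutations,
                  dimnames = list(strains, muts))
  truth[1:2, ] <- 0

  # susceptible-strain dose-mortality assays (probit stage input)
  assays <- lapply(seq_len(nAcaricides), function(j) {
    simulateBioassay(ld50 = ld50S[j], slope = slope[j],
                     strain = strains[1], acaricide = acaricides[j])
  })
  bioassayPath <- file.path(outDir, "bioassay.csv")
  writeBioassayCSV(assays, bioassayPath)

  # QS standards per mutation
  std <- do.call(rbind, lapply(muts, function(m) {
    def <- panel[panel$abbreviation == m, ][1, ]
    s <- simulateStandards(noiseSd = noiseSd, wild_nt = def$wild_nt,
                           mutant_nt = def$mutant_nt)
    cbind(mutation = m, s)
  }))
  standardsPath <- file.path(outDir, "standards.csv")
  utils::write.csv(std, standardsPath, row.names = FALSE, quote = FALSE)

  # peak table; drop two strain x mutation assays to exercise nd cells
  grid <- expand.grid(sample = strains, mutation = muts,
                      stringsAsFactors = FALSE)
  drop <- c(nrow(grid) - 1L, nrow(grid) %/% 2L)
  grid <- grid[-drop, ]
  peaks <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    def <- panel[panel$abbreviation == grid$mutation[i], ][1, ]
    h <- simulateChromatogram(truth[grid$sample[i], grid$mutation[i]],
                              noiseSd = noiseSd, wild_nt = def$wild_nt,
                              mutant_nt = def$mutant_nt)
    data.frame(sample = grid$sample[i], mutation = grid$mutation[i],
               height_A = h[["A"]], height_C = h[["C"]],
               height_G = h[["G"]], height_T = h[["T"]])
  }))
  peaksPath <- file.path(outDir, "peaks.csv")
  utils::write.csv(peaks, peaksPath, row.names = FALSE, quote = FALSE)

  # mortality at the (true) diagnostic dose; acaricide j linked to locus j
  nMites <- 51
  mort <- matrix(NA_real_, nStrains, nAcaricides,
                 dimnames = list(strains, acaricides))
  for (j in seq_len(nAcaricides)) {
    dd <- 2 * ld50S[j] * 10^(stats::qnorm(0.9) / slope[j])
    ld50 <- ld50S[j] * (1 + (RRmax[j] - 1) * truth[, j])
    p <- stats::pnorm(slope[j] * (log10(dd) - log10(ld50)))
    mort[, j] <- 100 * stats::rbinom(nStrains, nMites, p) / nMites
  }
  mort[nStrains, nAcaricides] <- NA  # one nd assay
  mortalityPath <- file.path(outDir, "mortality.tsv")
  writeMatrixTSV(mort, mortalityPath)

  invisible(list(
    paths = list(bioassay_csv = bioassayPath, standards_csv = standardsPath,
                 peaks_csv = peaksPath, mortality_tsv = mortalityPath),
    truth = list(freq = 100 * truth, ld50S = ld50S, slope = slope,
                 RRmax = RRmax, mortality = mort)
  ))
}
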