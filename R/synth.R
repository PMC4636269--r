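#' Simulate a binomial-probit bioassay
#'
#' Draws vial-level kill counts `n_dead ~ Binomial(n, c + (1 - c) *
#' Phi(alpha + beta * log10 d))` with `alpha = -slope * log10(ld50)` and
#' `beta = slope` — the sampling model the probit analysis assumes.
#' Deterministic under a fixed seed.
#'
#' @param ld50 true median lethal dose (> 0).
#' @param slope true probit slope per log10 dose (> 0).
#' @param doses vector of positive doses; the defaults span roughly
#'   LD10-LD99 of the default truth.
#' @param nPerDose mites per dose (scalar or per-dose vector); RCV vials
#'   hold 15-18 mites x 3 replicates, so ~50/dose is the realistic default.
#' @param naturalResponse control mortality c in [0, 1).
#' @param nControls number of dose-0 control vials (each `nPerDose` mites).
#' @param strain,acaricide,doseUnit labels for the returned dataset.
#' @param seed integer seed; NULL leaves the RNG stream untouched.
#' @return a [BioassayDataset-class].
#' @examples
#' simulateBioassay(ld50 = 0.1, slope = 2, seed = 42)
#' @export
simulateBioassay <- function(ld50 = 0.1, slope = 2,
                             doses = ld50 * 10^seq(-1.2, 1.2, length.out = 6),
                             nPerDose = 51, naturalResponse = 0,
                             nControls = 0,
                             strain = "sim", acaricide = "simAcaricide",
                             doseUnit = "ug/cm2", seed = NULL) {
  stopifnot(ld50 > 0, slope > 0, all(doses > 0),
            naturalResponse >= 0, naturalResponse < 1)
  if (!is.null(seed)) set.seed(seed)
  n <- rep_len(nPerDose, length(doses))
  p <- naturalResponse +
    (1 - naturalResponse) * stats::pnorm(slope * (log10(doses) - log10(ld50)))
  dead <- stats::rbinom(length(doses), n, p)
  d <- doses; nn <- n
  if (nControls > 0) {
    cdead <- stats::rbinom(nControls, rep_len(nPerDose, nControls)[1],
                           naturalResponse)
    d <- c(d, rep(0, nControls))
    nn <- c(nn, rep(rep_len(nPerDose, 1), nControls))
    dead <- c(dead, cdead)
  }
  bioassayDataset(strain, acaricide, dose = d, n_treated = nn, n_dead = dead,
                  doseUnit = doseUnit)
}

#' Simulate chromatogram peak heights for a pooled sample
#'
#' Two-allele peak model: the mutant and wild peaks have means `p * T` and
#' `(1 - p) * T` with Gaussian noise of standard deviation `noiseSd * T`,
#' truncated at zero; the two non-segregating nucleotides sit at a
#' baseline. This emulates mixing reference PCR products at known molar
#' ratios and reading the two peak intensities at the substituted position.
#'
#' @param fraction true resistant-allele fraction in [0, 1].
#' @param totalSignal mean total two-peak intensity T (arbitrary units).
#' @param noiseSd noise standard deviation as a fraction of T (default
#'   0.03, which reproduces calibration r2 in the high 0.98-0.999 range).
#' @param baseline mean background height of the other two nucleotides.
#' @param wild_nt,mutant_nt segregating nucleotides.
#' @param seed integer seed; NULL leaves the RNG stream untouched.
#' @return named numeric heights `c(A=, C=, G=, T=)`.
#' @examples
#' simulateChromatogram(0.3, seed = 1)
#' @export
simulateChromatogram <- function(fraction, totalSignal = 1000, noiseSd = 0.03,
                                 baseline = 5, wild_nt = "G", mutant_nt = "A",
                                 seed = NULL) {
  stopifnot(fraction >= 0, fraction <= 1, noiseSd >= 0, totalSignal > 0)
  if (!is.null(seed)) set.seed(seed)
  hm <- max(0, stats::rnorm(1, fraction * totalSignal, noiseSd * totalSignal))
  hw <- max(0, stats::rnorm(1, (1 - fraction) * totalSignal,
                            noiseSd * totalSignal))
  h <- c(A = 0, C = 0, G = 0, T = 0)
  others <- setdiff(names(h), c(wild_nt, mutant_nt))
  h[others] <- pmax(0, stats::rnorm(2, baseline, noiseSd * baseline))
  h[wild_nt] <- hw; h[mutant_nt] <- hm
  h
}

#' Simulate a QS calibration standard series
#'
#' @param fractions standard resistant fractions in percent (default the
#'   mixing design 0/10/30/50/70/90/100).
#' @param noiseSd,totalSignal,wild_nt,mutant_nt passed to
#'   [simulateChromatogram()].
#' @param seed integer seed.
#' @return data.frame `resistant_fraction`, `signal_ratio` (%).
#' @export
simulateStandards <- function(fractions = c(0, 10, 30, 50, 70, 90, 100),
                              noiseSd = 0.03, totalSignal = 1000,
                              wild_nt = "G", mutant_nt = "A", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ratio <- vapply(fractions / 100, function(p) {
    h <- simulateChromatogram(p, totalSignal, noiseSd,
                              wild_nt = wild_nt, mutant_nt = mutant_nt)
    signalRatio(h, wild_nt, mutant_nt)
  }, numeric(1))
  data.frame(resistant_fraction = fractions, signal_ratio = ratio)
}

#' Simulate a genotype-linked strain panel
#'
#' Creates the monotone genotype-to-phenotype link the correlation layer
#' tests for: each strain carries a true resistance-allele frequency
#' `p` per locus, its LD50 is shifted multiplicatively,
#' `LD50 = LD50_s * (1 + (RRmax - 1) * p)` (shifts multiply across loci),
#' mortality is observed at the susceptible-derived diagnostic dose
#' through [simulateBioassay()], and allele frequencies are observed
#' through [simulateChromatogram()] + [predictFrequency()] against a
#' simulated calibration curve per locus.
#'
#' @param nStrains number of strains (default 12, the panel size used in
#'   field monitoring).
#' @param trueFreq strains x loci matrix of true allele frequencies in
#'   [0, 1]; default spans 0-100% across strains.
#' @param ld50S susceptible-reference LD50.
#' @param slope probit slope (shared across strains).
#' @param RRmax resistance ratio at fixation (>= 1) per locus mapped to
#'   its acaricide.
#' @param nMites mites exposed per strain at the diagnostic dose.
#' @param noiseSd chromatogram noise (fraction of total signal); 0 gives
#'   the deterministic monotone link.
#' @param seed integer seed (one stream for the whole panel).
#' @return list: `panel` (a [ResistancePanel-class]), `truth` (list with
#'   `freq`, `ld50`, `dd`), `curves` (calibration curves per locus).
#' @export
simulateLinkedPanel <- function(nStrains = 12,
                                trueFreq = matrix(seq(0, 1, length.out = nStrains),
                                                  nStrains, 1,
                                                  dimnames = list(NULL, "locus1")),
                                ld50S = 0.1, slope = 2, RRmax = 50,
                                nMites = 51, noiseSd = 0.03, seed = NULL) {
  stopifnot(all(RRmax >= 1), all(trueFreq >= 0 & trueFreq <= 1))
  if (!is.null(seed)) set.seed(seed)
  trueFreq <- as.matrix(trueFreq)
  nLoci <- ncol(trueFreq)
  loci <- colnames(trueFreq)
  if (is.null(loci)) loci <- paste0("locus", seq_len(nLoci))
  colnames(trueFreq) <- loci
  strains <- sprintf("S%02d", seq_len(nStrains))
  rownames(trueFreq) <- strains
  RRmax <- rep_len(RRmax, nLoci)

  # susceptible-derived diagnostic dose (closed form: no estimation noise)
  ld90S <- ld50S * 10^(stats::qnorm(0.9) / slope)
  dd <- 2 * ld90S

  # per-locus multiplicative LD50 shift, multiplying across loci
  ld50 <- ld50S * apply(1 + sweep(trueFreq, 2, RRmax - 1, `*`), 1, prod)

  mort <- matrix(NA_real_, nStrains, nLoci,
                 dimnames = list(strains, paste0("acaricide_", loci)))
  for (j in seq_len(nLoci)) {
    ld50j <- ld50S * (1 + (RRmax[j] - 1) * trueFreq[, j])
    p <- stats::pnorm(slope * (log10(dd) - log10(ld50j)))
    if (noiseSd == 0) {
      mort[, j] <- 100 * p
    } else {
      mort[, j] <- 100 * stats::rbinom(nStrains, nMites, p) / nMites
    }
  }

  curves <- list()
  freq <- matrix(NA_real_, nStrains, nLoci, dimnames = list(strains, loci))
  for (j in seq_len(nLoci)) {
    std <- simulateStandards(noiseSd = noiseSd)
    curves[[loci[j]]] <- fitCalibration(std$resistant_fraction,
                                        std$signal_ratio, mutation = loci[j])
    for (i in seq_len(nStrains)) {
      h <- simulateChromatogram(trueFreq[i, j], noiseSd = noiseSd)
      r <- signalRatio(h, "G", "A")
      freq[i, j] <- predictFrequency(r, curves[[loci[j]]])$frequency
    }
  }
  list(panel = resistancePanel(mort, freq),
       truth = list(freq = 100 * trueFreq, ld50 = ld50, dd = dd),
       curves = curves)
}
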