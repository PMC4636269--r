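#' Spearman rank correlation with nd-aware deletion
#'
#' Rank correlation with average-rank tie handling. The p-value is the
#' exact null distribution of the rank statistic when `exact = TRUE`, the
#' sample is small (n <= 12) and untied; otherwise the t approximation.
#' Pairs with an NA ('nd') in either vector are dropped first.
#'
#' @param x,y numeric vectors of equal length (NA = nd).
#' @param exact use the exact null distribution when feasible
#'   (default TRUE; panels here have at most 12 strains).
#' @return list with `rho`, `p_value`, `n_used`, `method`. A constant
#'   vector yields `rho = NA` (undefined correlation), not an error.
#' @examples
#' spearmanCor(1:6, c(2, 1, 4, 3, 6, 5))
#' @export
spearmanCor <- function(x, y, exact = TRUE) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) {
    return(list(rho = NA_real_, p_value = NA_real_, n_used = n,
                method = "insufficient pairs"))
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n_used = n,
                method = "undefined (constant input)"))
  }
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  useExact <- exact && n <= 12L && !ties
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = useExact)
  )
  list(rho = unname(ct$estimate), p_value = ct$p.value, n_used = n,
       method = if (useExact) "exact" else "t approximation")
}

#' Construct a ResistancePanel
#'
#' @param mortality strains x acaricides matrix (% at diagnostic dose,
#'   NA = nd).
#' @param frequency strains x mutations matrix (% allele frequency,
#'   NA = nd). Rows are matched to `mortality` by strain name.
#' @return a [ResistancePanel-class].
#' @export
resistancePanel <- function(mortality, frequency) {
  mortality <- as.matrix(mortality); frequency <- as.matrix(frequency)
  if (!is.null(rownames(mortality)) && !is.null(rownames(frequency)) &&
      !identical(rownames(mortality), rownames(frequency)) &&
      setequal(rownames(mortality), rownames(frequency))) {
    frequency <- frequency[rownames(mortality), , drop = FALSE]
  }
  new("ResistancePanel", mortality = mortality, frequency = frequency)
}

setMethod("mortality", "ResistancePanel", function(x) x@mortality)
setMethod("alleleFrequencies", "ResistancePanel", function(x) x@frequency)

setMethod("show", "ResistancePanel", function(object) {
  cat("ResistancePanel:", nrow(object@mortality), "strains x",
      ncol(object@mortality), "acaricides /", ncol(object@frequency),
      "mutations\n")
  cat("  nd cells:", sum(is.na(object@mortality)), "mortality,",
      sum(is.na(object@frequency)), "frequency\n")
})

#' Cross-correlation matrix of a resistance panel
#'
#' Spearman correlations between all column pairs of the chosen matrices,
#' with pairwise nd deletion and significance flags (`*` p < 0.05, `**`
#' p < 0.01, on the raw p-values; an optional Benjamini-Hochberg column is
#' appended when `adjust = TRUE`).
#'
#' @param panel a [ResistancePanel-class].
#' @param mode `"mortality_vs_frequency"` (rows = mutations, columns =
#'   acaricides), `"frequency_vs_frequency"` or `"mortality_vs_mortality"`.
#' @param exact passed to [spearmanCor()].
#' @param adjust add BH-adjusted p-values to the long table?
#' @return list with matrices `rho`, `p`, `n`, `flags` and a tidy long
#'   data.frame `table`.
#' @export
correlationMatrix <- function(panel,
                              mode = c("mortality_vs_frequency",
                                       "frequency_vs_frequency",
                                       "mortality_vs_mortality"),
                              exact = TRUE, adjust = FALSE) {
  mode <- match.arg(mode)
  A <- switch(mode,
              mortality_vs_frequency = panel@frequency,
              frequency_vs_frequency = panel@frequency,
              mortality_vs_mortality = panel@mortality)
  B <- switch(mode,
              mortality_vs_frequency = panel@mortality,
              frequency_vs_frequency = panel@frequency,
              mortality_vs_mortality = panel@mortality)
  rho <- matrix(NA_real_, ncol(A), ncol(B),
                dimnames = list(colnames(A), colnames(B)))
  p <- rho; n <- rho
  for (i in seq_len(ncol(A))) {
    for (j in seq_len(ncol(B))) {
      r <- spearmanCor(A[, i], B[, j], exact = exact)
      rho[i, j] <- r$rho; p[i, j] <- r$p_value; n[i, j] <- r$n_used
    }
  }
  flags <- matrix("", nrow(rho), ncol(rho), dimnames = dimnames(rho))
  flags[!is.na(p) & p < 0.05] <- "*"
  flags[!is.na(p) & p < 0.01] <- "**"
  tab <- data.frame(
    row = rep(rownames(rho), times = ncol(rho)),
    col = rep(colnames(rho), each = nrow(rho)),
    rho = as.vector(rho), p_value = as.vector(p), n_used = as.vector(n),
    flag = as.vector(flags), stringsAsFactors = FALSE
  )
  if (adjust) tab$p_bh <- stats::p.adjust(tab$p_value, method = "BH")
  list(rho = rho, p = p, n = n, flags = flags, table = tab)
}

#' Render an annotated heat map and its underlying table
#'
#' Draws an annotated heat map with the actual value printed in each cell
#' and 'nd' marking not-determined cells, and writes the underlying matrix
#' as a TSV (values on the 0-100 scale, literal `nd` for NA). The table
#' writer is deterministic: identical input gives byte-identical output.
#'
#' @param mat numeric matrix (NA = nd).
#' @param file image path (`.png` or `.pdf`); NULL to skip drawing.
#' @param tableFile TSV path for the underlying table; NULL to skip.
#' @param main plot title.
#' @param digits digits for the cell annotations (default 1).
#' @return the annotated character matrix, invisibly.
#' @export
renderHeatmap <- function(mat, file = NULL, tableFile = NULL, main = "",
                          digits = 1) {
  mat <- as.matrix(mat)
  if (length(mat) == 0) stop("empty matrix")
  labels <- matrix(ifelse(is.na(mat), "nd",
                          formatC(mat, format = "f", digits = digits)),
                   nrow(mat), dimnames = dimnames(mat))
  if (!is.null(tableFile)) {
    out <- cbind(strain = rownames(mat),
                 as.data.frame(ifelse(is.na(mat), "nd",
                                      formatC(mat, format = "f", digits = digits))))
    utils::write.table(out, tableFile, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n")
  }
  if (!is.null(file)) {
    if (grepl("\\.pdf$", file)) grDevices::pdf(file, width = 8, height = 6)
    else grDevices::png(file, width = 1200, height = 900, res = 150)
    on.exit(grDevices::dev.off(), add = TRUE)
    pheatmap::pheatmap(mat, cluster_rows = FALSE, cluster_cols = FALSE,
                       display_numbers = labels, na_col = "grey85",
                       main = main, silent = FALSE)
  }
  invisible(labels)
}
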