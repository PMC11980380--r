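## Expression-linked statistics: TPM, decile stratification, metric-versus-
## expression regressions, neutrality plots, Benjamini-Hochberg correction
## and cross-taxon amino-acid slopes.

#' Transcripts per million from raw counts and raw lengths
#'
#' TPM_i = 1e6 (c_i / L_i) / sum_j (c_j / L_j), computed with the raw
#' transcript length (not an effective length), so the values sum to 1e6 per
#' cell by construction.
#'
#' @param readCounts Non-negative numeric vector of read counts for one cell.
#' @param lengths Positive numeric vector of transcript lengths (nt).
#' @return Numeric vector of TPM values summing to 1e6.
#' @export
tpm <- function(readCounts, lengths) {
  stopifnot(length(readCounts) == length(lengths))
  if (any(readCounts < 0, na.rm = TRUE)) stop("read counts must be non-negative")
  if (any(lengths <= 0, na.rm = TRUE)) stop("lengths must be positive")
  rate <- readCounts / lengths
  tot <- sum(rate, na.rm = TRUE)
  if (!is.finite(tot) || tot == 0) stop("all read counts are zero")
  1e6 * rate / tot
}

#' Expression decile bins
#'
#' Assigns each transcript to a decile of the cell's TPM distribution. Ranks
#' use ties.method = "min", so tied values (e.g. a block of zeros) share the
#' lower bin. Also returns masks for the bottom/top one and two deciles.
#'
#' @param x Numeric vector of TPM values for one cell (>= 10 positive values
#'   required).
#' @return List with \code{bin} (integer 1..10), and logical masks
#'   \code{bottom1}, \code{top1}, \code{bottom2}, \code{top2}.
#' @export
decileBins <- function(x) {
  if (sum(x > 0, na.rm = TRUE) < 10L)
    stop("decile stratification requires at least 10 transcripts with TPM > 0")
  n <- sum(!is.na(x))
  r <- rank(x, ties.method = "min", na.last = "keep")
  bin <- as.integer(floor((r - 1) * 10 / n) + 1L)
  bin[!is.na(bin) & bin > 10L] <- 10L
  list(bin = bin,
       bottom1 = !is.na(bin) & bin == 1L,
       top1 = !is.na(bin) & bin == 10L,
       bottom2 = !is.na(bin) & bin <= 2L,
       top2 = !is.na(bin) & bin >= 9L)
}

## internal: one regression row. Slope/intercept by OLS; p-value from the
## Spearman rank correlation (the paper's convention: slopes from linear
## regression, significance from Spearman).
.regressionRow <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("regression requires at least 3 paired finite values")
  if (stats::var(y) == 0) {
    return(data.frame(slope = 0, intercept = y[1L], spearmanRho = NA_real_,
                      pValue = NA_real_, qValue = NA_real_, n = n))
  }
  if (stats::var(x) == 0) {
    return(data.frame(slope = NA_real_, intercept = NA_real_,
                      spearmanRho = NA_real_, pValue = NA_real_,
                      qValue = NA_real_, n = n))
  }
  slope <- stats::cov(x, y) / stats::var(x)
  intercept <- mean(y) - slope * mean(x)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  data.frame(slope = slope, intercept = intercept,
             spearmanRho = unname(ct$estimate), pValue = ct$p.value,
             qValue = NA_real_, n = n)
}

#' Regression of a per-transcript metric on log10 TPM
#'
#' OLS slope of the metric on log10(TPM) with a Spearman rank-correlation
#' p-value, the construction used for codon-frequency-versus-expression and
#' GC-versus-expression slopes. Transcripts with TPM = 0 or missing values
#' are excluded (no pseudocount).
#'
#' @param metric Numeric vector (one value per transcript).
#' @param tpmValues Numeric vector of TPM values, same length.
#' @return One-row data.frame: slope, intercept, spearmanRho, pValue, qValue
#'   (NA until BH adjustment), n.
#' @export
metricVsLogTpm <- function(metric, tpmValues) {
  stopifnot(length(metric) == length(tpmValues))
  keep <- !is.na(tpmValues) & tpmValues > 0
  .regressionRow(log10(tpmValues[keep]), metric[keep])
}

#' Neutrality-plot slope (GC12 versus GC4)
#'
#' Per-gene regression of GC12 on GC4 over an optional transcript subset.
#' Under substitution bias alone the expected slope is 1; functional
#' constraint on amino acids drives it toward 0.
#'
#' @param gc12Values,gc4Values Numeric vectors, one value per transcript.
#' @param mask Optional logical subset (e.g. an expression decile).
#' @return One-row data.frame as in [metricVsLogTpm()]; slope NA when GC4 has
#'   no variance in the subset.
#' @export
neutralityPlot <- function(gc12Values, gc4Values, mask = NULL) {
  stopifnot(length(gc12Values) == length(gc4Values))
  if (is.null(mask)) mask <- rep(TRUE, length(gc4Values))
  .regressionRow(gc4Values[mask], gc12Values[mask])
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; a thin wrapper over
#' \code{p.adjust(..., method = "BH")} so every correction in the package
#' goes through one audited entry point. NAs are preserved.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Numeric vector of q-values.
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Cross-taxon amino-acid slopes against mean GC4
#'
#' For each amino acid, the slope of its mean usage frequency across taxa on
#' the taxa's mean GC4, computed separately for a lowly expressed and a
#' highly expressed gene set upstream. Under GC pressure, FYMINK slopes are
#' negative and GARP slopes positive; selection on amino-acid usage flattens
#' the slopes in highly expressed genes.
#'
#' @param aaFreqMatrix Numeric matrix, taxa x 20 amino acids (columns named
#'   with one-letter codes), of mean amino-acid frequencies for the chosen
#'   gene subset.
#' @param meanGc4 Numeric vector of per-taxon mean GC4 (length = nrow).
#' @return data.frame with one row per amino acid: aa, slope, intercept,
#'   spearmanRho, pValue, qValue (BH across the 20 amino acids), n.
#' @export
crossTaxonAaSlopes <- function(aaFreqMatrix, meanGc4) {
  stopifnot(nrow(aaFreqMatrix) == length(meanGc4))
  if (nrow(aaFreqMatrix) < 5L)
    stop("cross-taxon amino-acid slopes require at least 5 taxa")
  rows <- lapply(colnames(aaFreqMatrix), function(aa) {
    r <- .regressionRow(meanGc4, aaFreqMatrix[, aa])
    cbind(data.frame(aa = aa), r)
  })
  out <- do.call(rbind, rows)
  out$qValue <- bhAdjust(out$pValue)
  out
}
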