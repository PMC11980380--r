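## Codon-level statistics: counts, family frequencies, RSCU, Wright's
## effective number of codons (observed and composition-only expected),
## expected usage under single-nucleotide nulls, amino-acid usage and
## terminal stop-codon usage.

#' CodonCountTable: codon counts with family totals
#'
#' Codon counts for one scope (a transcript, a cell, or any pool), with
#' per-amino-acid totals and terminal stop counts kept alongside. Counts
#' exclude codons containing N; terminal stops are tallied separately and do
#' not enter the 61-codon count vector.
#'
#' @slot counts named integer(61), sense-codon counts.
#' @slot aaTotals named numeric(20), per-amino-acid totals.
#' @slot stopCounts named integer(3), terminal stop usage (TAA, TAG, TGA).
#' @slot scope character scalar label ("transcript", "cell", ...).
#' @exportClass CodonCountTable
setClass("CodonCountTable", representation(
  counts = "integer",
  aaTotals = "numeric",
  stopCounts = "integer",
  scope = "character"
))

setValidity("CodonCountTable", function(object) {
  msgs <- character(0)
  if (length(object@counts) != 61L) msgs <- c(msgs, "counts must have length 61")
  if (any(object@counts < 0L)) msgs <- c(msgs, "counts must be non-negative")
  if (length(object@stopCounts) != 3L) msgs <- c(msgs, "stopCounts must have length 3")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "CodonCountTable", function(object) {
  cat("CodonCountTable [", object@scope, "]: ",
      sum(object@counts), " sense codons, ",
      sum(object@stopCounts), " terminal stops\n", sep = "")
})

#' @describeIn countCodons Accessor for the 61-codon count vector.
#' @export
codonCounts <- function(table) table@counts

#' Count codons in coding sequences
#'
#' Tallies sense codons over one or more in-frame CDS. Terminal stop codons
#' are recorded separately in \code{stopCounts}; codons containing N (or any
#' non-ACGT character) and internal stop codons are excluded from all counts.
#'
#' @param cds Character vector of in-frame CDS or a DNAStringSet.
#' @param code A [GeneticCode-class] object.
#' @param scope Label stored on the resulting table.
#' @return A [CodonCountTable-class].
#' @examples
#' code <- standardGeneticCode()
#' tab <- countCodons("ATGGGGGGA", code)
#' codonCounts(tab)[c("ATG", "GGG", "GGA")]
#' @export
countCodons <- function(cds, code, scope = "cell") {
  allCods <- character(0)
  stops <- character(0)
  for (s in .asSeqChar(cds)) {
    sc <- .senseCodons(s, code)
    allCods <- c(allCods, sc$codons)
    if (!is.na(sc$terminalStop)) stops <- c(stops, sc$terminalStop)
  }
  counts <- table(factor(allCods, levels = code@senseCodons))
  stopCounts <- table(factor(stops, levels = code@stopSet))
  new("CodonCountTable",
      counts = setNames(as.integer(counts), code@senseCodons),
      aaTotals = .aaTotalsFromCounts(setNames(as.numeric(counts), code@senseCodons), code),
      stopCounts = setNames(as.integer(stopCounts), code@stopSet),
      scope = scope)
}

.aaTotalsFromCounts <- function(counts, code) {
  vapply(code@aaToCodons, function(cs) sum(counts[cs]), numeric(1))
}

#' Pool codon count tables
#'
#' @param tables List of [CodonCountTable-class] objects.
#' @param scope Label for the pooled table.
#' @return A [CodonCountTable-class] whose counts are the element-wise sums.
#' @export
poolCodonCounts <- function(tables, scope = "pooled") {
  stopifnot(length(tables) >= 1L)
  counts <- Reduce(`+`, lapply(tables, function(t) t@counts))
  stopCounts <- Reduce(`+`, lapply(tables, function(t) t@stopCounts))
  aaTot <- Reduce(`+`, lapply(tables, function(t) t@aaTotals))
  new("CodonCountTable", counts = counts, aaTotals = aaTot,
      stopCounts = stopCounts, scope = scope)
}

## internal: build table from a named numeric 61 count vector
.countTableFromVector <- function(counts, code, scope = "cell") {
  counts <- counts[code@senseCodons]
  new("CodonCountTable",
      counts = setNames(as.integer(round(counts)), code@senseCodons),
      aaTotals = .aaTotalsFromCounts(counts, code),
      stopCounts = setNames(integer(3), code@stopSet),
      scope = scope)
}

#' Codon frequency within its synonymous family
#'
#' The number of times a codon is used divided by the total number of times
#' its amino acid is used, the quantity shown in codon-usage heat maps (no
#' bias corresponds to 50% in a twofold family, 25% in a fourfold family).
#'
#' @param table A [CodonCountTable-class].
#' @param code A [GeneticCode-class].
#' @return Named numeric(61) of within-family frequencies; NA for codons whose
#'   family is unused.
#' @export
familyFrequencies <- function(table, code) {
  tot <- table@aaTotals[.aaOf(code, code@senseCodons)]
  out <- ifelse(tot > 0, table@counts / tot, NA_real_)
  setNames(out, code@senseCodons)
}

#' Relative synonymous codon usage (RSCU)
#'
#' RSCU_i = k n_i / n_a for a codon used n_i times in a family of k synonyms
#' used n_a times in total; 1 means usage proportional to equal usage, and
#' the values in a family sum to k.
#'
#' @inheritParams familyFrequencies
#' @return Named numeric(61); NA for unused families.
#' @export
rscu <- function(table, code) {
  k <- lengths(code@aaToCodons)[.aaOf(code, code@senseCodons)]
  unname(k) * familyFrequencies(table, code)
}

#' Wright's expected ENc under composition alone
#'
#' The composition-only null curve for the effective number of codons:
#' ENc*(s) = 2 + s + 29 / (s^2 + (1 - s)^2), where s is the silent-site GC
#' content (GC3S). At s = 0 the curve equals 31, the null used for taxa with
#' no G or C at silent third positions; at s = 1 it equals 32, and its
#' maximum of 60.5 minus epsilon lies near s = 0.5 (the value at 0.5 is 60.5).
#'
#' @param s Numeric vector of GC3S fractions in [0, 1].
#' @return Numeric vector of expected ENc values.
#' @examples
#' encExpected(c(0, 0.5, 1)) # 31, 60.5, 32
#' @export
encExpected <- function(s) {
  if (any(is.na(s)) || any(s < 0 | s > 1))
    stop("s must lie in [0, 1]")
  2 + s + 29 / (s^2 + (1 - s)^2)
}

## Wright's per-family codon homozygosity and class means, vectorized over
## the columns of a 61 x n count matrix. Families with fewer than 2
## occurrences, or with non-positive F-hat, are excluded from their class
## mean. A missing threefold mean (isoleucine unused) is replaced by the
## average of the twofold and fourfold means, per Wright's prescription;
## a missing twofold, fourfold or sixfold mean makes ENc NA.
.encFromCountMatrix <- function(M, code) {
  aaByCodon <- .aaOf(code, code@senseCodons)
  fams <- code@aaToCodons
  k <- lengths(fams)
  classes <- list(two = names(fams)[k == 2L],
                  three = names(fams)[k == 3L],
                  four = names(fams)[k == 4L],
                  six = names(fams)[k == 6L])
  n <- ncol(M)
  Fhat <- matrix(NA_real_, nrow = length(fams), ncol = n,
                 dimnames = list(names(fams), NULL))
  for (aa in names(fams)[k >= 2L]) {
    rows <- fams[[aa]]
    sub <- M[rows, , drop = FALSE]
    na <- colSums(sub)
    sump2 <- colSums(sub^2) / ifelse(na > 0, na^2, NA_real_)
    f <- (na * sump2 - 1) / (na - 1)
    f[na < 2L] <- NA_real_
    f[!is.na(f) & f <= 0] <- NA_real_
    Fhat[aa, ] <- f
  }
  classMean <- function(aas) {
    sub <- Fhat[aas, , drop = FALSE]
    cnt <- colSums(!is.na(sub))
    out <- colSums(sub, na.rm = TRUE) / ifelse(cnt > 0, cnt, NA_real_)
    out
  }
  F2 <- classMean(classes$two)
  F3 <- classMean(classes$three)
  F4 <- classMean(classes$four)
  F6 <- classMean(classes$six)
  F3 <- ifelse(is.na(F3), (F2 + F4) / 2, F3)
  enc <- 2 + 9 / F2 + 1 / F3 + 5 / F4 + 3 / F6
  enc[is.na(F2) | is.na(F4) | is.na(F6)] <- NA_real_
  enc <- pmin(enc, 61)
  nUsed <- colSums(!is.na(Fhat))
  list(enc = enc,
       classMeans = rbind(F2 = F2, F3 = F3, F4 = F4, F6 = F6),
       nFamiliesUsed = nUsed)
}

#' Observed effective number of codons (Wright)
#'
#' Computes ENc from a codon count table using Wright's per-family codon
#' homozygosity F-hat = (n_a sum p_i^2 - 1) / (n_a - 1) and the class
#' structure of the standard code (2 single-codon amino acids, 9 twofold, 1
#' threefold, 5 fourfold, 3 sixfold): ENc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6,
#' capped at 61. Families used fewer than twice (or with non-positive F-hat)
#' are dropped from their class mean; a missing isoleucine mean is replaced by
#' (F2 + F4)/2; if the twofold, fourfold or sixfold mean cannot be estimated
#' the result is NA.
#'
#' @param table A [CodonCountTable-class], or a named numeric(61) count vector.
#' @param code A [GeneticCode-class].
#' @return List with elements \code{enc} (numeric, in [20, 61] when defined),
#'   \code{classMeans} (named numeric: F2, F3, F4, F6) and
#'   \code{nFamiliesUsed}.
#' @export
encObserved <- function(table, code) {
  counts <- if (is(table, "CodonCountTable")) table@counts else table[code@senseCodons]
  M <- matrix(as.numeric(counts), ncol = 1, dimnames = list(code@senseCodons, NULL))
  res <- .encFromCountMatrix(M, code)
  list(enc = res$enc[1L],
       classMeans = res$classMeans[, 1L],
       nFamiliesUsed = res$nFamiliesUsed[1L])
}

#' Per-transcript ENc values
#'
#' Vectorized ENc over a set of CDS; transcripts shorter than
#' \code{minCodons} analyzable codons get NA (short genes give unstable
#' homozygosity estimates).
#'
#' @inheritParams countCodons
#' @param minCodons Minimum number of analyzable codons (default 100).
#' @return Numeric vector of ENc values.
#' @export
encPerTranscript <- function(cds, code, minCodons = 100L) {
  M <- .codonCountMatrix(cds, code)
  res <- .encFromCountMatrix(M, code)
  enc <- res$enc
  enc[colSums(M) < minCodons] <- NA_real_
  enc
}

## internal: 61 x n matrix of codon counts, one column per sequence
.codonCountMatrix <- function(cds, code) {
  seqs <- .asSeqChar(cds)
  cods <- lapply(seqs, function(s) .senseCodons(s, code)$codons)
  idx <- rep(seq_along(seqs), lengths(cods))
  tab <- table(factor(unlist(cods), levels = code@senseCodons),
               factor(idx, levels = seq_along(seqs)))
  M <- matrix(as.numeric(tab), nrow = 61L,
              dimnames = list(code@senseCodons, names(cds)))
  M
}

#' Expected within-family codon usage from third-position nucleotide content
#'
#' Expected codon frequencies in a synonymous family when usage is driven only
#' by single-nucleotide content at the silent position: p(codon) is
#' proportional to the frequency of its third-position nucleotide, restricted
#' to the family's codons and renormalized.
#'
#' @param aa One-letter amino-acid code.
#' @param ntFreqs Named numeric(4) of nucleotide frequencies (A, C, G, T),
#'   e.g. from silent sites or UTRs.
#' @param code A [GeneticCode-class].
#' @return Named numeric over the family's codons; NA if all allowed
#'   nucleotides have zero frequency.
#' @export
expectedCodonUsageFromNt <- function(aa, ntFreqs, code) {
  syn <- code@aaToCodons[[aa]]
  if (is.null(syn)) stop("unknown amino acid: ", aa)
  w <- ntFreqs[substr(syn, 3L, 3L)]
  tot <- sum(w)
  if (!is.finite(tot) || tot <= 0)
    return(setNames(rep(NA_real_, length(syn)), syn))
  setNames(as.numeric(w) / tot, syn)
}

#' Amino-acid usage with FYMINK and GARP fractions
#'
#' Amino-acid frequencies implied by a codon count table, plus the summed
#' frequencies of the AT-rich-codon amino acids (F, Y, M, I, N, K) and the
#' GC-rich-codon amino acids (G, A, R, P), the classic diagnostics of GC
#' pressure on proteomes.
#'
#' @inheritParams familyFrequencies
#' @return List with \code{freqs} (named numeric(20) summing to 1),
#'   \code{fyminkFrac} and \code{garpFrac}; all NA for an empty table.
#' @export
aaUsage <- function(table, code) {
  tot <- sum(table@aaTotals)
  if (tot == 0)
    return(list(freqs = setNames(rep(NA_real_, 20L), AA20),
                fyminkFrac = NA_real_, garpFrac = NA_real_))
  f <- table@aaTotals / tot
  list(freqs = f,
       fyminkFrac = sum(f[FYMINK]),
       garpFrac = sum(f[GARP]))
}

#' Hypothetical GC12 under equal codon usage
#'
#' The GC content at codon positions 1-2 implied by a set of amino-acid
#' frequencies when every amino acid uses its synonymous codons equally (no
#' codon usage bias): sum over amino acids of f_a times the mean G/C count at
#' positions 1 and 2 over the amino acid's synonyms, divided by 2.
#'
#' @param aaFreqs Named numeric(20) of amino-acid frequencies (summing to 1).
#' @param code A [GeneticCode-class].
#' @return A fraction in [0, 1].
#' @examples
#' code <- standardGeneticCode()
#' f <- setNames(rep(0, 20), c("A","C","D","E","F","G","H","I","K","L",
#'                             "M","N","P","Q","R","S","T","V","W","Y"))
#' f["G"] <- 1
#' hypotheticalGc12(f, code) # 1: glycine is GGN
#' @export
hypotheticalGc12 <- function(aaFreqs, code) {
  perAa <- vapply(names(code@aaToCodons), function(aa) {
    syn <- code@aaToCodons[[aa]]
    gcCount <- (substr(syn, 1L, 1L) %in% c("G", "C")) +
               (substr(syn, 2L, 2L) %in% c("G", "C"))
    mean(gcCount) / 2
  }, numeric(1))
  sum(aaFreqs[names(perAa)] * perAa)
}

#' Terminal stop-codon usage
#'
#' Frequencies of TAA, TAG and TGA among observed terminal stops.
#'
#' @param table A [CodonCountTable-class] (or list of them, pooled).
#' @return Named numeric(3) summing to 1, or all NA when no stop was observed.
#' @export
stopUsage <- function(table) {
  if (is.list(table)) table <- poolCodonCounts(table)
  tot <- sum(table@stopCounts)
  if (tot == 0)
    return(setNames(rep(NA_real_, 3L), names(table@stopCounts)))
  table@stopCounts / tot
}

#' Round percentages half-even
#'
#' Helper used when reporting family frequencies as percentages at two
#' decimals (IEC 60559 half-even, R's default rounding).
#'
#' @param x Numeric fractions.
#' @param digits Decimal places (default 2).
#' @return Numeric percentages.
#' @export
asPercent <- function(x, digits = 2L) round(100 * x, digits)
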