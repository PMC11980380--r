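## Per-cell aggregation (TaxonProfile) and the dataset-level analysis that
## reproduces the figure-level tables: composition summaries and bias
## categories, codon and amino-acid usage, ENc, SSDU, expression-stratified
## regressions, neutrality plots and cross-taxon amino-acid slopes.

#' TaxonProfile: per-cell aggregate of composition and usage statistics
#'
#' @slot cellId Cell label.
#' @slot codonTable A [CodonCountTable-class] pooled over the cell.
#' @slot transcriptStats data.frame, one row per transcript: nCodons, gc4,
#'   gc3s, gc12, enc, tpm, readCount, kmerCoverage.
#' @slot summaryStats Named numeric: medians and means of the per-transcript
#'   metrics, pooled silent-site skews, UTR GC means and skews.
#' @slot biasCategory One of AT-biased / intermediate / non-biased /
#'   GC-biased / unclassified (from median GC4).
#' @slot positionClassFreqs The cell's \code{PositionClassFreqs}.
#' @slot utrStats List: per-side GC, skews and dinucleotide bias.
#' @exportClass TaxonProfile
setClass("TaxonProfile", representation(
  cellId = "character",
  codonTable = "CodonCountTable",
  transcriptStats = "data.frame",
  summaryStats = "numeric",
  biasCategory = "character",
  positionClassFreqs = "list",
  utrStats = "list"
))

setMethod("show", "TaxonProfile", function(object) {
  ss <- object@summaryStats
  cat("TaxonProfile ", object@cellId, ": ",
      nrow(object@transcriptStats), " transcripts, ",
      sum(object@codonTable@counts), " codons\n",
      " median GC4 = ", signif(ss[["medianGc4"]], 3),
      ", median GC3S = ", signif(ss[["medianGc3s"]], 3),
      ", median ENc = ", signif(ss[["medianEnc"]], 4),
      " [", object@biasCategory, "]\n", sep = "")
})

#' @describeIn taxonProfile Accessor for the per-transcript statistics.
#' @export
transcriptStats <- function(object) object@transcriptStats

#' @describeIn taxonProfile Accessor for the bias category.
#' @export
biasCategory <- function(object) object@biasCategory

#' Build a TaxonProfile for one cell
#'
#' Computes per-transcript GC4, GC3S, GC12 and ENc, TPM from read counts and
#' raw transcript lengths, the pooled codon count table, silent-site skews,
#' per-taxon medians and means, the bias category, position/degeneracy-class
#' nucleotide frequencies and UTR composition (restricted to eligible UTRs
#' when an eligibility table is supplied).
#'
#' @param object A [TranscriptSet-class] restricted to one cell.
#' @param code A [GeneticCode-class].
#' @param utrEligibility Optional data.frame from [curateUtrs()].
#' @param minEncCodons Minimum codons for per-transcript ENc (default 100).
#' @return A [TaxonProfile-class].
#' @export
taxonProfile <- function(object, code = standardGeneticCode(),
                         utrEligibility = NULL, minEncCodons = 100L) {
  td <- object@transcriptData
  cellId <- unique(td$cellId)
  if (length(cellId) != 1L)
    stop("taxonProfile expects transcripts from exactly one cell")
  seqs <- setNames(as.character(object@cds), td$transcriptId)

  stats <- data.frame(
    transcriptId = td$transcriptId,
    nCodons = vapply(seqs, function(s)
      length(.senseCodons(s, code)$codons), numeric(1), USE.NAMES = FALSE),
    gc4 = gc4(seqs, code),
    gc3s = gc3s(seqs, code),
    gc12 = gc12(seqs, code),
    enc = encPerTranscript(seqs, code, minCodons = minEncCodons),
    readCount = td$readCount,
    kmerCoverage = td$kmerCoverage,
    stringsAsFactors = FALSE)
  stats$tpm <- if (all(is.na(td$readCount))) NA_real_ else
    tpm(ifelse(is.na(td$readCount), 0, td$readCount), nchar(seqs))

  tab <- countCodons(seqs, code, scope = cellId)
  silent <- silentThirdNucleotides(seqs, code, "gc3s")
  silentSkews <- skews(silent)

  utr5s <- td$utr5; utr3s <- td$utr3
  if (!is.null(utrEligibility)) {
    m <- match(td$transcriptId, utrEligibility$transcriptId)
    utr5s[utrEligibility$utr5Status[m] != "eligible"] <- NA
    utr3s[utrEligibility$utr3Status[m] != "eligible"] <- NA
  }
  utrStats <- list(
    utr5Gc = .utrGc(utr5s), utr3Gc = .utrGc(utr3s),
    utr5Skews = skews(paste(utr5s[!is.na(utr5s)], collapse = "")),
    utr3Skews = skews(paste(utr3s[!is.na(utr3s)], collapse = "")),
    utr5DinucBias = utrDinucleotideBias(utr5s),
    utr3DinucBias = utrDinucleotideBias(utr3s),
    nUtr5 = sum(!is.na(utr5s)), nUtr3 = sum(!is.na(utr3s)))

  med <- function(x) if (all(is.na(x))) NA_real_ else median(x, na.rm = TRUE)
  mn <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  summaryStats <- c(
    medianGc4 = med(stats$gc4), meanGc4 = mn(stats$gc4),
    medianGc3s = med(stats$gc3s), meanGc3s = mn(stats$gc3s),
    medianGc12 = med(stats$gc12), meanGc12 = mn(stats$gc12),
    medianEnc = med(stats$enc), meanEnc = mn(stats$enc),
    silentAtSkew = unname(silentSkews["atSkew"]),
    silentGcSkew = unname(silentSkews["gcSkew"]),
    utr5Gc = utrStats$utr5Gc, utr3Gc = utrStats$utr3Gc)

  new("TaxonProfile",
      cellId = cellId,
      codonTable = tab,
      transcriptStats = stats,
      summaryStats = summaryStats,
      biasCategory = classifyBias(summaryStats[["medianGc4"]]),
      positionClassFreqs = unclass(estimatePositionClassFreqs(seqs, code)),
      utrStats = utrStats)
}

.utrGc <- function(utrs) {
  utrs <- utrs[!is.na(utrs)]
  if (!length(utrs)) return(NA_real_)
  chars <- strsplit(paste(utrs, collapse = ""), "")[[1L]]
  chars <- chars[chars %in% NT4]
  if (!length(chars)) return(NA_real_)
  mean(chars %in% c("G", "C"))
}

#' Analyze a full (curated) dataset
#'
#' Runs every per-cell and cross-taxon analysis: taxon profiles,
#' codon-family frequencies and RSCU, per-codon frequency-versus-log10(TPM)
#' slopes with BH correction per cell, GC4/GC12-versus-expression slopes,
#' neutrality plots (all transcripts, bottom and top expression decile; BH
#' across cells within each subset), SSDU per cell, stop-codon usage, and
#' (with five or more cells) cross-taxon amino-acid slopes for lowly and
#' highly expressed gene sets. Cells whose analysis fails are recorded in
#' \code{failedCells} and do not abort the rest.
#'
#' @param object A [TranscriptSet-class] (typically curation survivors).
#' @param code A [GeneticCode-class].
#' @param utrEligibility Optional data.frame from [curateUtrs()].
#' @param minEncCodons Per-transcript ENc length cutoff (codons).
#' @param ssduMinGroupCount Minimum SSDU group size.
#' @return List of data.frames (composition, compositionByTaxon,
#'   codonFrequencies, rscu, enc, aaUsage, stopUsage, ssdu, regressions,
#'   neutrality, crossTaxonAa) plus \code{profiles} (list of
#'   [TaxonProfile-class]) and \code{failedCells}.
#' @export
analyzeDataset <- function(object, code = standardGeneticCode(),
                           utrEligibility = NULL, minEncCodons = 100L,
                           ssduMinGroupCount = 10L) {
  cells <- splitByCell(object)
  profiles <- list(); failed <- character(0)
  compRows <- list(); ctRows <- list(); freqRows <- list()
  rscuRows <- list(); encRows <- list(); aaRows <- list()
  stopRows <- list(); ssduRows <- list(); regRows <- list()
  neutRows <- list()
  aaBottom <- list(); aaTop <- list(); gc4Mean <- list()

  for (cl in names(cells)) {
    res <- tryCatch({
      ts <- cells[[cl]]
      prof <- taxonProfile(ts, code, utrEligibility, minEncCodons)
      stats <- prof@transcriptStats
      compRows[[cl]] <- cbind(data.frame(cellId = cl), stats)
      ss <- prof@summaryStats
      ctRows[[cl]] <- data.frame(
        cellId = cl, t(ss), biasCategory = prof@biasCategory,
        nTranscripts = nrow(stats))
      ff <- familyFrequencies(prof@codonTable, code)
      rs <- rscu(prof@codonTable, code)
      freqRows[[cl]] <- data.frame(
        cellId = cl, codon = names(ff),
        aa = .aaOf(code, names(ff)),
        count = unname(prof@codonTable@counts),
        familyFrequency = unname(ff))
      rscuRows[[cl]] <- data.frame(
        cellId = cl, codon = names(rs), rscu = unname(rs))
      encCell <- encObserved(prof@codonTable, code)
      encRows[[cl]] <- data.frame(
        cellId = cl, scope = "cell", enc = encCell$enc,
        medianTranscriptEnc = ss[["medianEnc"]])
      au <- aaUsage(prof@codonTable, code)
      aaRows[[cl]] <- data.frame(
        cellId = cl, aa = names(au$freqs), frequency = unname(au$freqs),
        fyminkFrac = au$fyminkFrac, garpFrac = au$garpFrac)
      su <- stopUsage(prof@codonTable)
      stopRows[[cl]] <- data.frame(
        cellId = cl, stopCodon = names(su), frequency = unname(su))
      sd <- computeSsdu(as.character(ts@cds), code,
                        minGroupCount = ssduMinGroupCount)
      ssduRows[[cl]] <- cbind(data.frame(cellId = cl), sd)

      ## expression-linked analyses need TPM
      if (!all(is.na(stats$tpm)) && sum(stats$tpm > 0, na.rm = TRUE) >= 10) {
        regRows[[cl]] <- .cellRegressions(ts, stats, code, cl)
        bins <- decileBins(stats$tpm)
        neutRows[[cl]] <- rbind(
          cbind(data.frame(cellId = cl, subset = "all"),
                neutralityPlot(stats$gc12, stats$gc4)),
          cbind(data.frame(cellId = cl, subset = "bottom_decile"),
                neutralityPlot(stats$gc12, stats$gc4, bins$bottom1)),
          cbind(data.frame(cellId = cl, subset = "top_decile"),
                neutralityPlot(stats$gc12, stats$gc4, bins$top1)))
        aaBottom[[cl]] <- .subsetAaFreqs(ts, bins$bottom2, code)
        aaTop[[cl]] <- .subsetAaFreqs(ts, bins$top2, code)
        gc4Mean[[cl]] <- mean(stats$gc4, na.rm = TRUE)
      }
      profiles[[cl]] <- prof
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) failed <- c(failed, setNames(res, cl))
  }

  neutrality <- if (length(neutRows)) do.call(rbind, neutRows) else NULL
  if (!is.null(neutrality)) {
    for (sub in unique(neutrality$subset)) {
      k <- neutrality$subset == sub
      neutrality$qValue[k] <- bhAdjust(neutrality$pValue[k])
    }
  }

  crossTaxon <- NULL
  if (length(aaBottom) >= 5L) {
    gm <- unlist(gc4Mean)
    bot <- do.call(rbind, aaBottom); rownames(bot) <- names(aaBottom)
    top <- do.call(rbind, aaTop); rownames(top) <- names(aaTop)
    bot <- bot[names(gm), , drop = FALSE]
    top <- top[names(gm), , drop = FALSE]
    crossTaxon <- rbind(
      cbind(data.frame(subset = "bottom2"), crossTaxonAaSlopes(bot, gm)),
      cbind(data.frame(subset = "top2"), crossTaxonAaSlopes(top, gm)))
  }

  bind <- function(x) if (length(x)) {
    out <- do.call(rbind, x); rownames(out) <- NULL; out
  } else NULL
  list(profiles = profiles,
       composition = bind(compRows),
       compositionByTaxon = bind(ctRows),
       codonFrequencies = bind(freqRows),
       rscu = bind(rscuRows),
       enc = bind(encRows),
       aaUsage = bind(aaRows),
       stopUsage = bind(stopRows),
       ssdu = bind(ssduRows),
       regressions = bind(regRows),
       neutrality = { if (!is.null(neutrality)) rownames(neutrality) <- NULL
                      neutrality },
       crossTaxonAa = crossTaxon,
       failedCells = failed)
}

## internal: per-cell regressions: 59 codon family frequencies (amino acids
## with 2+ synonyms) vs log10 TPM, BH-corrected per cell, plus GC4 and GC12
## vs log10 TPM.
.cellRegressions <- function(ts, stats, code, cl) {
  M <- .codonCountMatrix(as.character(ts@cds), code)
  aaByCodon <- .aaOf(code, code@senseCodons)
  famTotals <- rowsum(M, group = aaByCodon)
  rows <- list()
  multi <- code@senseCodons[
    lengths(code@aaToCodons)[aaByCodon] >= 2L]
  for (cod in multi) {
    tot <- famTotals[aaByCodon[match(cod, code@senseCodons)], ]
    f <- ifelse(tot > 0, M[cod, ] / tot, NA_real_)
    ok <- !is.na(f) & !is.na(stats$tpm) & stats$tpm > 0
    if (sum(ok) < 3L) next
    r <- metricVsLogTpm(f, stats$tpm)
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(cellId = cl, predictor = "log10Tpm",
                 response = paste0("freq_", cod), subset = "all"), r)
  }
  out <- do.call(rbind, rows)
  out$qValue <- bhAdjust(out$pValue)
  for (metric in c("gc4", "gc12")) {
    ok <- !is.na(stats[[metric]])
    if (sum(ok & stats$tpm > 0, na.rm = TRUE) >= 3L) {
      r <- metricVsLogTpm(stats[[metric]], stats$tpm)
      out <- rbind(out, cbind(
        data.frame(cellId = cl, predictor = "log10Tpm",
                   response = metric, subset = "all"), r))
    }
  }
  out
}

## internal: amino-acid frequency vector over a transcript subset
.subsetAaFreqs <- function(ts, mask, code) {
  tab <- countCodons(as.character(ts@cds)[mask], code)
  au <- aaUsage(tab, code)
  matrix(au$freqs, nrow = 1L, dimnames = list(NULL, names(au$freqs)))
}
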