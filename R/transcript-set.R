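## The TranscriptSet container and all external I/O: FASTA coding sequences
## (with optional UTRs), coverage/count TSVs, taxon maps, gene-family
## alignments, and the result-table writers.

#' TranscriptSet: curated coding sequences with per-transcript metadata
#'
#' The record model consumed by every analysis stage: one in-frame CDS per
#' transcript (sense strand, terminal stop retained in the sequence but
#' excluded from codon statistics) plus cell, gene-family, optional UTR,
#' coverage, read-count and TPM columns.
#'
#' @slot cds A [Biostrings::DNAStringSet] of CDS, named by transcript id.
#' @slot transcriptData data.frame with columns transcriptId, cellId,
#'   geneFamilyId, utr5, utr3 (character, NA when absent), kmerCoverage,
#'   readCount, tpm, missingCoverage (logical).
#' @exportClass TranscriptSet
setClass("TranscriptSet", representation(
  cds = "DNAStringSet",
  transcriptData = "data.frame"
))

setValidity("TranscriptSet", function(object) {
  msgs <- character(0)
  td <- object@transcriptData
  need <- c("transcriptId", "cellId", "geneFamilyId", "utr5", "utr3",
            "kmerCoverage", "readCount", "tpm", "missingCoverage")
  if (!all(need %in% names(td)))
    msgs <- c(msgs, paste("transcriptData must have columns:",
                          paste(setdiff(need, names(td)), collapse = ", ")))
  else {
    if (nrow(td) != length(object@cds))
      msgs <- c(msgs, "transcriptData rows must match the number of sequences")
    if (anyDuplicated(td$transcriptId))
      msgs <- c(msgs, "duplicate transcript ids")
    if (nrow(td) && !identical(names(object@cds), td$transcriptId))
      msgs <- c(msgs, "sequence names must equal transcriptData$transcriptId")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a TranscriptSet
#'
#' @param cds Named character vector or DNAStringSet of in-frame CDS.
#' @param cellId,geneFamilyId Character vectors (recycled if length 1).
#' @param utr5,utr3 Optional character vectors (NA when absent).
#' @param kmerCoverage,readCount Optional numeric vectors.
#' @return A [TranscriptSet-class].
#' @export
TranscriptSet <- function(cds, cellId, geneFamilyId = NA_character_,
                          utr5 = NA_character_, utr3 = NA_character_,
                          kmerCoverage = NA_real_, readCount = NA_real_) {
  if (!is(cds, "DNAStringSet")) cds <- Biostrings::DNAStringSet(cds)
  n <- length(cds)
  if (is.null(names(cds))) stop("cds must be named by transcript id")
  td <- data.frame(
    transcriptId = names(cds),
    cellId = rep_len(as.character(cellId), n),
    geneFamilyId = rep_len(as.character(geneFamilyId), n),
    utr5 = rep_len(as.character(utr5), n),
    utr3 = rep_len(as.character(utr3), n),
    kmerCoverage = rep_len(as.numeric(kmerCoverage), n),
    readCount = rep_len(as.numeric(readCount), n),
    tpm = rep_len(NA_real_, n),
    missingCoverage = rep_len(is.na(as.numeric(kmerCoverage)), n),
    stringsAsFactors = FALSE)
  new("TranscriptSet", cds = cds, transcriptData = td)
}

#' @describeIn TranscriptSet Number of transcripts.
#' @param x,object A TranscriptSet.
#' @export
setMethod("length", "TranscriptSet", function(x) length(x@cds))

setMethod("show", "TranscriptSet", function(object) {
  td <- object@transcriptData
  cat("TranscriptSet: ", length(object), " transcripts, ",
      length(unique(td$cellId)), " cell(s), ",
      length(unique(td$geneFamilyId[!is.na(td$geneFamilyId)])),
      " gene families\n", sep = "")
  cat(" with UTR5: ", sum(!is.na(td$utr5)), "; with UTR3: ",
      sum(!is.na(td$utr3)), "; with coverage: ",
      sum(!td$missingCoverage), "\n", sep = "")
})

#' @describeIn TranscriptSet Subset by index, logical mask or transcript id.
#' @param i Index vector.
#' @export
setMethod("[", "TranscriptSet", function(x, i) {
  if (is.character(i)) i <- match(i, x@transcriptData$transcriptId)
  td <- x@transcriptData[i, , drop = FALSE]
  rownames(td) <- NULL
  new("TranscriptSet", cds = x@cds[i], transcriptData = td)
})

#' @describeIn TranscriptSet CDS accessor (DNAStringSet).
#' @export
cds <- function(object) object@cds

#' @describeIn TranscriptSet Metadata accessor (data.frame).
#' @export
transcriptData <- function(object) object@transcriptData

#' @describeIn TranscriptSet Cell id per transcript.
#' @export
cellIds <- function(object) object@transcriptData$cellId

#' Replace metadata columns (internal-facing, validated)
#' @param object A TranscriptSet.
#' @param value data.frame with the canonical columns.
#' @keywords internal
`transcriptData<-` <- function(object, value) {
  object@transcriptData <- value
  validObject(object)
  object
}

#' Split a TranscriptSet by cell
#'
#' @param object A [TranscriptSet-class].
#' @return Named list of TranscriptSet, one per cell.
#' @export
splitByCell <- function(object) {
  cells <- unique(object@transcriptData$cellId)
  setNames(lapply(cells, function(cl) object[object@transcriptData$cellId == cl]),
           cells)
}

#' Load a transcript dataset from FASTA and TSV inputs
#'
#' Reads coding sequences (FASTA; headers are transcript ids, first
#' whitespace-delimited token), an optional UTR source, a coverage/count TSV
#' and a taxon map, assembling a frame-validated [TranscriptSet-class].
#'
#' UTRs are accepted in either of two forms: FASTA records whose ids carry a
#' \code{_utr5} / \code{_utr3} suffix on the transcript id, or a coordinate
#' table (TSV with columns transcriptId, cdsStart, cdsEnd; 0-based half-open
#' over the full transcript sequence), in which case the FASTA records are
#' full transcripts and the CDS is cut out of them.
#'
#' Records are rejected (with a logged reason) when the CDS length is not a
#' multiple of 3, when an internal stop codon is present, or when more than
#' \code{maxNFrac} of the CDS is N. A duplicate transcript id is a hard
#' error. Records without a coverage entry are kept and flagged.
#'
#' @param cdsFasta Path to the CDS (or full-transcript) FASTA.
#' @param coverageTsv Optional TSV with columns transcriptId, kmerCoverage,
#'   readCount.
#' @param taxonMapTsv Optional TSV with columns transcriptId, cellId and
#'   optionally geneFamilyId.
#' @param utrTable Optional coordinate TSV (see above).
#' @param alignmentsDir Optional directory of per-family aligned FASTA files
#'   (\code{<geneFamilyId>.fasta}).
#' @param maxNFrac Maximum tolerated fraction of N in a CDS (default 0.1).
#' @return List with \code{records} (TranscriptSet), \code{alignments}
#'   (named list of gapped character vectors, possibly empty) and \code{log}
#'   (data.frame of rejected records and flags).
#' @export
loadDataset <- function(cdsFasta, coverageTsv = NULL, taxonMapTsv = NULL,
                        utrTable = NULL, alignmentsDir = NULL,
                        maxNFrac = 0.1) {
  fa <- Biostrings::readDNAStringSet(cdsFasta)
  names(fa) <- sub("\\s.*$", "", names(fa))
  ids <- names(fa)

  utr5 <- utr3 <- setNames(rep(NA_character_, length(fa)), ids)
  isUtr <- grepl("_utr[53]$", ids)
  if (any(isUtr)) {
    utrSeqs <- fa[isUtr]
    fa <- fa[!isUtr]
    ids <- names(fa)
    utr5 <- utr3 <- setNames(rep(NA_character_, length(fa)), ids)
    for (nm in names(utrSeqs)) {
      base <- sub("_utr[53]$", "", nm)
      if (!base %in% ids) next
      if (endsWith(nm, "_utr5")) utr5[[base]] <- as.character(utrSeqs[[nm]])
      else utr3[[base]] <- as.character(utrSeqs[[nm]])
    }
  }
  if (anyDuplicated(ids))
    stop("duplicate transcript id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))

  seqs <- as.character(fa)
  if (!is.null(utrTable)) {
    coords <- read.delim(utrTable, stringsAsFactors = FALSE)
    stopifnot(all(c("transcriptId", "cdsStart", "cdsEnd") %in% names(coords)))
    for (i in seq_len(nrow(coords))) {
      id <- coords$transcriptId[i]
      if (!id %in% ids) next
      full <- seqs[[id]]
      s <- coords$cdsStart[i]; e <- coords$cdsEnd[i]   # 0-based half-open
      if (s > 0) utr5[[id]] <- substr(full, 1L, s)
      if (e < nchar(full)) utr3[[id]] <- substr(full, e + 1L, nchar(full))
      seqs[[id]] <- substr(full, s + 1L, e)
    }
  }

  code <- standardGeneticCode()
  logRows <- list()
  keep <- rep(TRUE, length(seqs))
  for (i in seq_along(seqs)) {
    s <- toupper(seqs[[i]])
    reason <- NULL
    if (nchar(s) %% 3L != 0L) {
      reason <- "length not divisible by 3"
    } else {
      cods <- .codonSplit(s)
      body <- cods[-length(cods)]
      if (any(body %in% code@stopSet)) reason <- "internal stop"
      else if (mean(strsplit(s, "")[[1L]] == "N") > maxNFrac)
        reason <- sprintf("more than %d%% N", round(100 * maxNFrac))
    }
    if (!is.null(reason)) {
      keep[i] <- FALSE
      logRows[[length(logRows) + 1L]] <-
        data.frame(transcriptId = ids[i], event = "rejected", detail = reason)
    }
  }

  cellId <- setNames(rep(NA_character_, length(ids)), ids)
  famId <- setNames(rep(NA_character_, length(ids)), ids)
  if (!is.null(taxonMapTsv)) {
    tm <- read.delim(taxonMapTsv, stringsAsFactors = FALSE)
    m <- match(ids, tm$transcriptId)
    cellId[] <- tm$cellId[m]
    if ("geneFamilyId" %in% names(tm)) famId[] <- tm$geneFamilyId[m]
  }
  cov <- setNames(rep(NA_real_, length(ids)), ids)
  cnt <- setNames(rep(NA_real_, length(ids)), ids)
  if (!is.null(coverageTsv)) {
    cv <- read.delim(coverageTsv, stringsAsFactors = FALSE)
    m <- match(ids, cv$transcriptId)
    if ("kmerCoverage" %in% names(cv)) cov[] <- cv$kmerCoverage[m]
    if ("readCount" %in% names(cv)) cnt[] <- cv$readCount[m]
    for (id in ids[is.na(cov)])
      logRows[[length(logRows) + 1L]] <-
        data.frame(transcriptId = id, event = "flag", detail = "missing coverage")
  }

  ts <- TranscriptSet(Biostrings::DNAStringSet(seqs[keep]),
                      cellId = cellId[keep], geneFamilyId = famId[keep],
                      utr5 = utr5[keep], utr3 = utr3[keep],
                      kmerCoverage = cov[keep], readCount = cnt[keep])
  alignments <- if (!is.null(alignmentsDir))
    readGeneFamilyAlignments(alignmentsDir) else list()
  logDf <- if (length(logRows)) do.call(rbind, logRows)
    else data.frame(transcriptId = character(0), event = character(0),
                    detail = character(0))
  list(records = ts, alignments = alignments, log = logDf)
}

#' Read per-family alignments from a directory of aligned FASTA files
#'
#' Each \code{<family>.fasta} (or .fa) file holds one gene-family alignment;
#' rows are gapped sequences named by transcript id and must share one width.
#'
#' @param dir Directory path.
#' @return Named list (by family id) of named character vectors of gapped
#'   rows.
#' @export
readGeneFamilyAlignments <- function(dir) {
  files <- list.files(dir, pattern = "\\.(fa|fasta)$", full.names = TRUE)
  out <- list()
  for (f in files) {
    fam <- sub("\\.(fa|fasta)$", "", basename(f))
    aln <- Biostrings::readBStringSet(f)
    names(aln) <- sub("\\s.*$", "", names(aln))
    rows <- toupper(as.character(aln))
    if (length(unique(nchar(rows))) > 1L)
      stop("alignment rows of unequal length in ", f)
    out[[fam]] <- rows
  }
  out
}

#' Write a TranscriptSet back to FASTA + TSV
#'
#' Writes \code{cds.fasta} (with \code{_utr5}/\code{_utr3} records for
#' present UTRs), \code{coverage.tsv} and \code{taxon_map.tsv} in a form that
#' [loadDataset()] reads back to an equal TranscriptSet.
#'
#' @param object A [TranscriptSet-class].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
writeDataset <- function(object, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  td <- object@transcriptData
  seqs <- as.character(object@cds)
  extra <- character(0)
  for (i in seq_len(nrow(td))) {
    if (!is.na(td$utr5[i]))
      extra[paste0(td$transcriptId[i], "_utr5")] <- td$utr5[i]
    if (!is.na(td$utr3[i]))
      extra[paste0(td$transcriptId[i], "_utr3")] <- td$utr3[i]
  }
  allSeqs <- c(setNames(seqs, td$transcriptId), extra)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(allSeqs),
                              file.path(dir, "cds.fasta"), width = 70L)
  write.table(data.frame(transcriptId = td$transcriptId,
                         kmerCoverage = td$kmerCoverage,
                         readCount = td$readCount),
              file.path(dir, "coverage.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(transcriptId = td$transcriptId,
                         cellId = td$cellId,
                         geneFamilyId = td$geneFamilyId),
              file.path(dir, "taxon_map.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

## internal: format numeric columns at fixed precision for deterministic
## table output
.formatTable <- function(df, digits = 6L) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
      df[[j]] <- formatC(df[[j]], digits = digits, format = "g")
  }
  df
}

#' Write analysis result tables to TSV
#'
#' Writes one deterministic TSV per analysis (composition,
#' composition_by_taxon, codon_frequencies, rscu, enc, aa_usage, stop_usage,
#' ssdu, regressions, neutrality, curation_log). Empty results produce
#' headers-only files; floats are written at fixed precision; rows are sorted
#' on their key columns, so re-running on the same input is byte-identical.
#'
#' @param results A named list of data.frames as produced by
#'   [analyzeDataset()] (missing elements are skipped, except that known
#'   tables always get at least a headers-only file).
#' @param outDir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
writeResultTables <- function(results, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  for (nm in names(results)) {
    df <- results[[nm]]
    if (!is.data.frame(df)) next
    keys <- intersect(c("cellId", "transcriptId", "framePos", "dinucleotide",
                        "codon", "aa", "subset", "predictor", "response",
                        "ruleId"), names(df))
    if (length(keys) && nrow(df))
      df <- df[do.call(order, df[keys]), , drop = FALSE]
    path <- file.path(outDir, paste0(nm, ".tsv"))
    write.table(.formatTable(df), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    written <- c(written, path)
  }
  invisible(written)
}
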