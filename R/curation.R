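## Sequence-level curation battery for single-cell transcriptome artifacts:
## cross-cell contamination (index hopping), within-cell duplicates from
## misassembly, short/partial transcripts, paralog clades, gap-heavy
## alignment rows, composition outliers, and UTR eligibility.
##
## Rule order is fixed: cross-contamination -> within-cell dedup ->
## structural filters -> composition outliers -> UTR eligibility; each stage
## sees the survivors of the previous one.

#' Curation thresholds
#'
#' All thresholds of the curation battery in one place. Defaults follow the
#' published filter battery: cross-contaminants are pairs at >= 99% identity
#' between cells where the flagged member has k-mer coverage < 10 with a
#' same-cell partner above 20, or coverage < 20 with a partner above 100;
#' within-cell duplicates are pairs over 95% identity or sharing a 50 bp
#' exact run; transcripts under 25% (or same-cell paralogs under 50%) of the
#' family mean length are dropped, as are alignment rows with at least 30%
#' gaps; composition outliers (|robust z| > 3 on GC3S or ENc) are removed
#' when coverage is below 10 or a non-outlying same-cell paralog with higher
#' coverage exists; UTRs must be longer than 50 bp and shorter than 500 bp.
#'
#' @param xcontamIdentity,dupIdentity Identity gates (fractions).
#' @param exactRun Exact-run length for the duplicate rule (bp).
#' @param shortFrac,paralogFrac,gapFrac Structural-filter fractions.
#' @param covLo,covHi,partnerLo,partnerHi Coverage thresholds of the two
#'   cross-contamination rules.
#' @param outlierZ,outlierCov Composition-outlier robust-z cutoff and
#'   coverage threshold.
#' @param minCellTranscripts Minimum transcripts per cell for the outlier
#'   rule (skipped below this).
#' @param utrMinLen,utrMaxLen UTR length gates (exclusive).
#' @param minEncCodons Minimum codons for per-transcript ENc in the outlier
#'   rule.
#' @return A named list of thresholds.
#' @export
curationParams <- function(xcontamIdentity = 0.99, dupIdentity = 0.95,
                           exactRun = 50L, shortFrac = 0.25,
                           paralogFrac = 0.50, gapFrac = 0.30,
                           covLo = 10, covHi = 20,
                           partnerLo = 20, partnerHi = 100,
                           outlierZ = 3, outlierCov = 10,
                           minCellTranscripts = 20L,
                           utrMinLen = 50L, utrMaxLen = 500L,
                           minEncCodons = 100L) {
  as.list(environment())
}

.emptyDecisions <- function() {
  data.frame(transcriptId = character(0), ruleId = character(0),
             evidence = character(0), stringsAsFactors = FALSE)
}

.decision <- function(id, rule, evidence) {
  data.frame(transcriptId = id, ruleId = rule, evidence = evidence,
             stringsAsFactors = FALSE)
}

## internal: pairwise identity. When both rows are present in the family
## alignment, identity is matches over shared non-gap columns; otherwise a
## global pairwise alignment is computed (after a cheap shared-kmer
## prescreen for long sequences).
.alignedIdentity <- function(rowA, rowB) {
  a <- strsplit(rowA, "")[[1L]]
  b <- strsplit(rowB, "")[[1L]]
  ok <- a != "-" & b != "-"
  if (!sum(ok)) return(0)
  sum(a[ok] == b[ok]) / sum(ok)
}

.freeIdentity <- function(seqA, seqB) {
  aln <- Biostrings::pairwiseAlignment(seqA, seqB, type = "global")
  Biostrings::pid(aln, type = "PID1") / 100
}

.sharedKmer <- function(seqA, seqB, k) {
  if (nchar(seqA) < k || nchar(seqB) < k) return(FALSE)
  ka <- unique(substring(seqA, 1:(nchar(seqA) - k + 1L),
                         k:nchar(seqA)))
  kb <- unique(substring(seqB, 1:(nchar(seqB) - k + 1L),
                         k:nchar(seqB)))
  any(ka %in% kb)
}

.pairIdentity <- function(idA, idB, seqs, aln) {
  if (!is.null(aln) && idA %in% names(aln) && idB %in% names(aln))
    return(.alignedIdentity(aln[[idA]], aln[[idB]]))
  ## prescreen: near-identical sequences necessarily share a long exact run
  if (!.sharedKmer(seqs[[idA]], seqs[[idB]], 16L)) return(0)
  .freeIdentity(seqs[[idA]], seqs[[idB]])
}

## internal: split transcript ids by gene family (NA family -> own singleton)
.familyGroups <- function(td) {
  fam <- td$geneFamilyId
  fam[is.na(fam)] <- paste0(".orphan.", td$transcriptId[is.na(fam)])
  split(td$transcriptId, fam)
}

#' Flag cross-cell contaminants (index hopping)
#'
#' Candidates are cross-cell pairs within a gene family at or above the
#' identity gate (default 99%). A member is flagged when its k-mer coverage
#' is below \code{covLo} and some same-cell partner in the family has
#' coverage above \code{partnerLo} (rule \code{xcontam_10_20}), or when its
#' coverage is below \code{covHi} with a partner above \code{partnerHi}
#' (rule \code{xcontam_20_100}). Candidates with missing coverage are
#' skipped and logged.
#'
#' @param object A [TranscriptSet-class].
#' @param alignments Named list of gene-family alignments (gapped character
#'   vectors), or NULL to align candidate pairs directly.
#' @param params See [curationParams()].
#' @return data.frame of removal decisions (transcriptId, ruleId, evidence).
#' @export
flagCrossContaminants <- function(object, alignments = NULL,
                                  params = curationParams()) {
  td <- object@transcriptData
  seqs <- setNames(as.character(object@cds), td$transcriptId)
  cov <- setNames(td$kmerCoverage, td$transcriptId)
  cell <- setNames(td$cellId, td$transcriptId)
  decisions <- list()
  for (fam in names(.familyGroups(td))) {
    ids <- .familyGroups(td)[[fam]]
    if (length(ids) < 2L) next
    aln <- alignments[[fam]]
    ## best same-cell partner coverage per member
    partnerCov <- vapply(ids, function(id) {
      others <- ids[ids != id & cell[ids] == cell[[id]]]
      if (!length(others)) return(NA_real_)
      suppressWarnings(max(cov[others], na.rm = TRUE))
    }, numeric(1))
    partnerCov[!is.finite(partnerCov)] <- NA_real_
    ## a member can only be flagged if its own coverage and a qualifying
    ## partner exist; restrict identity computations to those
    canFlag <- !is.na(cov[ids]) & !is.na(partnerCov) &
      ((cov[ids] < params$covLo & partnerCov > params$partnerLo) |
       (cov[ids] < params$covHi & partnerCov > params$partnerHi))
    if (!any(canFlag)) next
    for (id in ids[canFlag]) {
      mates <- ids[cell[ids] != cell[[id]]]
      for (mate in mates) {
        if (is.na(cov[[mate]])) next
        idy <- .pairIdentity(id, mate, seqs, aln)
        if (idy < params$xcontamIdentity) next
        rule <- if (cov[[id]] < params$covLo &&
                    partnerCov[[id]] > params$partnerLo)
          "xcontam_10_20" else "xcontam_20_100"
        decisions[[length(decisions) + 1L]] <- .decision(
          id, rule,
          sprintf("partner=%s identity=%.4f cov=%.3g sameCellCov=%.3g",
                  mate, idy, cov[[id]], partnerCov[[id]]))
        break
      }
    }
  }
  if (!length(decisions)) return(.emptyDecisions())
  unique(do.call(rbind, decisions))
}

#' Remove within-cell duplicates
#'
#' For any same-cell pair within a gene family that is more than 95%
#' identical, or that shares an exact run of at least 50 bp, the lower
#' k-mer coverage member is removed (ties: the shorter sequence, then the
#' lexicographically later id).
#'
#' @inheritParams flagCrossContaminants
#' @return data.frame of removal decisions.
#' @export
dedupWithinCell <- function(object, alignments = NULL,
                            params = curationParams()) {
  td <- object@transcriptData
  seqs <- setNames(as.character(object@cds), td$transcriptId)
  cov <- setNames(td$kmerCoverage, td$transcriptId)
  cell <- setNames(td$cellId, td$transcriptId)
  decisions <- list()
  fams <- .familyGroups(td)
  for (fam in names(fams)) {
    ids <- fams[[fam]]
    aln <- alignments[[fam]]
    byCell <- split(ids, cell[ids])
    for (ids2 in byCell) {
      if (length(ids2) < 2L) next
      for (i in seq_len(length(ids2) - 1L)) for (j in (i + 1L):length(ids2)) {
        a <- ids2[i]; b <- ids2[j]
        run <- .sharedKmer(seqs[[a]], seqs[[b]], params$exactRun)
        idy <- if (run) NA_real_ else .pairIdentity(a, b, seqs, aln)
        if (!run && (is.na(idy) || idy <= params$dupIdentity)) next
        loser <- .lowerCoverageMember(a, b, cov, seqs)
        ev <- if (run) sprintf("partner=%s sharedRun>=%dbp",
                               setdiff(c(a, b), loser), params$exactRun)
          else sprintf("partner=%s identity=%.4f",
                       setdiff(c(a, b), loser), idy)
        decisions[[length(decisions) + 1L]] <-
          .decision(loser, "samecell_dup", ev)
      }
    }
  }
  if (!length(decisions)) return(.emptyDecisions())
  unique(do.call(rbind, decisions))
}

.lowerCoverageMember <- function(a, b, cov, seqs) {
  ca <- cov[[a]]; cb <- cov[[b]]
  if (is.na(ca)) ca <- -Inf
  if (is.na(cb)) cb <- -Inf
  if (ca != cb) return(if (ca < cb) a else b)
  la <- nchar(seqs[[a]]); lb <- nchar(seqs[[b]])
  if (la != lb) return(if (la < lb) a else b)
  max(a, b)  # lexicographically later id loses
}

#' Structural filters: short transcripts, short paralogs, paralog clades,
#' gap-heavy rows
#'
#' Within each gene family (mean ungapped length computed over the family's
#' current members): (a) transcripts shorter than \code{shortFrac} times the
#' mean are removed (\code{short_25pct}); (b) same-cell paralogs (cells with
#' two or more members) shorter than \code{paralogFrac} times the mean are
#' removed (\code{paralog_50pct}); (c) within connected components of
#' same-cell pairs at >= \code{dupIdentity} identity (a tree-free surrogate
#' for ingroup-paralog clades) all but the highest-coverage member are
#' removed (\code{best_paralog}); (d) alignment rows with a gap fraction of
#' at least \code{gapFrac} are removed (\code{gap_30pct}).
#'
#' @inheritParams flagCrossContaminants
#' @return data.frame of removal decisions.
#' @export
structuralFilters <- function(object, alignments = NULL,
                              params = curationParams()) {
  td <- object@transcriptData
  seqs <- setNames(as.character(object@cds), td$transcriptId)
  cov <- setNames(td$kmerCoverage, td$transcriptId)
  cell <- setNames(td$cellId, td$transcriptId)
  decisions <- list()
  fams <- .familyGroups(td)
  for (fam in names(fams)) {
    ids <- fams[[fam]]
    aln <- alignments[[fam]]
    lens <- nchar(seqs[ids])
    meanLen <- mean(lens)
    if (length(ids) >= 2L) {
      short <- ids[lens < params$shortFrac * meanLen]
      for (id in short)
        decisions[[length(decisions) + 1L]] <- .decision(
          id, "short_25pct",
          sprintf("len=%d familyMean=%.1f", nchar(seqs[[id]]), meanLen))
      byCell <- split(ids, cell[ids])
      for (ids2 in byCell) {
        if (length(ids2) < 2L) next
        shortPar <- ids2[nchar(seqs[ids2]) < params$paralogFrac * meanLen]
        shortPar <- setdiff(shortPar, short)
        for (id in shortPar)
          decisions[[length(decisions) + 1L]] <- .decision(
            id, "paralog_50pct",
            sprintf("len=%d familyMean=%.1f", nchar(seqs[[id]]), meanLen))
        ## paralog clades: connected components of >= dupIdentity same-cell
        ## pairs; keep the highest coverage member
        comp <- .identityComponents(ids2, seqs, aln, params$dupIdentity)
        for (grp in comp) {
          if (length(grp) < 2L) next
          keepId <- .bestCoverageMember(grp, cov, seqs)
          for (id in setdiff(grp, keepId))
            decisions[[length(decisions) + 1L]] <- .decision(
              id, "best_paralog",
              sprintf("kept=%s cov=%.3g keptCov=%.3g", keepId,
                      cov[[id]], cov[[keepId]]))
        }
      }
    }
    if (!is.null(aln)) {
      for (id in intersect(ids, names(aln))) {
        gf <- mean(strsplit(aln[[id]], "")[[1L]] == "-")
        if (gf >= params$gapFrac)
          decisions[[length(decisions) + 1L]] <- .decision(
            id, "gap_30pct", sprintf("gapFrac=%.3f", gf))
      }
    }
  }
  if (!length(decisions)) return(.emptyDecisions())
  unique(do.call(rbind, decisions))
}

.identityComponents <- function(ids, seqs, aln, gate) {
  n <- length(ids)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    idy <- .pairIdentity(ids[i], ids[j], seqs, aln)
    if (idy >= gate) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  unname(split(ids, roots))
}

.bestCoverageMember <- function(ids, cov, seqs) {
  cv <- cov[ids]
  cv[is.na(cv)] <- -Inf
  best <- ids[cv == max(cv)]
  if (length(best) > 1L) {
    lens <- nchar(seqs[best])
    best <- best[lens == max(lens)]
  }
  min(best)  # lexicographically first id wins remaining ties
}

#' Composition-outlier filter on the joint GC3S-ENc distribution
#'
#' Per cell (with at least \code{minCellTranscripts} transcripts, otherwise
#' skipped), transcripts are outliers when their robust z-score (median/MAD)
#' exceeds \code{outlierZ} on GC3S or on ENc. An outlier is removed when its
#' k-mer coverage is below \code{outlierCov}, or when a non-outlying
#' same-cell paralog (same gene family) with higher coverage exists.
#'
#' @param object A [TranscriptSet-class].
#' @param code A [GeneticCode-class].
#' @param params See [curationParams()].
#' @return data.frame of removal decisions.
#' @export
compositionOutlierFilter <- function(object, code,
                                     params = curationParams()) {
  td <- object@transcriptData
  seqs <- as.character(object@cds)
  g3 <- gc3s(seqs, code)
  en <- encPerTranscript(seqs, code, minCodons = params$minEncCodons)
  decisions <- list()
  for (cl in unique(td$cellId)) {
    idx <- which(td$cellId == cl)
    if (length(idx) < params$minCellTranscripts) {
      message("composition outlier rule skipped for cell ", cl,
              " (fewer than ", params$minCellTranscripts, " transcripts)")
      next
    }
    zg <- .robustZ(g3[idx])
    ze <- .robustZ(en[idx])
    out <- (!is.na(zg) & abs(zg) > params$outlierZ) |
           (!is.na(ze) & abs(ze) > params$outlierZ)
    if (!any(out)) next
    for (k in idx[out]) {
      id <- td$transcriptId[k]
      cv <- td$kmerCoverage[k]
      remove <- FALSE; why <- NULL
      if (!is.na(cv) && cv < params$outlierCov) {
        remove <- TRUE
        why <- sprintf("cov=%.3g<%g", cv, params$outlierCov)
      } else {
        fam <- td$geneFamilyId[k]
        mates <- setdiff(idx[!out], k)          # non-outlying, same cell
        mates <- mates[td$geneFamilyId[mates] %in% fam]
        better <- mates[!is.na(td$kmerCoverage[mates]) & !is.na(cv) &
                        td$kmerCoverage[mates] > cv]
        if (length(better)) {
          remove <- TRUE
          why <- sprintf("nonOutlyingParalog=%s",
                         td$transcriptId[better[1L]])
        }
      }
      if (remove)
        decisions[[length(decisions) + 1L]] <- .decision(
          id, "composition_outlier",
          sprintf("zGc3s=%.2f zEnc=%.2f %s", zg[match(k, idx)],
                  ze[match(k, idx)], why))
    }
  }
  if (!length(decisions)) return(.emptyDecisions())
  unique(do.call(rbind, decisions))
}

.robustZ <- function(x) {
  med <- median(x, na.rm = TRUE)
  md <- mad(x, na.rm = TRUE)
  if (is.na(md) || md == 0) return(rep(NA_real_, length(x)))
  (x - med) / md
}

#' UTR eligibility flags
#'
#' A 5' UTR is eligible when it is longer than \code{utrMinLen} and shorter
#' than \code{utrMaxLen} bp and the CDS start methionine aligns with a
#' methionine of at least one other row of the family alignment; a 3' UTR
#' additionally requires another row with a stop codon in the same alignment
#' columns. Absent UTRs are flagged "absent", not ineligible. When no family
#' alignment is available, only the length gates apply.
#'
#' @inheritParams flagCrossContaminants
#' @return data.frame with columns transcriptId, utr5Status, utr3Status
#'   (each "eligible", "ineligible" or "absent") and rule columns naming the
#'   failed gate.
#' @export
curateUtrs <- function(object, alignments = NULL, params = curationParams()) {
  td <- object@transcriptData
  out <- data.frame(transcriptId = td$transcriptId,
                    utr5Status = "absent", utr5Rule = NA_character_,
                    utr3Status = "absent", utr3Rule = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(td))) {
    fam <- td$geneFamilyId[i]
    aln <- alignments[[fam]]
    id <- td$transcriptId[i]
    for (side in c(5L, 3L)) {
      u <- if (side == 5L) td$utr5[i] else td$utr3[i]
      if (is.na(u)) next
      status <- "eligible"; rule <- NA_character_
      L <- nchar(u)
      if (L <= params$utrMinLen || L >= params$utrMaxLen) {
        status <- "ineligible"
        rule <- sprintf("utr_ineligible_%dp_length", side)
      } else if (!is.null(aln) && id %in% names(aln)) {
        okAnchor <- if (side == 5L)
          .sharedStartMet(id, aln) else .sharedStopColumn(id, aln)
        if (!okAnchor) {
          status <- "ineligible"
          rule <- sprintf("utr_ineligible_%dp_anchor", side)
        }
      }
      if (side == 5L) { out$utr5Status[i] <- status; out$utr5Rule[i] <- rule }
      else { out$utr3Status[i] <- status; out$utr3Rule[i] <- rule }
    }
  }
  out
}

## internal: first three non-gap columns of the row; TRUE if another row
## shows ATG at those columns
.sharedStartMet <- function(id, aln) {
  chars <- strsplit(aln[[id]], "")[[1L]]
  colsIdx <- which(chars != "-")[1:3]
  if (any(is.na(colsIdx))) return(FALSE)
  for (other in setdiff(names(aln), id)) {
    oc <- strsplit(aln[[other]], "")[[1L]][colsIdx]
    if (identical(paste(oc, collapse = ""), "ATG")) return(TRUE)
  }
  FALSE
}

## internal: last three non-gap columns; TRUE if another row has a stop
## codon at those columns
.sharedStopColumn <- function(id, aln) {
  chars <- strsplit(aln[[id]], "")[[1L]]
  ng <- which(chars != "-")
  if (length(ng) < 3L) return(FALSE)
  colsIdx <- tail(ng, 3L)
  for (other in setdiff(names(aln), id)) {
    oc <- paste(strsplit(aln[[other]], "")[[1L]][colsIdx], collapse = "")
    if (oc %in% c("TAA", "TAG", "TGA")) return(TRUE)
  }
  FALSE
}

#' Run the full curation battery
#'
#' Applies the rules in their fixed order (cross-contamination, within-cell
#' dedup, structural filters, composition outliers, UTR eligibility), each
#' stage operating on the survivors of the previous stage. The battery is
#' idempotent: running it again on the survivors removes nothing.
#'
#' @param object A [TranscriptSet-class].
#' @param alignments Named list of gene-family alignments (may be empty).
#' @param code A [GeneticCode-class].
#' @param params See [curationParams()].
#' @return List with \code{records} (surviving TranscriptSet),
#'   \code{decisions} (the curation log: transcriptId, ruleId, evidence) and
#'   \code{utrEligibility} (per-survivor UTR flags).
#' @export
curateTranscripts <- function(object, alignments = list(),
                              code = standardGeneticCode(),
                              params = curationParams()) {
  stages <- list(
    function(ts) flagCrossContaminants(ts, alignments, params),
    function(ts) dedupWithinCell(ts, alignments, params),
    function(ts) structuralFilters(ts, alignments, params),
    function(ts) compositionOutlierFilter(ts, code, params))
  decisions <- .emptyDecisions()
  ts <- object
  for (stage in stages) {
    d <- stage(ts)
    if (nrow(d)) {
      decisions <- rbind(decisions, d)
      ts <- ts[!ts@transcriptData$transcriptId %in% d$transcriptId]
    }
  }
  utr <- curateUtrs(ts, alignments, params)
  list(records = ts, decisions = decisions, utrEligibility = utr)
}
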