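## Site-specific synonymous dinucleotide usage (SSDU).
##
## SSDU compares the observed usage of each dinucleotide at each codon frame
## position (pos1 = codon positions 1-2, pos2 = positions 2-3, bridge =
## position 3 plus the next codon's position 1) against a null expectation
## that conditions on the amino-acid sequence and on single-nucleotide
## frequencies stratified by codon position and degeneracy class. A value of
## 1 means no bias beyond what position-stratified mononucleotide content and
## the protein sequence impose.

DINUCS <- sort(as.vector(outer(c("A","C","G","T"), c("A","C","G","T"), paste0)))

## internal: stratum key "p.k" for codon x position
.stratumKeys <- function(code) {
  keys <- matrix(NA_character_, nrow = 61L, ncol = 3L,
                 dimnames = list(code@senseCodons, NULL))
  for (p in 1:3)
    keys[, p] <- paste0(p, ".", code@posDegeneracy[, p])
  keys
}

#' Estimate nucleotide frequencies stratified by position and degeneracy class
#'
#' Assigns every codon site of the input CDS to a stratum (codon position,
#' degeneracy class of that position) and tabulates the empirical nucleotide
#' frequencies per stratum. In the standard code the occupied strata are
#' (1,1), (1,2), (2,1), (3,1), (3,2), (3,3) and (3,4). Strata with no sites
#' are marked absent and fall back to the pooled frequency of their codon
#' position (recorded in the \code{fallback} field).
#'
#' @param cds Character vector of in-frame CDS or a DNAStringSet (typically
#'   all curated transcripts of one cell, pooled).
#' @param code A [GeneticCode-class].
#' @return An object of class \code{PositionClassFreqs}: a list with
#'   \code{freqs} (matrix, strata x 4 nucleotides), \code{siteCounts},
#'   \code{absent} (logical), \code{fallback} (character vector of strata
#'   that used the pooled-position fallback).
#' @export
estimatePositionClassFreqs <- function(cds, code) {
  M <- .codonCountMatrix(cds, code)
  counts <- rowSums(M)
  .positionClassFreqsFromCounts(counts, code)
}

## internal: from a named 61 count vector
.positionClassFreqsFromCounts <- function(counts, code) {
  keys <- .stratumKeys(code)
  strata <- sort(unique(as.vector(keys)))
  freqMat <- matrix(0, nrow = length(strata), ncol = 4L,
                    dimnames = list(strata, NT4))
  siteCounts <- setNames(numeric(length(strata)), strata)
  poolPos <- matrix(0, nrow = 3L, ncol = 4L, dimnames = list(1:3, NT4))
  for (p in 1:3) {
    nt <- substr(code@senseCodons, p, p)
    tb <- rowsum(as.numeric(counts), group = paste0(keys[, p], ":", nt))
    parts <- strsplit(rownames(tb), ":", fixed = TRUE)
    for (i in seq_along(parts)) {
      freqMat[parts[[i]][1L], parts[[i]][2L]] <-
        freqMat[parts[[i]][1L], parts[[i]][2L]] + tb[i, 1L]
    }
    tbp <- rowsum(as.numeric(counts), group = nt)
    poolPos[p, rownames(tbp)] <- tbp[, 1L]
  }
  siteCounts[] <- rowSums(freqMat)
  absent <- siteCounts == 0
  fallback <- character(0)
  for (s in strata) {
    if (absent[[s]]) {
      p <- as.integer(substr(s, 1L, 1L))
      tot <- sum(poolPos[p, ])
      freqMat[s, ] <- if (tot > 0) poolPos[p, ] / tot else rep(0.25, 4L)
      fallback <- c(fallback, s)
    } else {
      freqMat[s, ] <- freqMat[s, ] / siteCounts[[s]]
    }
  }
  structure(list(freqs = freqMat, siteCounts = siteCounts,
                 absent = absent, fallback = fallback),
            class = "PositionClassFreqs")
}

#' @export
print.PositionClassFreqs <- function(x, ...) {
  cat("PositionClassFreqs: nucleotide frequencies by (position, degeneracy class)\n")
  print(round(x$freqs, 4))
  if (length(x$fallback))
    cat("strata with pooled-position fallback:",
        paste(x$fallback, collapse = ", "), "\n")
  invisible(x)
}

#' Uniform stratified frequencies
#'
#' Convenience constructor: every stratum uniform over A, C, G, T. Under this
#' null, codon probabilities reduce to equal usage within each synonymous
#' family, and SSDU reduces to the original equal-usage synonymous
#' dinucleotide usage statistic.
#'
#' @param code A [GeneticCode-class].
#' @return A \code{PositionClassFreqs} object.
#' @export
uniformPositionClassFreqs <- function(code) {
  keys <- .stratumKeys(code)
  strata <- sort(unique(as.vector(keys)))
  freqMat <- matrix(0.25, nrow = length(strata), ncol = 4L,
                    dimnames = list(strata, NT4))
  structure(list(freqs = freqMat,
                 siteCounts = setNames(rep(NA_real_, length(strata)), strata),
                 absent = setNames(rep(FALSE, length(strata)), strata),
                 fallback = character(0)),
            class = "PositionClassFreqs")
}

## internal: named numeric(61): P(codon | its amino acid) under the
## stratified single-nucleotide null. The weight of a codon is the product
## over positions of the frequency of its nucleotide in the stratum
## (position, degeneracy class of the codon at that position); weights are
## normalized within each synonymous family. A family whose weights sum to
## zero falls back to equal usage (recorded in attribute "uniformFallback").
.nullProbsByAa <- function(freqs, code) {
  keys <- .stratumKeys(code)
  w <- rep(1, 61L)
  for (p in 1:3) {
    nt <- substr(code@senseCodons, p, p)
    w <- w * freqs$freqs[cbind(keys[, p], nt)]
  }
  names(w) <- code@senseCodons
  out <- setNames(rep(NA_real_, 61L), code@senseCodons)
  fell <- character(0)
  for (aa in names(code@aaToCodons)) {
    syn <- code@aaToCodons[[aa]]
    tot <- sum(w[syn])
    if (tot > 0) {
      out[syn] <- w[syn] / tot
    } else {
      out[syn] <- 1 / length(syn)
      fell <- c(fell, aa)
    }
  }
  attr(out, "uniformFallback") <- fell
  out
}

#' Null probability of a codon given its amino acid
#'
#' Probability of observing a codon among its synonyms under the
#' degeneracy-stratified single-nucleotide null: the product over codon
#' positions of the stratum frequency of the codon's nucleotide, normalized
#' over the amino acid's synonymous set (so the probabilities over synonyms
#' sum to 1). If every synonym has zero weight the family falls back to
#' equal usage.
#'
#' @param codon A sense codon.
#' @param aa Its one-letter amino acid (checked for consistency).
#' @param freqs A \code{PositionClassFreqs} object.
#' @param code A [GeneticCode-class].
#' @return A probability.
#' @export
nullCodonProbability <- function(codon, aa, freqs, code) {
  codon <- toupper(codon)
  if (!codon %in% code@senseCodons) stop("not a sense codon: ", codon)
  if (.aaOf(code, codon) != aa)
    stop(codon, " does not encode ", aa)
  p <- .nullProbsByAa(freqs, code)
  unname(p[codon])
}

#' Site-specific synonymous dinucleotide usage (SSDU)
#'
#' For each dinucleotide h and frame position p (pos1 = codon positions 1-2,
#' pos2 = positions 2-3, bridge = codon position 3 with the next codon's
#' position 1), SSDU is the synonymous-group-weighted mean of observed over
#' expected proportions: SSDU(h, p) = sum_g n_g (o_g / e_g) / sum_g n_g,
#' where groups g are amino acids (pos1, pos2) or ordered amino-acid pairs
#' (bridge), o_g is the observed proportion of group occurrences whose
#' realized synonymous configuration carries h at p, and e_g its probability
#' under the stratified single-nucleotide null (adjacent codons independent
#' for the bridge). Groups with e_g of 0 or 1 carry no synonymous information
#' and are excluded, as are groups observed fewer than \code{minGroupCount}
#' times. SSDU is 1 in expectation under the null.
#'
#' @param cds Character vector of in-frame CDS or a DNAStringSet (one cell).
#' @param code A [GeneticCode-class].
#' @param freqs Optional \code{PositionClassFreqs}; estimated from \code{cds}
#'   when NULL.
#' @param minGroupCount Minimum group occurrences (default 10); tiny groups
#'   make o/e ratios explode.
#' @return A data.frame (one row per dinucleotide x frame position) with
#'   columns dinucleotide, framePos, observed, expected (group-size-weighted
#'   means), ssdu, log2Ssdu, nGroups, nSites. Rows with no informative group
#'   have NA ssdu.
#' @export
computeSsdu <- function(cds, code, freqs = NULL, minGroupCount = 10L) {
  seqs <- .asSeqChar(cds)
  codList <- lapply(seqs, function(s) .senseCodons(s, code)$codons)
  counts <- table(factor(unlist(codList), levels = code@senseCodons))
  counts <- setNames(as.numeric(counts), code@senseCodons)
  if (is.null(freqs))
    freqs <- .positionClassFreqsFromCounts(counts, code)
  nullP <- .nullProbsByAa(freqs, code)

  aaByCodon <- .aaOf(code, code@senseCodons)
  din1 <- substr(code@senseCodons, 1L, 2L)
  din2 <- substr(code@senseCodons, 2L, 3L)

  ## adjacent codon pairs within transcripts (terminal stop and N-containing
  ## codons already removed; bridges never span transcripts)
  pairStrings <- unlist(lapply(codList, function(cc) {
    if (length(cc) < 2L) return(character(0))
    paste(cc[-length(cc)], cc[-1L], sep = ".")
  }), use.names = FALSE)
  pairCounts <- table(pairStrings)

  rows <- list()

  ## pos1 / pos2: groups are amino acids
  for (fp in c("pos1", "pos2")) {
    din <- if (fp == "pos1") din1 else din2
    ## e_g(h): null probability that the amino acid's realized codon shows h
    ind <- matrix(0, nrow = 61L, ncol = 16L, dimnames = list(code@senseCodons, DINUCS))
    ind[cbind(seq_len(61L), match(din, DINUCS))] <- 1
    E <- rowsum(nullP * ind, group = aaByCodon)
    O <- rowsum(counts * ind, group = aaByCodon)
    nG <- rowsum(counts, group = aaByCodon)[, 1L]
    for (h in DINUCS) {
      e <- E[, h]; o <- O[, h] / ifelse(nG > 0, nG, NA_real_)
      inf <- !is.na(e) & e > 0 & e < 1 & nG >= minGroupCount
      rows[[length(rows) + 1L]] <- .ssduRow(h, fp, o, e, nG, inf)
    }
  }

  ## bridge: groups are ordered amino-acid pairs; null assumes independence
  pEnd <- rowsum(nullP * .ntIndicator(substr(code@senseCodons, 3L, 3L)),
                 group = aaByCodon)
  pStart <- rowsum(nullP * .ntIndicator(substr(code@senseCodons, 1L, 1L)),
                   group = aaByCodon)
  if (length(pairCounts)) {
    pairNames <- names(pairCounts)
    c1 <- substr(pairNames, 1L, 3L)
    c2 <- substr(pairNames, 5L, 7L)
    g <- paste0(aaByCodon[match(c1, code@senseCodons)], ".",
                aaByCodon[match(c2, code@senseCodons)])
    h <- paste0(substr(c1, 3L, 3L), substr(c2, 1L, 1L))
    nPair <- as.numeric(pairCounts)
    nG <- rowsum(nPair, group = g)[, 1L]
    oMat <- matrix(0, nrow = length(nG), ncol = 16L,
                   dimnames = list(names(nG), DINUCS))
    agg <- rowsum(nPair, group = paste0(g, "|", h))
    parts <- strsplit(rownames(agg), "|", fixed = TRUE)
    for (i in seq_along(parts))
      oMat[parts[[i]][1L], parts[[i]][2L]] <- agg[i, 1L]
    gAa <- strsplit(names(nG), ".", fixed = TRUE)
    a1 <- vapply(gAa, `[`, character(1), 1L)
    a2 <- vapply(gAa, `[`, character(1), 2L)
    for (h0 in DINUCS) {
      e <- pEnd[a1, substr(h0, 1L, 1L)] * pStart[a2, substr(h0, 2L, 2L)]
      o <- oMat[, h0] / nG
      inf <- !is.na(e) & e > 0 & e < 1 & nG >= minGroupCount
      rows[[length(rows) + 1L]] <- .ssduRow(h0, "bridge", o, e, nG, inf)
    }
  } else {
    for (h0 in DINUCS)
      rows[[length(rows) + 1L]] <- .ssduRow(h0, "bridge", numeric(0),
                                            numeric(0), numeric(0), logical(0))
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.ntIndicator <- function(nt) {
  m <- matrix(0, nrow = length(nt), ncol = 4L, dimnames = list(NULL, NT4))
  m[cbind(seq_along(nt), match(nt, NT4))] <- 1
  m
}

.ssduRow <- function(h, fp, o, e, nG, informative) {
  if (!any(informative)) {
    return(data.frame(dinucleotide = h, framePos = fp, observed = NA_real_,
                      expected = NA_real_, ssdu = NA_real_,
                      log2Ssdu = NA_real_, nGroups = 0L, nSites = 0L))
  }
  o <- o[informative]; e <- e[informative]; nG <- nG[informative]
  W <- sum(nG)
  ssdu <- sum(nG * (o / e)) / W
  data.frame(dinucleotide = h, framePos = fp,
             observed = sum(nG * o) / W,
             expected = sum(nG * e) / W,
             ssdu = ssdu,
             log2Ssdu = ifelse(ssdu > 0, log2(ssdu), NA_real_),
             nGroups = sum(informative), nSites = as.integer(round(W)))
}
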