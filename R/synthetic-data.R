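## Synthetic multi-taxon transcriptome generator. Emulates the statistical
## structure the analyses assume: controllable silent-site nucleotide
## composition (and hence GC4), a shared amino-acid profile, log-normal
## transcript lengths and expression, optional expression-linked codon
## selection, i.i.d. UTRs, optional boundary GC enrichment, terminal-stop
## weights, multinomial read counts, log-normal k-mer coverage, and injected
## cross-cell contaminants with coverage asymmetry.

#' A realistic shared amino-acid profile
#'
#' Default amino-acid frequencies used by the generator: enriched for
#' leucine, lysine and isoleucine and depleted for methionine, histidine,
#' cysteine and tryptophan, the usage pattern conserved across foraminifera
#' (and much of the tree of life). Normalized to sum to 1.
#'
#' @return Named numeric(20).
#' @export
defaultAaProfile <- function() {
  p <- c(A = 0.070, C = 0.016, D = 0.052, E = 0.063, F = 0.042,
         G = 0.058, H = 0.021, I = 0.062, K = 0.075, L = 0.095,
         M = 0.021, N = 0.048, P = 0.047, Q = 0.040, R = 0.052,
         S = 0.075, T = 0.055, V = 0.062, W = 0.011, Y = 0.033)
  p / sum(p)
}

#' Silent-site nucleotide distribution for a GC4 target
#'
#' Maps a target GC4 fraction to a nucleotide distribution with the mild
#' strand asymmetry seen at silent sites (positive AT skew: A over T;
#' negative GC skew: C over G).
#'
#' @param gc4Target Fraction of G+C at fourfold sites.
#' @return Named numeric(4) over A, C, G, T.
#' @export
silentNtDistribution <- function(gc4Target) {
  stopifnot(gc4Target >= 0, gc4Target <= 1)
  c(A = (1 - gc4Target) * 0.55, C = gc4Target * 0.55,
    G = gc4Target * 0.45, T = (1 - gc4Target) * 0.45)
}

#' Configuration for one simulated taxon (cell)
#'
#' @param cellId Cell label.
#' @param gc4Target Target GC4 (silent-site GC content); ignored when
#'   \code{silentDist} is given.
#' @param silentDist Optional explicit named numeric(4) silent-site
#'   nucleotide distribution.
#' @param aaProfile Amino-acid frequencies (named numeric(20)).
#' @param nTranscripts Number of transcripts.
#' @param lengthMeanLog,lengthSdLog Log-normal CDS length (codons).
#' @param exprMeanLog,exprSdLog Log-normal true expression.
#' @param selectionStrength Expression-linked codon-selection strength
#'   (>= 0); the optimal codon's weight is multiplied by
#'   exp(selectionStrength * log10(expression)).
#' @param optimalCodons Named character (amino acid -> codon); default: the
#'   most AT-rich synonym (ties broken A over T at the third position).
#' @param utrLenMeanLog,utrLenSdLog Log-normal UTR lengths (nt).
#' @param utrGc UTR GC content (i.i.d. nucleotides).
#' @param boundaryBoostLen,boundaryBoostDelta Number of codons at each CDS
#'   end whose silent-site distribution is shifted toward GC, and the shift
#'   (0 disables; the shifted distribution is (1 - delta) dist + delta
#'   GC-only).
#' @param stopWeights Terminal stop weights over TAA, TAG, TGA (TAG
#'   underweighted by default, as observed in all foraminifera).
#' @param coverageMeanLog,coverageSdLog Log-normal k-mer coverage.
#' @param totalReads Total mapped reads for the multinomial read counts.
#' @param regime Composition regime: "standard" (all transcripts share the
#'   taxon silent distribution), "silent-spread" (each transcript draws its
#'   own silent-site GC level, applied at third positions only) or
#'   "all-positions-spread" (per-transcript GC level applied to every codon
#'   position, amino acids emergent rather than drawn from the profile).
#' @param gcSpreadRange Range of the per-transcript GC level for the spread
#'   regimes (default c(0.15, 0.85)).
#' @return Named list.
#' @export
taxonConfig <- function(cellId, gc4Target = 0.45, silentDist = NULL,
                        aaProfile = defaultAaProfile(),
                        nTranscripts = 300L,
                        lengthMeanLog = log(250), lengthSdLog = 0.35,
                        exprMeanLog = 2, exprSdLog = 1.2,
                        selectionStrength = 0, optimalCodons = NULL,
                        utrLenMeanLog = log(150), utrLenSdLog = 0.4,
                        utrGc = 0.35,
                        boundaryBoostLen = 0L, boundaryBoostDelta = 0,
                        stopWeights = c(TAA = 0.55, TAG = 0.10, TGA = 0.35),
                        coverageMeanLog = log(50), coverageSdLog = 1,
                        totalReads = 2e5,
                        regime = c("standard", "silent-spread",
                                   "all-positions-spread"),
                        gcSpreadRange = c(0.15, 0.85)) {
  regime <- match.arg(regime)
  if (is.null(silentDist)) silentDist <- silentNtDistribution(gc4Target)
  if (abs(sum(silentDist) - 1) > 1e-8) stop("silentDist must sum to 1")
  if (abs(sum(aaProfile) - 1) > 1e-6) stop("aaProfile must sum to 1")
  if (any(stopWeights < 0) || sum(stopWeights) <= 0)
    stop("invalid stopWeights")
  stopWeights <- stopWeights / sum(stopWeights)
  as.list(environment())
}

#' Default five-taxon panel
#'
#' One taxon per bias category boundary of interest: GC4 targets 0.03 and
#' 0.10 (AT-biased), 0.25 (intermediate), 0.45 (non-biased) and 0.72
#' (GC-biased).
#'
#' @param ... Overrides passed to every [taxonConfig()] call.
#' @return List of taxon configurations.
#' @export
defaultPanel <- function(...) {
  targets <- c(0.03, 0.10, 0.25, 0.45, 0.72)
  lapply(targets, function(g)
    taxonConfig(cellId = sprintf("cell_gc%02d", round(100 * g)),
                gc4Target = g, ...))
}

#' Simulation configuration
#'
#' @param taxa List of [taxonConfig()] objects (default: [defaultPanel()]).
#' @param contamination List of contamination events, each a list with
#'   donorCell, recipientCell, nSeqs, coverageRatio.
#' @param seed Optional integer seed; all generation is reproducible from it.
#' @return Named list.
#' @export
simulationConfig <- function(taxa = defaultPanel(), contamination = list(),
                             seed = NULL) {
  list(taxa = taxa, contamination = contamination, seed = seed)
}

## internal: default optimal codon per amino acid: the most AT-rich synonym,
## ties broken toward A at the third position, then alphabetically
.defaultOptimalCodons <- function(code) {
  vapply(code@aaToCodons, function(syn) {
    at <- vapply(strsplit(syn, ""), function(ch) sum(ch %in% c("A", "T")),
                 numeric(1))
    cand <- syn[at == max(at)]
    third <- substr(cand, 3L, 3L)
    if (any(third == "A")) cand <- cand[third == "A"]
    sort(cand)[1L]
  }, character(1))
}

## internal: draw codons for sites of one amino acid (vectorized).
## weights[site, codon] = prod_p freqs_p(nt_p) * selection tilt; freqs at
## position 3 (and 1-2 in the all-positions case) may vary per transcript.
.sampleCodonsForAa <- function(syn, nSites, w) {
  if (length(syn) == 1L) return(rep(syn, nSites))
  ## w: nSites x length(syn) positive weight matrix
  cw <- w / rowSums(w)
  cum <- cw
  for (j in 2:ncol(cum)) cum[, j] <- cum[, j - 1L] + cum[, j]
  u <- runif(nSites)
  idx <- rowSums(u > cum) + 1L
  idx[idx > length(syn)] <- length(syn)
  syn[idx]
}

#' Simulate a multi-taxon transcriptome
#'
#' Generates in-frame CDS per taxon: amino acids i.i.d. from the taxon's
#' profile (first codon fixed to ATG), codons drawn from the taxon's silent
#' nucleotide distribution restricted to each amino acid's synonyms (product
#' over positions, normalized within the family) and tilted toward the
#' designated optimal codon with weight exp(selectionStrength *
#' log10(expression)); a terminal stop from the stop weights; i.i.d. UTRs;
#' read counts multinomial with rates proportional to expression times
#' length; log-normal k-mer coverage. Gene-family ids are shared across taxa
#' by transcript index (an idealized single-copy ortholog set).
#'
#' @param config A [simulationConfig()] (or list of taxonConfig for
#'   convenience).
#' @param seed Optional integer seed overriding the config's.
#' @return List with \code{records} (a [TranscriptSet-class]), \code{truth}
#'   (per-transcript data.frame: trueExpression, optimalCodonFraction,
#'   contaminant, gcLevel) and \code{taxonTruth} (per-taxon targets and
#'   regime labels).
#' @export
simulateTranscriptome <- function(config = simulationConfig(), seed = NULL) {
  if (!is.null(config$cellId)) config <- simulationConfig(taxa = list(config))
  if (is.null(config$taxa)) config <- simulationConfig(taxa = config)
  seed <- if (!is.null(seed)) seed else config$seed
  if (!is.null(seed)) set.seed(seed)
  code <- standardGeneticCode()

  allCds <- character(0); allIds <- character(0)
  allCell <- character(0); allFam <- character(0)
  allUtr5 <- character(0); allUtr3 <- character(0)
  allCov <- numeric(0); allCnt <- numeric(0)
  truthRows <- list()

  for (tx in config$taxa) {
    sim <- .simulateCell(tx, code)
    allCds <- c(allCds, sim$cdsWithStop)
    allIds <- c(allIds, sim$ids)
    allCell <- c(allCell, rep(tx$cellId, length(sim$ids)))
    allFam <- c(allFam, sim$fam)
    allUtr5 <- c(allUtr5, sim$utr5)
    allUtr3 <- c(allUtr3, sim$utr3)
    allCov <- c(allCov, sim$coverage)
    allCnt <- c(allCnt, sim$readCount)
    truthRows[[length(truthRows) + 1L]] <- sim$truth
  }
  names(allCds) <- allIds
  ts <- TranscriptSet(allCds, cellId = allCell, geneFamilyId = allFam,
                      utr5 = allUtr5, utr3 = allUtr3,
                      kmerCoverage = allCov, readCount = allCnt)
  truth <- do.call(rbind, truthRows)
  taxonTruth <- do.call(rbind, lapply(config$taxa, function(tx)
    data.frame(cellId = tx$cellId,
               gc4Target = sum(tx$silentDist[c("G", "C")]),
               regime = tx$regime,
               selectionStrength = tx$selectionStrength)))
  out <- list(records = ts, truth = truth, taxonTruth = taxonTruth)
  if (length(config$contamination))
    out <- injectContamination(out, config$contamination)
  out
}

.simulateCell <- function(tx, code) {
  n <- tx$nTranscripts
  lens <- pmax(30L, as.integer(round(rlnorm(n, tx$lengthMeanLog,
                                            tx$lengthSdLog))))
  expr <- rlnorm(n, tx$exprMeanLog, tx$exprSdLog)
  ids <- sprintf("%s_t%04d", tx$cellId, seq_len(n))
  fam <- sprintf("gf%04d", seq_len(n))
  opt <- tx$optimalCodons
  if (is.null(opt)) opt <- .defaultOptimalCodons(code)

  spread <- tx$regime != "standard"
  gcLevel <- if (spread)
    runif(n, tx$gcSpreadRange[1L], tx$gcSpreadRange[2L])
  else rep(sum(tx$silentDist[c("G", "C")]), n)
  distByTx <- if (spread)
    t(vapply(gcLevel, silentNtDistribution, numeric(4)))
  else matrix(tx$silentDist, nrow = n, ncol = 4L, byrow = TRUE,
              dimnames = list(NULL, names(tx$silentDist)))
  colnames(distByTx) <- names(tx$silentDist)
  distByTx <- distByTx[, NT4, drop = FALSE]
  taxonDist <- tx$silentDist[NT4]
  boostedOf <- function(d) {
    if (tx$boundaryBoostDelta <= 0) return(d)
    gcOnly <- c(A = 0, C = 0.5, G = 0.5, T = 0)
    (1 - tx$boundaryBoostDelta) * d + tx$boundaryBoostDelta * gcOnly[NT4]
  }

  ## site bookkeeping over all transcripts at once
  siteTx <- rep(seq_len(n), lens)
  sitePos <- unlist(lapply(lens, seq_len), use.names = FALSE)
  siteFromEnd <- unlist(lapply(lens, function(L) rev(seq_len(L))),
                        use.names = FALSE)
  boundary <- tx$boundaryBoostLen > 0 &
    (sitePos <= tx$boundaryBoostLen | siteFromEnd <= tx$boundaryBoostLen)
  nSites <- length(siteTx)

  if (tx$regime == "all-positions-spread") {
    aaSite <- rep("ANY", nSites)
  } else {
    aaSite <- sample(names(tx$aaProfile), nSites, replace = TRUE,
                     prob = tx$aaProfile)
  }
  aaSite[sitePos == 1L] <- if (tx$regime == "all-positions-spread")
    "ANY" else "M"

  codSite <- character(nSites)
  groups <- if (tx$regime == "all-positions-spread") "ANY"
    else unique(aaSite)
  for (aa in groups) {
    sel <- which(aaSite == aa)
    if (!length(sel)) next
    syn <- if (aa == "ANY") code@senseCodons else code@aaToCodons[[aa]]
    nt1 <- substr(syn, 1L, 1L); nt2 <- substr(syn, 2L, 2L)
    nt3 <- substr(syn, 3L, 3L)
    txIdx <- siteTx[sel]
    if (tx$regime == "silent-spread" || tx$regime == "standard") {
      ## positions 1-2 always follow the taxon-level distribution so that
      ## per-transcript silent spread stays strictly silent
      w1 <- matrix(taxonDist[nt1], nrow = length(sel), ncol = length(syn),
                   byrow = TRUE)
      w2 <- matrix(taxonDist[nt2], nrow = length(sel), ncol = length(syn),
                   byrow = TRUE)
      d3 <- distByTx[txIdx, , drop = FALSE]
      if (any(boundary[sel])) {
        b <- boundary[sel]
        d3[b, ] <- t(apply(d3[b, , drop = FALSE], 1L, boostedOf))
      }
      w3 <- d3[, nt3, drop = FALSE]
    } else {
      d <- distByTx[txIdx, , drop = FALSE]
      w1 <- d[, nt1, drop = FALSE]
      w2 <- d[, nt2, drop = FALSE]
      w3 <- d[, nt3, drop = FALSE]
    }
    w <- w1 * w2 * w3
    if (tx$selectionStrength > 0 && aa != "ANY") {
      isOpt <- syn == opt[[aa]]
      if (any(isOpt)) {
        tilt <- exp(tx$selectionStrength * log10(expr[txIdx]))
        w[, isOpt] <- w[, isOpt] * tilt
      }
    }
    bad <- rowSums(w) <= 0
    if (any(bad)) w[bad, ] <- 1
    codSite[sel] <- .sampleCodonsForAa(syn, length(sel), w)
  }

  stops <- sample(names(tx$stopWeights), n, replace = TRUE,
                  prob = tx$stopWeights)
  cdsBody <- vapply(split(codSite, siteTx), paste, character(1), collapse = "")
  cdsWithStop <- paste0(cdsBody[as.character(seq_len(n))], stops)

  utrDist <- c(A = (1 - tx$utrGc) / 2, C = tx$utrGc / 2,
               G = tx$utrGc / 2, T = (1 - tx$utrGc) / 2)
  drawUtr <- function() {
    L <- max(10L, as.integer(round(rlnorm(1, tx$utrLenMeanLog,
                                          tx$utrLenSdLog))))
    paste(sample(NT4, L, replace = TRUE, prob = utrDist), collapse = "")
  }
  utr5 <- vapply(seq_len(n), function(i) drawUtr(), character(1))
  utr3 <- vapply(seq_len(n), function(i) drawUtr(), character(1))

  ntLens <- nchar(cdsWithStop)
  rates <- expr * ntLens
  readCount <- as.numeric(rmultinom(1L, size = tx$totalReads,
                                    prob = rates / sum(rates)))
  coverage <- rlnorm(n, tx$coverageMeanLog, tx$coverageSdLog)

  optFrac <- vapply(split(seq_len(nSites), siteTx), function(ix) {
    aaHere <- aaSite[ix]
    ok <- aaHere %in% names(opt)
    if (!any(ok)) return(NA_real_)
    mean(codSite[ix][ok] == opt[aaHere[ok]])
  }, numeric(1))

  list(cdsWithStop = cdsWithStop, ids = ids, fam = fam,
       utr5 = utr5, utr3 = utr3, coverage = coverage,
       readCount = readCount,
       truth = data.frame(transcriptId = ids, cellId = tx$cellId,
                          trueExpression = expr,
                          lengthCodons = lens,
                          gcLevel = gcLevel,
                          optimalCodonFraction =
                            optFrac[as.character(seq_len(n))],
                          contaminant = FALSE))
}

#' Inject cross-cell contaminants
#'
#' Copies donor transcripts into recipient cells at >= 99% identity (a small
#' number of synonymous third-position substitutions) with k-mer coverage
#' scaled by \code{coverageRatio}, emulating index hopping between cells on
#' one sequencing plate. Truth flags are set on the planted copies.
#'
#' @param sim A list as returned by [simulateTranscriptome()].
#' @param events List of events: each a list with donorCell, recipientCell,
#'   nSeqs, coverageRatio (> 0).
#' @return The amended simulation list.
#' @export
injectContamination <- function(sim, events) {
  code <- standardGeneticCode()
  ts <- sim$records
  for (ev in events) {
    if (is.null(ev$coverageRatio) || ev$coverageRatio <= 0)
      stop("coverageRatio must be positive")
    td <- ts@transcriptData
    donors <- which(td$cellId == ev$donorCell & !grepl("_xc_", td$transcriptId))
    if (!length(donors)) stop("no donor transcripts in cell ", ev$donorCell)
    pick <- sample(donors, min(ev$nSeqs, length(donors)))
    for (i in pick) {
      seqStr <- as.character(ts@cds[[i]])
      mut <- .mutateSynonymously(seqStr, code,
                                 nSub = max(1L, floor(0.004 * nchar(seqStr))))
      newId <- sprintf("%s_xc_%s", td$transcriptId[i], ev$recipientCell)
      add <- TranscriptSet(
        setNames(Biostrings::DNAStringSet(mut), newId),
        cellId = ev$recipientCell,
        geneFamilyId = td$geneFamilyId[i],
        kmerCoverage = td$kmerCoverage[i] * ev$coverageRatio,
        readCount = max(1, round(td$readCount[i] * ev$coverageRatio)))
      ts <- .bindTranscriptSets(ts, add)
      sim$truth <- rbind(sim$truth, data.frame(
        transcriptId = newId, cellId = ev$recipientCell,
        trueExpression = NA_real_, lengthCodons = nchar(mut) / 3,
        gcLevel = NA_real_, optimalCodonFraction = NA_real_,
        contaminant = TRUE))
    }
  }
  sim$records <- ts
  sim
}

## internal: substitute nSub third positions of fourfold-box codons with a
## different allowed nucleotide (amino acid unchanged, frame intact)
.mutateSynonymously <- function(seqStr, code, nSub) {
  cods <- .codonSplit(seqStr)
  four <- which(cods %in% code@fourfoldThirdSet)
  if (!length(four)) return(seqStr)
  pick <- sample(four, min(nSub, length(four)))
  for (i in pick) {
    cur <- substr(cods[i], 3L, 3L)
    substr(cods[i], 3L, 3L) <- sample(setdiff(NT4, cur), 1L)
  }
  paste(cods, collapse = "")
}

.bindTranscriptSets <- function(a, b) {
  new("TranscriptSet",
      cds = c(a@cds, b@cds),
      transcriptData = rbind(a@transcriptData, b@transcriptData))
}
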