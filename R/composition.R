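## Nucleotide-level composition metrics on CDS and UTRs.
##
## All metrics operate on in-frame CDS strings (sense strand). A terminal stop
## codon, if present, is excluded, as are codons containing N; trailing
## partial codons are dropped.

## internal: split a sequence into codon strings (trailing partial codon
## dropped); returns character(0) for sequences shorter than one codon.
.codonSplit <- function(seq) {
  n <- nchar(seq)
  n <- n - n %% 3L
  if (n < 3L) return(character(0))
  substring(seq, seq.int(1L, n - 2L, 3L), seq.int(3L, n, 3L))
}

## internal: analyzable sense codons of one CDS: terminal stop removed,
## stop codons and N/ambiguity-containing codons dropped.
## Returns list(codons=, terminalStop= NA or codon string).
.senseCodons <- function(seq, code) {
  cods <- .codonSplit(toupper(seq))
  termStop <- NA_character_
  if (length(cods) && cods[length(cods)] %in% code@stopSet) {
    termStop <- cods[length(cods)]
    cods <- cods[-length(cods)]
  }
  cods <- cods[cods %in% code@senseCodons]
  list(codons = cods, terminalStop = termStop)
}

## internal: coerce DNAStringSet / character to character vector of sequences
.asSeqChar <- function(x) {
  if (is(x, "XStringSet")) as.character(x) else as.character(x)
}

#' GC content at fourfold degenerate silent sites (GC4)
#'
#' Fraction of G or C among the third positions of codons whose third position
#' is fourfold degenerate (the eight four-codon boxes, including the fourfold
#' halves of leucine, serine and arginine). Threefold (isoleucine) and twofold
#' sites do not qualify.
#'
#' @param cds Character vector of in-frame CDS, or a DNAStringSet.
#' @param code A [GeneticCode-class] object.
#' @return Numeric vector; NA where a sequence has no qualifying codon.
#' @examples
#' code <- standardGeneticCode()
#' gc4("GGGGGC", code) # 1
#' gc4("ATGTGG", code) # NA: no fourfold site
#' @export
gc4 <- function(cds, code) {
  vapply(.asSeqChar(cds), function(s) {
    cods <- .senseCodons(s, code)$codons
    cods <- cods[cods %in% code@fourfoldThirdSet]
    if (!length(cods)) return(NA_real_)
    mean(substr(cods, 3L, 3L) %in% c("G", "C"))
  }, numeric(1), USE.NAMES = FALSE)
}

#' GC content at third positions of GC3S-eligible codons
#'
#' Fraction of G or C at the third positions of all sense codons except those
#' encoding methionine (ATG) and tryptophan (TGG).
#'
#' @inheritParams gc4
#' @return Numeric vector; NA where no eligible codon exists.
#' @export
gc3s <- function(cds, code) {
  vapply(.asSeqChar(cds), function(s) {
    cods <- .senseCodons(s, code)$codons
    cods <- cods[cods %in% code@gc3sEligibleSet]
    if (!length(cods)) return(NA_real_)
    mean(substr(cods, 3L, 3L) %in% c("G", "C"))
  }, numeric(1), USE.NAMES = FALSE)
}

#' GC content at codon positions 1 and 2 (GC12)
#'
#' Fraction of G or C over the first and second positions of all sense codons,
#' the largely non-synonymous positions.
#'
#' @inheritParams gc4
#' @return Numeric vector.
#' @export
gc12 <- function(cds, code) {
  vapply(.asSeqChar(cds), function(s) {
    cods <- .senseCodons(s, code)$codons
    if (!length(cods)) stop("gc12 requires at least one sense codon")
    nts <- c(substr(cods, 1L, 1L), substr(cods, 2L, 2L))
    mean(nts %in% c("G", "C"))
  }, numeric(1), USE.NAMES = FALSE)
}

#' AT and GC strand skews
#'
#' Computes the strand asymmetry measures AT skew = (A - T)/(A + T) and GC
#' skew = (G - C)/(G + C) over a set of nucleotides, given either as a single
#' sequence string or as a character vector of single nucleotides.
#'
#' @param x A sequence string (length-1 character) or a character vector of
#'   nucleotides.
#' @return Named numeric vector \code{c(atSkew=, gcSkew=)}; NA where the
#'   denominator is zero.
#' @examples
#' skews("AATT") # atSkew 0, gcSkew NA
#' @export
skews <- function(x) {
  if (length(x) == 1L && nchar(x[1L]) > 1L)
    x <- strsplit(toupper(x), "")[[1L]]
  else
    x <- toupper(x)
  a <- sum(x == "A"); t <- sum(x == "T")
  g <- sum(x == "G"); cc <- sum(x == "C")
  c(atSkew = if (a + t > 0) (a - t) / (a + t) else NA_real_,
    gcSkew = if (g + cc > 0) (g - cc) / (g + cc) else NA_real_)
}

#' Third-position nucleotides at silent sites
#'
#' Extracts the third-position nucleotides of fourfold-degenerate (or
#' GC3S-eligible) codons of one or more CDS; used for silent-site skews and
#' for single-nucleotide null expectations.
#'
#' @inheritParams gc4
#' @param siteSet "fourfold" (default) or "gc3s".
#' @return Character vector of nucleotides, pooled over sequences.
#' @export
silentThirdNucleotides <- function(cds, code, siteSet = c("fourfold", "gc3s")) {
  siteSet <- match.arg(siteSet)
  keep <- if (siteSet == "fourfold") code@fourfoldThirdSet else code@gc3sEligibleSet
  unlist(lapply(.asSeqChar(cds), function(s) {
    cods <- .senseCodons(s, code)$codons
    substr(cods[cods %in% keep], 3L, 3L)
  }), use.names = FALSE)
}

#' Positional silent-site GC profile near CDS ends
#'
#' Mean GC3S indicator by codon index counted from the 5' end and from the 3'
#' end, over a set of transcripts. Used to detect elevated silent-site GC
#' near CDS-UTR boundaries. Transcripts shorter than the window contribute
#' only their available indices.
#'
#' @inheritParams gc4
#' @param window Number of codon positions profiled from each end (default 50).
#' @return List with data.frames \code{fivePrime} and \code{threePrime}, each
#'   with columns index, meanGc3s, n.
#' @export
positionalGc3sProfile <- function(cds, code, window = 50L) {
  window <- as.integer(window)
  if (is.na(window) || window < 1L) stop("window must be a positive integer")
  sum5 <- n5 <- sum3 <- n3 <- numeric(window)
  for (s in .asSeqChar(cds)) {
    cods <- .senseCodons(s, code)$codons
    elig <- cods %in% code@gc3sEligibleSet
    gcv <- substr(cods, 3L, 3L) %in% c("G", "C")
    L <- length(cods)
    if (!L) next
    k <- min(window, L)
    i5 <- seq_len(k)
    use <- elig[i5]
    n5[i5][use] <- n5[i5][use] + 1
    sum5[i5][use] <- sum5[i5][use] + gcv[i5][use]
    i3 <- L - seq_len(k) + 1L          # codon index counted from the 3' end
    use <- elig[i3]
    n3[seq_len(k)][use] <- n3[seq_len(k)][use] + 1
    sum3[seq_len(k)][use] <- sum3[seq_len(k)][use] + gcv[i3][use]
  }
  list(
    fivePrime = data.frame(index = seq_len(window),
                           meanGc3s = ifelse(n5 > 0, sum5 / n5, NA_real_),
                           n = as.integer(n5)),
    threePrime = data.frame(index = seq_len(window),
                            meanGc3s = ifelse(n3 > 0, sum3 / n3, NA_real_),
                            n = as.integer(n3)))
}

#' Classify compositional bias from median GC4
#'
#' Assigns the per-taxon bias category from the median GC4 over transcripts:
#' AT-biased below 15%, intermediate below 40%, non-biased up to 60%,
#' GC-biased above, mirroring the category ranges observed in foraminifera
#' (2.3%-13% AT-biased taxa through 70%-76% GC-biased taxa).
#'
#' @param medianGc4 Numeric vector of median GC4 fractions.
#' @return Character vector in \{"AT-biased", "intermediate", "non-biased",
#'   "GC-biased", "unclassified"\} (the latter for NA input).
#' @export
classifyBias <- function(medianGc4) {
  out <- rep("unclassified", length(medianGc4))
  ok <- !is.na(medianGc4)
  x <- medianGc4[ok]
  out[ok] <- ifelse(x < 0.15, "AT-biased",
             ifelse(x < 0.40, "intermediate",
             ifelse(x <= 0.60, "non-biased", "GC-biased")))
  out
}

#' Dinucleotide bias of UTRs controlling for single-nucleotide frequency
#'
#' Observed/expected ratio f(XY) / (f(X) f(Y)) per dinucleotide, where f(XY)
#' is the frequency among overlapping dinucleotides within each UTR (pairs
#' never span two UTRs) and f(X) the single-nucleotide frequency over the same
#' UTR set. A ratio of 1 indicates no bias beyond mononucleotide content.
#'
#' @param utrs Character vector of UTR sequences (NAs dropped).
#' @return Named numeric(16) of ratios, names "AA".."TT"; NA where the
#'   expected frequency is zero or no dinucleotide exists.
#' @export
utrDinucleotideBias <- function(utrs) {
  utrs <- toupper(utrs[!is.na(utrs) & nzchar(utrs)])
  dinucs <- as.vector(outer(NT4, NT4, paste0))
  out <- setNames(rep(NA_real_, 16L), sort(dinucs))
  if (!length(utrs)) return(out)
  ntCounts <- setNames(numeric(4), NT4)
  diCounts <- setNames(numeric(16), sort(dinucs))
  for (u in utrs) {
    chars <- strsplit(u, "")[[1L]]
    chars <- chars
    tb <- table(factor(chars[chars %in% NT4], levels = NT4))
    ntCounts <- ntCounts + as.numeric(tb)
    if (length(chars) >= 2L) {
      di <- paste0(chars[-length(chars)], chars[-1L])
      di <- di[di %in% names(diCounts)]
      if (length(di)) {
        tb2 <- table(factor(di, levels = names(diCounts)))
        diCounts <- diCounts + as.numeric(tb2)
      }
    }
  }
  nNt <- sum(ntCounts); nDi <- sum(diCounts)
  if (nNt == 0 || nDi == 0) return(out)
  fNt <- ntCounts / nNt
  fDi <- diCounts / nDi
  for (d in names(out)) {
    e <- fNt[[substr(d, 1L, 1L)]] * fNt[[substr(d, 2L, 2L)]]
    out[[d]] <- if (e > 0) fDi[[d]] / e else NA_real_
  }
  out
}
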