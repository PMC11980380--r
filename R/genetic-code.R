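#' @import methods
#' @importClassesFrom Biostrings DNAStringSet
#' @importFrom stats median mad quantile rlnorm runif rmultinom setNames
#'   complete.cases aggregate cor.test lm coef p.adjust var sd
#' @importFrom utils read.delim write.table head tail
NULL

## fixed alphabets used throughout (one-letter amino-acid codes, sorted)
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
NT4 <- c("A", "C", "G", "T")
FYMINK <- c("F", "Y", "M", "I", "N", "K")
GARP <- c("G", "A", "R", "P")

#' GeneticCode: the standard nuclear code with degeneracy machinery
#'
#' Holds the codon-to-amino-acid table of the "universal" genetic code (61
#' sense codons, 3 stops) together with every derived degeneracy structure the
#' composition and codon-usage statistics need: per-position synonymous
#' nucleotide sets, third-position degeneracy classes (onefold to fourfold),
#' the set of codons with a strictly fourfold-degenerate third position (the
#' GC4 site set), and the 59-codon GC3S-eligible set (all sense codons except
#' ATG and TGG).
#'
#' @slot codonToAa named character(64); maps codon to one-letter amino acid or
#'   \code{"*"} for stops.
#' @slot senseCodons character(61), the non-stop codons.
#' @slot stopSet character(3): TAA, TAG, TGA.
#' @slot aaToCodons named list(20): synonymous codons per amino acid.
#' @slot synNtSets named list(61); for each sense codon, a list of three
#'   character vectors giving the nucleotides at that position that preserve
#'   the encoded amino acid with the other two positions held fixed.
#' @slot posDegeneracy integer matrix 61 x 3; sizes of the synNtSets.
#' @slot thirdPosDegeneracy named integer(61); degeneracy class of the third
#'   position (1, 2, 3 or 4).
#' @slot fourfoldThirdSet character(32); codons whose third position is
#'   fourfold degenerate (the 8 four-codon boxes, including the fourfold
#'   halves of Leu, Ser and Arg).
#' @slot gc3sEligibleSet character(59); sense codons excluding ATG and TGG.
#' @slot sixfoldFamilies character(3): Leu, Ser, Arg, kept separately for
#'   Wright's ENc class averaging.
#' @exportClass GeneticCode
setClass("GeneticCode", representation(
  codonToAa = "character",
  senseCodons = "character",
  stopSet = "character",
  aaToCodons = "list",
  synNtSets = "list",
  posDegeneracy = "matrix",
  thirdPosDegeneracy = "integer",
  fourfoldThirdSet = "character",
  gc3sEligibleSet = "character",
  sixfoldFamilies = "character"
))

setValidity("GeneticCode", function(object) {
  msgs <- character(0)
  if (length(object@senseCodons) != 61L)
    msgs <- c(msgs, "must have exactly 61 sense codons")
  if (length(object@stopSet) != 3L)
    msgs <- c(msgs, "must have exactly 3 stop codons")
  if (length(object@fourfoldThirdSet) != 32L)
    msgs <- c(msgs, "fourfoldThirdSet must contain 32 codons")
  if (length(object@gc3sEligibleSet) != 59L)
    msgs <- c(msgs, "gc3sEligibleSet must contain 59 codons")
  deg <- object@thirdPosDegeneracy
  if (!all(names(deg) %in% object@senseCodons) ||
      !all(deg %in% 1:4))
    msgs <- c(msgs, "thirdPosDegeneracy must assign each sense codon a class in 1..4")
  ile <- c("ATA", "ATT", "ATC")
  if (!all(deg[ile] == 3L))
    msgs <- c(msgs, "isoleucine codons must have third-position class 3")
  if (length(msgs)) msgs else TRUE
})

#' Build the standard nuclear genetic code
#'
#' Constructs a [GeneticCode-class] object from the standard code table,
#' deriving all degeneracy sets by brute-force substitution: a nucleotide
#' belongs to the synonymous set of a codon position if substituting it (with
#' the other two positions held fixed) yields the same amino acid.
#' Substitutions that create a stop codon never count as synonymous.
#'
#' @return A validated [GeneticCode-class] object.
#' @examples
#' code <- standardGeneticCode()
#' positionDegeneracy(code, "GGA", 3) # 4 (glycine box)
#' @export
standardGeneticCode <- function() {
  tab <- Biostrings::GENETIC_CODE
  codons <- names(tab)
  stopSet <- sort(codons[tab == "*"])
  sense <- codons[tab != "*"]
  aaToCodons <- split(sense, tab[sense])

  synNtSets <- vector("list", length(sense))
  names(synNtSets) <- sense
  posDeg <- matrix(NA_integer_, nrow = length(sense), ncol = 3,
                   dimnames = list(sense, NULL))
  for (cod in sense) {
    aa <- tab[[cod]]
    sets <- vector("list", 3L)
    for (p in 1:3) {
      variants <- vapply(NT4, function(nt) {
        v <- cod
        substr(v, p, p) <- nt
        v
      }, character(1))
      sets[[p]] <- NT4[tab[variants] == aa]
      posDeg[cod, p] <- length(sets[[p]])
    }
    synNtSets[[cod]] <- sets
  }
  thirdDeg <- posDeg[, 3L]
  fourfold <- sort(sense[thirdDeg == 4L])
  gc3s <- sort(setdiff(sense, c("ATG", "TGG")))
  sixfold <- names(aaToCodons)[lengths(aaToCodons) == 6L]

  new("GeneticCode",
      codonToAa = tab,
      senseCodons = sense,
      stopSet = stopSet,
      aaToCodons = aaToCodons[AA20],
      synNtSets = synNtSets,
      posDegeneracy = posDeg,
      thirdPosDegeneracy = setNames(as.integer(thirdDeg), sense),
      fourfoldThirdSet = fourfold,
      gc3sEligibleSet = gc3s,
      sixfoldFamilies = sort(sixfold))
}

setMethod("show", "GeneticCode", function(object) {
  cat("GeneticCode (standard nuclear code)\n",
      " sense codons: ", length(object@senseCodons),
      "; stops: ", paste(object@stopSet, collapse = ", "), "\n",
      " fourfold third positions: ", length(object@fourfoldThirdSet),
      "; GC3S-eligible codons: ", length(object@gc3sEligibleSet), "\n",
      sep = "")
})

#' Number of synonymous nucleotides at one codon position
#'
#' Returns the degeneracy of a single codon position: how many of the four
#' nucleotides keep the encoded amino acid unchanged when the other two
#' positions are held fixed. Third positions take values 1-4; first positions
#' are 1 or 2 (the split boxes of Leu and Arg); second positions are always 1.
#'
#' @param code A [GeneticCode-class] object.
#' @param codon A sense codon (character scalar, e.g. "GGA").
#' @param position Codon position, 1, 2 or 3.
#' @return Integer in 1..4.
#' @examples
#' code <- standardGeneticCode()
#' positionDegeneracy(code, "ATA", 3) # 3: isoleucine box
#' positionDegeneracy(code, "TTA", 1) # 2: T or C both give leucine
#' @export
positionDegeneracy <- function(code, codon, position) {
  stopifnot(is(code, "GeneticCode"), position %in% 1:3)
  codon <- toupper(codon)
  if (codon %in% code@stopSet)
    stop("position degeneracy is undefined for stop codon ", codon)
  if (!codon %in% code@senseCodons)
    stop("not a sense codon: ", codon)
  unname(code@posDegeneracy[codon, position])
}

#' Nucleotides that preserve the amino acid at a codon position
#'
#' @inheritParams positionDegeneracy
#' @return Character vector of synonymous nucleotides (always contains the
#'   codon's own nucleotide at that position).
#' @export
synonymousNucleotides <- function(code, codon, position) {
  stopifnot(is(code, "GeneticCode"), position %in% 1:3)
  codon <- toupper(codon)
  if (!codon %in% code@senseCodons)
    stop("not a sense codon: ", codon)
  code@synNtSets[[codon]][[position]]
}

#' Dump the genetic-code degeneracy tables to TSV (for audit)
#'
#' @param code A [GeneticCode-class] object.
#' @param path Output TSV path.
#' @return Invisibly, the data.frame written.
#' @export
writeGeneticCodeTable <- function(code, path) {
  df <- data.frame(
    codon = code@senseCodons,
    aa = unname(code@codonToAa[code@senseCodons]),
    deg1 = code@posDegeneracy[, 1L],
    deg2 = code@posDegeneracy[, 2L],
    deg3 = code@posDegeneracy[, 3L],
    fourfoldThird = code@senseCodons %in% code@fourfoldThirdSet,
    gc3sEligible = code@senseCodons %in% code@gc3sEligibleSet,
    row.names = NULL)
  df <- df[order(df$codon), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

## internal: amino acid of a (vector of) sense codons
.aaOf <- function(code, codons) unname(code@codonToAa[codons])
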