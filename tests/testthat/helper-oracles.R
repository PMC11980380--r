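## Independent oracle implementations, deliberately naive (scalar loops over
## codons), used to cross-check the vectorized package code.

CODE <- standardGeneticCode()

## brute-force codon table of one sequence (terminal stop dropped, stops and
## N codons excluded)
oracleCodons <- function(seq) {
  seq <- toupper(seq)
  out <- character(0)
  i <- 1
  while (i + 2 <= nchar(seq)) {
    out <- c(out, substr(seq, i, i + 2))
    i <- i + 3
  }
  if (length(out) && out[length(out)] %in% c("TAA", "TAG", "TGA"))
    out <- out[-length(out)]
  out[out %in% CODE@senseCodons]
}

## step-by-step Wright ENc from a named 61-count vector
oracleEnc <- function(counts) {
  fams <- CODE@aaToCodons
  k <- lengths(fams)
  Fbar <- function(aas) {
    fs <- c()
    for (aa in aas) {
      n <- sum(counts[fams[[aa]]])
      if (n < 2) next
      p <- counts[fams[[aa]]] / n
      f <- (n * sum(p^2) - 1) / (n - 1)
      if (f > 0) fs <- c(fs, f)
    }
    if (length(fs)) mean(fs) else NA_real_
  }
  F2 <- Fbar(names(fams)[k == 2]); F3 <- Fbar(names(fams)[k == 3])
  F4 <- Fbar(names(fams)[k == 4]); F6 <- Fbar(names(fams)[k == 6])
  if (is.na(F3)) F3 <- (F2 + F4) / 2
  if (is.na(F2) || is.na(F4) || is.na(F6)) return(NA_real_)
  min(61, 2 + 9 / F2 + 1 / F3 + 5 / F4 + 3 / F6)
}

## brute-force Benjamini-Hochberg step-up
oracleBH <- function(p) {
  m <- length(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cands <- c()
    for (j in seq_len(m)) {
      rj <- sum(p <= p[j])              # rank of p_j among sorted values
      if (p[j] >= p[i]) cands <- c(cands, m * p[j] / rj)
    }
    q[i] <- min(1, min(cands))
  }
  q
}

## direct equal-usage synonymous dinucleotide usage (SDU) estimator:
## groups are amino acids (pos1/pos2) or ordered amino-acid pairs (bridge);
## e_g assumes every synonymous codon equally likely
oracleSdu <- function(codons, pairs, minGroupCount = 10) {
  fams <- CODE@aaToCodons
  aaOf <- function(cod) unname(CODE@codonToAa[cod])
  dinPos <- function(cod, fp)
    if (fp == "pos1") substr(cod, 1, 2) else substr(cod, 2, 3)
  out <- list()
  dinucs <- sort(as.vector(outer(c("A","C","G","T"), c("A","C","G","T"), paste0)))
  for (fp in c("pos1", "pos2")) for (h in dinucs) {
    num <- den <- 0; any <- FALSE
    for (aa in names(fams)) {
      syn <- fams[[aa]]
      e <- mean(dinPos(syn, fp) == h)
      obsCod <- codons[aaOf(codons) == aa]
      n <- length(obsCod)
      if (n < minGroupCount || e <= 0 || e >= 1) next
      o <- mean(dinPos(obsCod, fp) == h)
      num <- num + n * o / e; den <- den + n; any <- TRUE
    }
    out[[paste(h, fp)]] <- if (any) num / den else NA_real_
  }
  if (!is.null(pairs)) {
    aa1 <- aaOf(pairs[, 1]); aa2 <- aaOf(pairs[, 2])
    grp <- paste(aa1, aa2)
    for (h in dinucs) {
      num <- den <- 0; any <- FALSE
      for (g in unique(grp)) {
        sel <- grp == g
        n <- sum(sel)
        if (n < minGroupCount) next
        a <- sub(" .*", "", g); b <- sub(".* ", "", g)
        e <- mean(substr(fams[[a]], 3, 3) == substr(h, 1, 1)) *
             mean(substr(fams[[b]], 1, 1) == substr(h, 2, 2))
        if (e <= 0 || e >= 1) next
        o <- mean(substr(pairs[sel, 1], 3, 3) == substr(h, 1, 1) &
                  substr(pairs[sel, 2], 1, 1) == substr(h, 2, 2))
        num <- num + n * o / e; den <- den + n; any <- TRUE
      }
      out[[paste(h, "bridge")]] <- if (any) num / den else NA_real_
    }
  }
  out
}

## random in-frame CDS with given codon count (no terminal stop unless asked)
randomCds <- function(nCodons, withStop = FALSE,
                      pool = CODE@senseCodons) {
  body <- paste(sample(pool, nCodons, replace = TRUE), collapse = "")
  if (withStop) paste0(body, sample(c("TAA", "TAG", "TGA"), 1)) else body
}

## random codon count table (named 61-vector)
randomCountVector <- function(total = 2000) {
  probs <- as.numeric(stats::runif(61)^2)
  counts <- as.numeric(rmultinom(1, total, probs / sum(probs)))
  stats::setNames(counts, CODE@senseCodons)
}

## simulate codon sequences directly from the stratified single-nucleotide
## null (the SSDU null model itself): amino acids i.i.d. from the profile,
## codons drawn from the null's per-family probabilities
simulateFromNull <- function(nTranscripts, codonsPer, freqs,
                             aaProfile = defaultAaProfile()) {
  nullP <- foramCodon:::.nullProbsByAa(freqs, CODE)
  S <- nTranscripts * codonsPer
  aas <- sample(names(aaProfile), S, replace = TRUE, prob = aaProfile)
  cods <- character(S)
  for (aa in unique(aas)) {
    syn <- CODE@aaToCodons[[aa]]
    idx <- which(aas == aa)
    cods[idx] <- if (length(syn) == 1) syn
      else sample(syn, length(idx), replace = TRUE, prob = nullP[syn])
  }
  unname(vapply(split(cods, rep(seq_len(nTranscripts), each = codonsPer)),
                paste, character(1), collapse = ""))
}

## a deliberately non-uniform stratified frequency object
skewedFreqs <- function() {
  fr <- uniformPositionClassFreqs(CODE)
  fr$freqs["3.4", ] <- c(A = 0.45, C = 0.10, G = 0.15, T = 0.30)
  fr$freqs["3.2", ] <- c(A = 0.50, C = 0.20, G = 0.10, T = 0.20)
  fr$freqs["3.3", ] <- c(A = 0.20, C = 0.30, G = 0.10, T = 0.40)
  fr$freqs["1.2", ] <- c(A = 0.30, C = 0.30, G = 0.10, T = 0.30)
  fr
}
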