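test_that("codon counting is exact, additive, and separates terminal stops", {
  tab <- countCodons("ATGGGGGGA", CODE)
  expect_equal(unname(codonCounts(tab)[c("ATG", "GGG", "GGA")]), c(1L, 1L, 1L))
  expect_equal(sum(codonCounts(tab)), 3L)

  withStop <- countCodons("ATGGGGTAA", CODE)
  expect_equal(sum(codonCounts(withStop)), 2L)
  expect_equal(unname(withStop@stopCounts["TAA"]), 1L)

  ## N-containing codons are excluded
  tabN <- countCodons("ATGGNGGGA", CODE)
  expect_equal(sum(codonCounts(tabN)), 2L)

  ## pooling two transcripts equals the sum of their tables
  s1 <- randomCds(20); s2 <- randomCds(30)
  pooled <- countCodons(c(s1, s2), CODE)
  summed <- poolCodonCounts(list(countCodons(s1, CODE), countCodons(s2, CODE)))
  expect_equal(codonCounts(pooled), codonCounts(summed))

  ## brute-force recount over a 10-transcript cell
  set.seed(5)
  seqs <- replicate(10, randomCds(sample(10:50, 1), withStop = TRUE))
  tab10 <- countCodons(seqs, CODE)
  brute <- table(factor(unlist(lapply(seqs, oracleCodons)),
                        levels = CODE@senseCodons))
  expect_equal(unname(codonCounts(tab10)), as.integer(brute))
  ## amino-acid totals consistent with counts under the code map
  expect_equal(unname(tab10@aaTotals),
               unname(vapply(CODE@aaToCodons,
                             function(cs) sum(codonCounts(tab10)[cs]),
                             numeric(1))))
})

test_that("family frequencies reproduce the arginine worked example and the
          unbiased-null midpoints", {
  ## Allogromia arnoldi arginine counts: CGG=3, CGC=8, AGA=1213 of 1845
  counts <- setNames(rep(0, 61), CODE@senseCodons)
  counts["CGG"] <- 3; counts["CGC"] <- 8; counts["AGA"] <- 1213
  counts["CGA"] <- 1845 - 3 - 8 - 1213    # remainder of the family
  tab <- foramCodon:::.countTableFromVector(counts, CODE)
  ff <- familyFrequencies(tab, CODE)
  expect_equal(asPercent(ff[["CGG"]]), 0.16)
  expect_equal(asPercent(ff[["CGC"]]), 0.43)
  expect_equal(asPercent(ff[["AGA"]]), 65.75)

  ## uniform usage: 25% in a fourfold family, 50% in a twofold family
  uni <- setNames(rep(10, 61), CODE@senseCodons)
  tabU <- foramCodon:::.countTableFromVector(uni, CODE)
  ffU <- familyFrequencies(tabU, CODE)
  expect_equal(unname(ffU[CODE@aaToCodons[["G"]]]), rep(0.25, 4))
  expect_equal(unname(ffU[CODE@aaToCodons[["K"]]]), rep(0.5, 2))

  ## a twofold family concentrated in one codon
  one <- setNames(rep(0, 61), CODE@senseCodons); one["AAA"] <- 7
  ffO <- familyFrequencies(foramCodon:::.countTableFromVector(one, CODE), CODE)
  expect_equal(unname(ffO[c("AAA", "AAG")]), c(1, 0))
  expect_true(all(is.na(ffO[CODE@aaToCodons[["G"]]])))
})

test_that("RSCU matches its definition on random tables", {
  set.seed(6)
  for (i in 1:20) {
    counts <- randomCountVector()
    tab <- foramCodon:::.countTableFromVector(counts, CODE)
    rs <- rscu(tab, CODE)
    for (aa in names(CODE@aaToCodons)) {
      syn <- CODE@aaToCodons[[aa]]
      na <- sum(counts[syn])
      if (na == 0) { expect_true(all(is.na(rs[syn]))); next }
      expect_equal(unname(rs[syn]),
                   unname(length(syn) * counts[syn] / na))
      expect_equal(sum(rs[syn]), length(syn))     # family sums to k
    }
  }
  uni <- setNames(rep(10, 61), CODE@senseCodons)
  rsU <- rscu(foramCodon:::.countTableFromVector(uni, CODE), CODE)
  expect_equal(unname(rsU[CODE@aaToCodons[["A"]]]), rep(1, 4))
  one <- setNames(rep(0, 61), CODE@senseCodons); one["AAA"] <- 5
  rsO <- rscu(foramCodon:::.countTableFromVector(one, CODE), CODE)
  expect_equal(unname(rsO[c("AAA", "AAG")]), c(2, 0))
})

test_that("observed ENc hits Wright's limits and matches the step-by-step
          oracle on random tables", {
  ## one codon per amino acid, each used twice: ENc = 20
  minimal <- setNames(rep(0, 61), CODE@senseCodons)
  for (aa in names(CODE@aaToCodons)) minimal[CODE@aaToCodons[[aa]][1]] <- 2
  expect_equal(encObserved(minimal, CODE)$enc, 20)

  ## uniform heavy usage: ENc approaches (and is capped at) 61
  uni <- setNames(rep(10000, 61), CODE@senseCodons)
  expect_equal(encObserved(uni, CODE)$enc, 61)

  set.seed(7)
  for (i in 1:60) {
    counts <- randomCountVector(total = sample(c(200, 1000, 5000), 1))
    expect_equal(encObserved(counts, CODE)$enc, oracleEnc(counts),
                 tolerance = 1e-12)
  }
})

test_that("ENc never decreases when a family's usage becomes more even", {
  set.seed(8)
  for (i in 1:30) {
    counts <- randomCountVector(total = 3000)
    enc0 <- encObserved(counts, CODE)$enc
    ## move one count from the most-used to the least-used codon of a
    ## multi-codon family (a majorization step toward evenness)
    aa <- sample(names(CODE@aaToCodons)[lengths(CODE@aaToCodons) >= 2], 1)
    syn <- CODE@aaToCodons[[aa]]
    if (sum(counts[syn]) < 2) next
    hi <- syn[which.max(counts[syn])]; lo <- syn[which.min(counts[syn])]
    if (counts[hi] - counts[lo] < 2) next
    counts[hi] <- counts[hi] - 1; counts[lo] <- counts[lo] + 1
    enc1 <- encObserved(counts, CODE)$enc
    expect_gte(enc1, enc0 - 1e-9)
  }
})

test_that("the composition-only expected ENc curve has the published
          endpoints and its maximum near 0.5", {
  expect_equal(encExpected(0), 31)
  expect_equal(encExpected(1), 32)
  expect_equal(encExpected(0.5), 60.5)
  s <- seq(0, 1, by = 0.001)
  expect_lt(abs(s[which.max(encExpected(s))] - 0.5), 0.01)
  expect_error(encExpected(1.2), "\\[0, 1\\]")
})

test_that("expected codon usage from nucleotide content renormalizes over the
          family", {
  uni <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  expect_equal(unname(expectedCodonUsageFromNt("G", uni, CODE)), rep(0.25, 4))
  atOnly <- c(A = 0.5, C = 0, G = 0, T = 0.5)
  lys <- expectedCodonUsageFromNt("K", atOnly, CODE)
  expect_equal(unname(lys[c("AAA", "AAG")]), c(1, 0))
  f <- c(A = 0.4, C = 0.1, G = 0.1, T = 0.4)
  gly <- expectedCodonUsageFromNt("G", f, CODE)
  expect_equal(unname(gly[c("GGA", "GGT", "GGG", "GGC")]),
               c(0.4, 0.4, 0.1, 0.1))
  zero <- c(A = 0, C = 0, G = 0, T = 0)
  expect_true(all(is.na(expectedCodonUsageFromNt("K", zero, CODE))))
})

test_that("amino-acid usage and FYMINK/GARP fractions match a recount", {
  fymink <- countCodons("TTTTATATGATTAATAAA", CODE)  # F Y M I N K
  u <- aaUsage(fymink, CODE)
  expect_equal(u$fyminkFrac, 1)
  expect_equal(u$garpFrac, 0)
  garp <- countCodons("GGAGCACGACCA", CODE)          # G A R P
  expect_equal(aaUsage(garp, CODE)$garpFrac, 1)

  set.seed(9)
  counts <- randomCountVector()
  u2 <- aaUsage(foramCodon:::.countTableFromVector(counts, CODE), CODE)
  brute <- vapply(CODE@aaToCodons, function(cs) sum(counts[cs]), numeric(1))
  expect_equal(u2$freqs, brute / sum(brute))
  expect_equal(sum(u2$freqs), 1)
  expect_lte(u2$fyminkFrac + u2$garpFrac, 1)

  empty <- foramCodon:::.countTableFromVector(
    setNames(rep(0, 61), CODE@senseCodons), CODE)
  expect_true(is.na(aaUsage(empty, CODE)$fyminkFrac))
})

test_that("hypothetical GC12 under equal codon usage is linear in the
          amino-acid mix", {
  f0 <- setNames(rep(0, 20), names(CODE@aaToCodons))
  fG <- f0; fG["G"] <- 1
  expect_equal(hypotheticalGc12(fG, CODE), 1)   # glycine GGN
  fK <- f0; fK["K"] <- 1
  expect_equal(hypotheticalGc12(fK, CODE), 0)   # lysine AAA/AAG
  fMix <- f0; fMix["G"] <- 0.5; fMix["K"] <- 0.5
  expect_equal(hypotheticalGc12(fMix, CODE), 0.5)
})

test_that("stop usage frequencies are recovered from counts and simulation", {
  seqs <- c("ATGAAATAA", "ATGAAATAA", "ATGAAATGA")
  su <- stopUsage(countCodons(seqs, CODE))
  expect_equal(unname(su), c(2 / 3, 0, 1 / 3))
  allTag <- stopUsage(countCodons("ATGTAG", CODE))
  expect_equal(unname(allTag), c(0, 1, 0))
  expect_true(all(is.na(stopUsage(countCodons("ATGAAA", CODE)))))

  ## generator stop weights recovered within 3 sigma binomial
  set.seed(10)
  w <- c(TAA = 0.6, TAG = 0.1, TGA = 0.3)
  tx <- taxonConfig("st", nTranscripts = 2000, lengthMeanLog = log(12),
                    stopWeights = w)
  sim <- simulateTranscriptome(simulationConfig(taxa = list(tx)), seed = 10)
  su2 <- stopUsage(countCodons(as.character(cds(sim$records)), CODE))
  sig <- sqrt(w * (1 - w) / 2000)
  expect_true(all(abs(su2 - w) < 3 * sig + 1e-9))
})
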