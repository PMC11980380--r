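test_that("generation is fully deterministic given a seed", {
  cfg <- simulationConfig(taxa = list(
    taxonConfig("d1", gc4Target = 0.2, nTranscripts = 40)),
    contamination = list(list(donorCell = "d1", recipientCell = "d1",
                              nSeqs = 0, coverageRatio = 1)))
  cfg$contamination <- list()
  a <- simulateTranscriptome(cfg, seed = 99)
  b <- simulateTranscriptome(cfg, seed = 99)
  expect_identical(as.character(cds(a$records)), as.character(cds(b$records)))
  expect_identical(transcriptData(a$records), transcriptData(b$records))
  expect_identical(a$truth, b$truth)
  ## and byte-identical on disk
  d1 <- tempfile(); d2 <- tempfile()
  writeDataset(a$records, d1); writeDataset(b$records, d2)
  expect_identical(readLines(file.path(d1, "cds.fasta")),
                   readLines(file.path(d2, "cds.fasta")))
})

test_that("silent-site composition converges to the target distribution", {
  set.seed(29)
  target <- 0.05
  tx <- taxonConfig("gc", gc4Target = target, nTranscripts = 300)
  sim <- simulateTranscriptome(simulationConfig(taxa = list(tx)), seed = 29)
  seqs <- as.character(cds(sim$records))
  ## spec-level recovery: median GC4 within the binomial band
  medGc4 <- median(gc4(seqs, CODE), na.rm = TRUE)
  expect_true(medGc4 > 0.03 && medGc4 < 0.07)

  ## larger run: fourfold third-position nucleotide frequencies approach the
  ## generating distribution
  tx2 <- taxonConfig("gc2", gc4Target = 0.3, nTranscripts = 700)
  sim2 <- simulateTranscriptome(simulationConfig(taxa = list(tx2)), seed = 30)
  nts <- silentThirdNucleotides(as.character(cds(sim2$records)), CODE,
                                "fourfold")
  emp <- table(factor(nts, levels = c("A", "C", "G", "T"))) / length(nts)
  expect_gt(length(nts), 5e4)
  expect_lt(max(abs(as.numeric(emp) -
                    silentNtDistribution(0.3)[c("A", "C", "G", "T")])), 0.01)
})

test_that("amino-acid usage is conserved across taxa with divergent silent
          bias", {
  set.seed(31)
  sim <- simulateTranscriptome(simulationConfig(taxa = list(
    taxonConfig("at", gc4Target = 0.03, nTranscripts = 250),
    taxonConfig("gc", gc4Target = 0.72, nTranscripts = 250))), seed = 31)
  cells <- splitByCell(sim$records)
  f <- lapply(cells, function(ts)
    aaUsage(countCodons(as.character(cds(ts)), CODE), CODE)$freqs)
  total <- sum(countCodons(as.character(cds(sim$records)), CODE)@counts)
  expect_gt(total, 1e5)
  expect_lt(max(abs(f[[1]] - f[[2]])), 0.02)
})

test_that("without selection the GC4-expression slope is null; with
          selection designated codons respond in sign", {
  set.seed(32)
  sig <- replicate(12, {
    tx <- taxonConfig("s0", gc4Target = 0.3, nTranscripts = 120,
                      lengthMeanLog = log(150))
    sim <- simulateTranscriptome(simulationConfig(taxa = list(tx)))
    td <- transcriptData(sim$records)
    tpmv <- tpm(td$readCount, nchar(as.character(cds(sim$records))))
    metricVsLogTpm(gc4(as.character(cds(sim$records)), CODE), tpmv)$pValue
  })
  expect_gte(mean(sig > 0.05), 0.75)   # mostly non-significant under s=0

  ## selection tied to expression: optimal-codon frequency rises with TPM
  tx <- taxonConfig("s1", gc4Target = 0.3, nTranscripts = 200,
                    selectionStrength = 1)
  sim <- simulateTranscriptome(simulationConfig(taxa = list(tx)), seed = 33)
  seqs <- as.character(cds(sim$records))
  td <- transcriptData(sim$records)
  tpmv <- tpm(td$readCount, nchar(seqs))
  opt <- foramCodon:::.defaultOptimalCodons(CODE)
  M <- foramCodon:::.codonCountMatrix(seqs, CODE)
  lysTot <- M["AAA", ] + M["AAG", ]
  fOpt <- ifelse(lysTot > 0, M[opt[["K"]], ] / lysTot, NA)
  rOpt <- metricVsLogTpm(fOpt, tpmv)
  expect_gt(rOpt$slope, 0)
  other <- setdiff(c("AAA", "AAG"), opt[["K"]])
  rSyn <- metricVsLogTpm(ifelse(lysTot > 0, M[other, ] / lysTot, NA), tpmv)
  expect_lt(rSyn$slope, 0)
})

test_that("contaminant injection plants near-identical low-coverage copies
          and flags truth", {
  set.seed(34)
  sim <- simulateTranscriptome(
    simulationConfig(
      taxa = list(taxonConfig("don", gc4Target = 0.2, nTranscripts = 40),
                  taxonConfig("rec", gc4Target = 0.2, nTranscripts = 40)),
      contamination = list(list(donorCell = "don", recipientCell = "rec",
                                nSeqs = 5, coverageRatio = 0.05))),
    seed = 34)
  td <- transcriptData(sim$records)
  planted <- sim$truth$transcriptId[sim$truth$contaminant]
  expect_equal(length(planted), 5L)
  expect_true(all(td$cellId[match(planted, td$transcriptId)] == "rec"))
  for (p in planted) {
    donorId <- sub("_xc_rec$", "", p)
    a <- as.character(cds(sim$records)[[p]])
    b <- as.character(cds(sim$records)[[donorId]])
    expect_equal(nchar(a), nchar(b))
    idy <- mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
    expect_gte(idy, 0.99)
    ## amino-acid sequence unchanged (synonymous substitutions only)
    expect_identical(unname(CODE@codonToAa[oracleCodons(a)]),
                     unname(CODE@codonToAa[oracleCodons(b)]))
    covRatio <- td$kmerCoverage[td$transcriptId == p] /
      td$kmerCoverage[td$transcriptId == donorId]
    expect_equal(covRatio, 0.05, tolerance = 1e-9)
  }
  expect_error(injectContamination(sim, list(list(
    donorCell = "don", recipientCell = "rec", nSeqs = 1,
    coverageRatio = 0))), "positive")
})

test_that("curation recovers planted contaminants and raises no false
          alarms on clean data", {
  set.seed(35)
  ## the planted scenario: donor partners well above 20x coverage, copies at
  ## ratio 0.05 (hence under the coverage-10 gate)
  sim <- simulateTranscriptome(
    simulationConfig(
      taxa = list(taxonConfig("don", gc4Target = 0.25, nTranscripts = 60,
                              coverageMeanLog = log(60),
                              coverageSdLog = 0.3),
                  taxonConfig("rec", gc4Target = 0.25, nTranscripts = 60,
                              coverageMeanLog = log(60),
                              coverageSdLog = 0.3)),
      contamination = list(list(donorCell = "don", recipientCell = "rec",
                                nSeqs = 5, coverageRatio = 0.05))),
    seed = 35)
  planted <- sim$truth$transcriptId[sim$truth$contaminant]
  d <- flagCrossContaminants(sim$records)
  expect_true(all(planted %in% d$transcriptId))     # full recall
  expect_true(all(d$transcriptId %in% planted))     # no false positives

  ## a planted pair at ~98% identity is below the gate
  base <- randomCds(100, pool = CODE@fourfoldThirdSet)
  flip <- function(s, idx) {
    m <- c(A = "T", T = "A", G = "C", C = "G")
    for (i in idx) substr(s, 3 * i, 3 * i) <- m[[substr(s, 3 * i, 3 * i)]]
    s
  }
  ts <- TranscriptSet(c(d1 = base, r0 = randomCds(100), r1 = flip(base, seq(7, 98, by = 13))),
                      cellId = c("don", "rec", "rec"), geneFamilyId = "gfx",
                      kmerCoverage = c(60, 50, 3))
  expect_equal(nrow(flagCrossContaminants(ts)), 0L)

  ## clean replicates: zero cross-contaminant flags
  for (r in 1:5) {
    simC <- simulateTranscriptome(
      simulationConfig(taxa = list(
        taxonConfig("c1", gc4Target = 0.1, nTranscripts = 50),
        taxonConfig("c2", gc4Target = 0.1, nTranscripts = 50))),
      seed = 100 + r)
    expect_equal(nrow(flagCrossContaminants(simC$records)), 0L)
  }
})
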