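## Small constructed sets exercising each rule at its thresholds, plus the
## shipped 14-sequence fixture checked against a hand-derived survivor set
## and an independent re-derivation of the rules.

fixtureDir <- system.file("extdata", "curation", package = "foramCodon")

makeSet <- function(seqs, cell, fam, cov) {
  TranscriptSet(seqs, cellId = cell, geneFamilyId = fam, kmerCoverage = cov)
}

## deterministic synonymous copies: flip third positions of fourfold codons
synCopy <- function(seq, codonIdx) {
  flip <- c(A = "T", T = "A", G = "C", C = "G")
  for (i in codonIdx) {
    p <- 3 * i
    substr(seq, p, p) <- flip[[substr(seq, p, p)]]
  }
  seq
}

test_that("cross-contaminant coverage rules fire exactly at their
          thresholds", {
  set.seed(18)
  base <- randomCds(100, pool = CODE@fourfoldThirdSet)
  partner <- randomCds(100, pool = CODE@fourfoldThirdSet)
  copy <- synCopy(base, c(20, 70))                   # 99.3% identical
  ## X in cell B, cov 5, 99%+ identical to A's seq; same-cell partner cov 25
  ts <- makeSet(c(a1 = base, b1 = partner, bX = copy),
                cell = c("A", "B", "B"), fam = "gf1", cov = c(50, 25, 5))
  d <- flagCrossContaminants(ts)
  expect_equal(d$transcriptId, "bX")
  expect_equal(d$ruleId, "xcontam_10_20")

  ## cov 15 with partner cov 50: 15 < 20 but partner <= 100 -> kept
  ts2 <- makeSet(c(a1 = base, b1 = partner, bX = copy),
                 cell = c("A", "B", "B"), fam = "gf1", cov = c(50, 50, 15))
  expect_equal(nrow(flagCrossContaminants(ts2)), 0L)

  ## same but partner cov 150 -> xcontam_20_100
  ts3 <- makeSet(c(a1 = base, b1 = partner, bX = copy),
                 cell = c("A", "B", "B"), fam = "gf1", cov = c(50, 150, 15))
  d3 <- flagCrossContaminants(ts3)
  expect_equal(d3$ruleId, "xcontam_20_100")

  ## a pair at ~98% identity never qualifies
  far <- synCopy(base, seq(10, 100, by = 15))        # 7 subs ~ 97.7%
  ts4 <- makeSet(c(a1 = base, b1 = partner, bX = far),
                 cell = c("A", "B", "B"), fam = "gf1", cov = c(50, 25, 5))
  expect_equal(nrow(flagCrossContaminants(ts4)), 0L)

  ## missing coverage: candidate skipped
  ts5 <- makeSet(c(a1 = base, b1 = partner, bX = copy),
                 cell = c("A", "B", "B"), fam = "gf1", cov = c(50, 25, NA))
  expect_equal(nrow(flagCrossContaminants(ts5)), 0L)
})

test_that("within-cell dedup removes the lower-coverage member on either
          gate", {
  set.seed(19)
  base <- randomCds(100, pool = CODE@fourfoldThirdSet)
  near <- synCopy(base, seq(12, 96, by = 12))        # 8 subs ~ 97.3%
  ts <- makeSet(c(p = base, q = near), cell = "A", fam = "gf1", cov = c(80, 8))
  d <- dedupWithinCell(ts)
  expect_equal(d$transcriptId, "q")
  expect_equal(d$ruleId, "samecell_dup")

  ## 60 bp planted exact run, low overall identity
  other <- paste0(substr(base, 1, 60),
                  randomCds(80, pool = CODE@fourfoldThirdSet))
  ts2 <- makeSet(c(p = base, r = other), cell = "A", fam = "gf1",
                 cov = c(80, 8))
  d2 <- dedupWithinCell(ts2)
  expect_equal(d2$transcriptId, "r")

  ## low identity and max shared run 30 bp: kept
  short <- paste0(substr(base, 1, 30),
                  randomCds(90, pool = CODE@fourfoldThirdSet))
  ts3 <- makeSet(c(p = base, s = short), cell = "A", fam = "gf1",
                 cov = c(80, 8))
  expect_equal(nrow(dedupWithinCell(ts3)), 0L)

  ## tied coverage: the shorter sequence is removed
  shorter <- substr(base, 1, 294)
  ts4 <- makeSet(c(p = base, q = shorter), cell = "A", fam = "gf1",
                 cov = c(10, 10))
  d4 <- dedupWithinCell(ts4)
  expect_equal(d4$transcriptId, "q")
})

test_that("structural filters apply the published length and gap fractions", {
  set.seed(20)
  long1 <- randomCds(200); long2 <- randomCds(200)
  tiny <- randomCds(20)                              # 60 nt
  ## family mean (600 + 600 + 60)/3 = 420; 60 < 0.25 * 420
  ts <- makeSet(c(f1 = long1, f2 = long2, f3 = tiny),
                cell = c("A", "B", "C"), fam = "gf1", cov = c(10, 10, 10))
  d <- structuralFilters(ts)
  expect_equal(d$transcriptId, "f3")
  expect_equal(d$ruleId, "short_25pct")

  ## same-cell paralog under half the family mean
  mid <- randomCds(50)                               # 150 nt
  ts2 <- makeSet(c(f1 = long1, f2 = long2, f4 = mid),
                 cell = c("A", "B", "A"), fam = "gf1", cov = c(10, 10, 10))
  d2 <- structuralFilters(ts2)
  expect_equal(d2$transcriptId, "f4")
  expect_equal(d2$ruleId, "paralog_50pct")

  ## gap rule from the alignment: >= 30% gap columns
  aln <- list(gf1 = c(g1 = paste0(long1, strrep("-", 0)),
                      g2 = paste0(substr(long1, 1, 390), strrep("-", 210))))
  ts3 <- makeSet(c(g1 = long1, g2 = substr(long1, 1, 390)),
                 cell = c("A", "B"), fam = "gf1", cov = c(10, 10))
  d3 <- structuralFilters(ts3, alignments = aln)
  expect_true("gap_30pct" %in% d3$ruleId)
  expect_true("g2" %in% d3$transcriptId[d3$ruleId == "gap_30pct"])
})

test_that("composition outliers are removed only with low coverage or a
          better paralog, and tiny cells are skipped", {
  set.seed(21)
  ## a GC-balanced cell with one extreme-GC3S, low-coverage transcript
  normal <- replicate(30, randomCds(120))
  outlier <- paste(rep("AAA", 120), collapse = "")    # GC3S = 0
  seqs <- c(setNames(normal, sprintf("n%02d", 1:30)), out1 = outlier)
  ts <- makeSet(seqs, cell = "A", fam = sprintf("gf%d", c(1:30, 1)),
                cov = c(rep(50, 30), 4))
  d <- suppressMessages(compositionOutlierFilter(ts, CODE))
  expect_true("out1" %in% d$transcriptId)
  expect_equal(unique(d$ruleId), "composition_outlier")

  ## same outlier with high coverage and no paralog: kept
  ts2 <- makeSet(seqs, cell = "A", fam = sprintf("gf%d", c(1:30, 31)),
                 cov = c(rep(50, 30), 80))
  expect_false("out1" %in%
    suppressMessages(compositionOutlierFilter(ts2, CODE))$transcriptId)

  ## high coverage but a non-outlying same-family paralog with higher
  ## coverage: removed
  ts3 <- makeSet(seqs, cell = "A", fam = sprintf("gf%d", c(1:30, 1)),
                 cov = c(100, rep(50, 29), 80))
  expect_true("out1" %in%
    suppressMessages(compositionOutlierFilter(ts3, CODE))$transcriptId)

  ## fewer than 20 transcripts: rule skipped with a message
  small <- ts[1:10]
  expect_message(compositionOutlierFilter(small, CODE), "skipped")

  ## all transcripts within 1 z unit: nothing removed
  ts4 <- makeSet(setNames(normal, sprintf("n%02d", 1:30)), cell = "A",
                 fam = sprintf("gf%d", 1:30), cov = rep(50, 30))
  expect_equal(nrow(suppressMessages(compositionOutlierFilter(ts4, CODE))), 0L)
})

test_that("UTR eligibility applies length gates and alignment anchors", {
  set.seed(22)
  s1 <- paste0("ATG", randomCds(59)); s2 <- paste0("ATG", randomCds(59))
  aln <- list(gf1 = c(m1 = s1, m2 = s2))   # both rows start with ATG
  ts <- TranscriptSet(c(m1 = s1, m2 = s2), cellId = c("A", "B"),
                      geneFamilyId = "gf1",
                      utr5 = c(strrep("A", 40),     # too short (<= 50)
                               strrep("A", 120)),
                      utr3 = c(NA, strrep("T", 600)))  # too long (>= 500)
  el <- curateUtrs(ts, alignments = aln)
  expect_equal(el$utr5Status, c("ineligible", "eligible"))
  expect_match(el$utr5Rule[1], "length")
  expect_equal(el$utr3Status, c("absent", "ineligible"))

  ## 5' anchor: no other row has ATG at the start columns
  noMet <- sub("^ATG", "GGG", s2)
  aln2 <- list(gf1 = c(m1 = s1, m2 = noMet))
  ts2 <- TranscriptSet(c(m1 = s1, m2 = noMet), cellId = c("A", "B"),
                       geneFamilyId = "gf1",
                       utr5 = c(strrep("A", 120), NA))
  el2 <- curateUtrs(ts2, alignments = aln2)
  expect_equal(el2$utr5Status[1], "ineligible")
  expect_match(el2$utr5Rule[1], "anchor")

  ## 3' anchor: another row must hold a stop in the same columns
  withStop <- paste0(s1, "TAA"); mateStop <- paste0(s2, "TGA")
  aln3 <- list(gf1 = c(w1 = withStop, w2 = mateStop))
  ts3 <- TranscriptSet(c(w1 = withStop, w2 = mateStop),
                       cellId = c("A", "B"), geneFamilyId = "gf1",
                       utr3 = c(strrep("T", 200), NA))
  expect_equal(curateUtrs(ts3, alignments = aln3)$utr3Status[1], "eligible")
  ## replace the mate's stop with a sense codon: anchor fails
  aln4 <- list(gf1 = c(w1 = withStop, w2 = paste0(s2, "GGG")))
  expect_equal(curateUtrs(ts3, alignments = aln4)$utr3Status[1],
               "ineligible")
})

test_that("the shipped 14-sequence fixture is curated to the hand-derived
          survivor set, matching a direct rule evaluation", {
  ld <- loadDataset(file.path(fixtureDir, "cds.fasta"),
                    coverageTsv = file.path(fixtureDir, "coverage.tsv"),
                    taxonMapTsv = file.path(fixtureDir, "taxon_map.tsv"),
                    alignmentsDir = file.path(fixtureDir, "alignments"))
  expect_equal(length(ld$records), 14L)
  cur <- suppressMessages(curateTranscripts(ld$records, ld$alignments, CODE))

  survivors <- sort(transcriptData(cur$records)$transcriptId)
  expect_equal(survivors, c("A1", "B1", "B3", "C1", "C2", "D1", "E2"))
  rules <- setNames(cur$decisions$ruleId, cur$decisions$transcriptId)
  expect_equal(rules[["B2"]], "xcontam_10_20")
  expect_equal(rules[["A2"]], "samecell_dup")
  expect_equal(rules[["A3"]], "samecell_dup")
  expect_equal(rules[["C3"]], "short_25pct")
  expect_equal(rules[["C4"]], "paralog_50pct")
  expect_equal(rules[["D2"]], "best_paralog")
  expect_equal(rules[["E1"]], "gap_30pct")
  ## the curation log names exactly the removed transcripts
  expect_equal(sort(cur$decisions$transcriptId),
               sort(setdiff(transcriptData(ld$records)$transcriptId,
                            survivors)))

  ## independent re-derivation from raw identities and thresholds
  td <- transcriptData(ld$records)
  seqs <- setNames(as.character(cds(ld$records)), td$transcriptId)
  ident <- function(a, b) {
    x <- strsplit(seqs[[a]], "")[[1]]; y <- strsplit(seqs[[b]], "")[[1]]
    n <- min(length(x), length(y))
    mean(x[1:n] == y[1:n])   # fixture alignments are gapless and flush
  }
  cov <- setNames(td$kmerCoverage, td$transcriptId)
  ## B2 is the only sequence with coverage < 10 that is >= 99% identical to
  ## a cross-cell sequence and has a same-cell partner above 20
  expect_gte(ident("B2", "A1"), 0.99)
  expect_lt(cov[["B2"]], 10); expect_gt(cov[["B1"]], 20)
  ## B3 fails the second gate: partner coverage not above 100
  expect_gte(ident("B3", "A1"), 0.99)
  expect_lt(cov[["B3"]], 20); expect_lte(cov[["B1"]], 100)
  ## A2 over the 95% dedup gate; A3 shares a 60 bp run with A1
  expect_gt(ident("A2", "A1"), 0.95)
  expect_equal(substr(seqs[["A3"]], 1, 60), substr(seqs[["A1"]], 1, 60))
  expect_lt(ident("A3", "A1"), 0.95)
  ## structural numbers: family gf2 mean length and the two fractions
  gf2 <- td$transcriptId[td$geneFamilyId == "gf2"]
  mLen <- mean(nchar(seqs[gf2]))
  expect_lt(nchar(seqs[["C3"]]), 0.25 * mLen)
  expect_lt(nchar(seqs[["C4"]]), 0.50 * mLen)
  expect_gte(nchar(seqs[["C4"]]), 0.25 * mLen)
  ## D pair at exactly the 95% boundary: dedup (strict >) spares it, the
  ## paralog-clade rule (>=) removes the lower-coverage member
  expect_equal(ident("D1", "D2"), 0.95)
  expect_gt(cov[["D1"]], cov[["D2"]])

  ## idempotence: curating the survivors again removes nothing
  again <- suppressMessages(
    curateTranscripts(cur$records, ld$alignments, CODE))
  expect_equal(nrow(again$decisions), 0L)
  expect_equal(sort(transcriptData(again$records)$transcriptId), survivors)
})
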