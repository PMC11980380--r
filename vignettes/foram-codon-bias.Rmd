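---
title: "Methods: composition, codon usage and silent-site dinucleotide bias in foramCodon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composition, codon usage and silent-site dinucleotide bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`foramCodon` implements the statistics needed to characterize nucleotide,
codon, and amino-acid usage in curated single-cell transcriptomes of
organisms with extreme and heterogeneous silent-site composition, of which
foraminifera are the motivating case. This vignette documents the models and
procedures, the tunable parameters and their defaults, the numerical
choices, what the synthetic-data generator does and does not emulate, and
the design decisions taken where the methodology was genuinely open.

# The genetic-code machinery

All statistics are derived from the standard nuclear code (61 sense codons,
3 stops). `standardGeneticCode()` derives every degeneracy structure by
brute-force substitution: the synonymous nucleotide set of a codon position
is the set of nucleotides that preserves the amino acid with the other two
positions held fixed, and a substitution creating a stop never counts as
synonymous. Two consequences worth stating:

* position 2 is always onefold; position 1 is twofold only in the split
  boxes of leucine (TTR/CTR) and arginine (CGR/AGR); position 3 carries the
  classes onefold (ATG, TGG), twofold (24 codons), threefold (isoleucine),
  and fourfold (32 codons: the eight four-codon boxes, including the
  fourfold halves of Leu, Ser, Arg).
* the sixfold amino acids (Leu, Ser, Arg) are handled per codon box for
  degeneracy purposes, but form their own class (weight 3) in Wright's ENc.

Only the standard code ships; organisms using reassigned stop codons are out
of scope.

# Composition metrics

* **GC4** is computed over third positions of strictly fourfold codons.
  Threefold isoleucine sites are excluded — a definitional choice; including
  them would mix a site class whose allowed set is asymmetric (A/C/T).
* **GC3S** uses all sense codons except ATG and TGG (59 codons).
* **GC12** covers positions 1–2 of all sense codons.
* A terminal stop codon is recorded for stop-usage analysis but excluded
  from every composition and codon statistic; trailing partial codons are
  dropped; any codon containing N is excluded from all counts, and
  transcripts with more than 10% N are rejected at load time (a conservative
  policy; the thresholds live in `loadDataset(maxNFrac=)`).
* Per-taxon summaries are medians over transcripts (means are also emitted,
  since some cross-taxon regressions use means).
* The positional GC3S profile uses a default window of 50 codons from each
  CDS end; the value is a reporting choice, not a fitted constant.
* Bias categories cut median GC4 at 0.15 / 0.40 / 0.60. The underlying
  empirical distribution has gaps near these cuts; the package applies the
  boundaries deterministically (< 0.15 AT-biased, < 0.40 intermediate,
  ≤ 0.60 non-biased, else GC-biased; NA gives "unclassified").

# Wright's effective number of codons

Per amino-acid family, codon homozygosity is estimated as
F̂ = (n·Σp̂ᵢ² − 1)/(n − 1) with n the family total. ENc sums class averages:
ENc = 2 + 9/F̄₂ + 1/F̄₃ + 5/F̄₄ + 3/F̄₆, capped at 61. Missing-data rules
follow Wright's prescription: families with n < 2 (or F̂ ≤ 0, which occurs at
small n) are dropped from their class mean; a missing threefold mean
(isoleucine unused) is replaced by (F̄₂ + F̄₄)/2; if the twofold, fourfold or
sixfold mean cannot be estimated, ENc is NA for that scope. ENc is computed
both per cell (pooled counts) and per transcript; per-transcript values
require `minEncCodons` (default 100) analyzable codons because homozygosity
estimates on short genes are unstable. The composition-only null curve is
ENc\*(s) = 2 + s + 29/(s² + (1 − s)²), evaluated on GC3S; its endpoints are
31 (s = 0) and 32 (s = 1) and its maximum sits at 60.5 near s = 0.5.

# SSDU: site-specific synonymous dinucleotide usage

SSDU asks whether a dinucleotide is over- or under-used at a specific codon
frame position once the amino-acid sequence and position-specific
mononucleotide content are controlled. The three frame positions are pos1
(codon positions 1–2), pos2 (positions 2–3) and bridge (position 3 with the
next codon's position 1; bridges never span transcripts, and the pair into a
terminal stop is excluded).

**The null.** Single-nucleotide frequencies are estimated per stratum
(codon position, degeneracy class of that position) — in the standard code
the occupied strata are (1,1), (1,2), (2,1) and (3,1)…(3,4). The null
probability of a codon given its amino acid is the product over positions of
the stratum frequency of its nucleotide, normalized over the synonymous
family. Two details:

* *Normalization is at the family level, not per position.* For every family
  whose synonyms vary at a single position the two conventions coincide; for
  the sixfold families they differ, and only family-level normalization has
  the property that uniform strata reduce the null to equal usage (1/k per
  synonym), which is what makes SSDU degenerate exactly to the original
  equal-usage synonymous dinucleotide usage statistic under a flat null.
  The package treats that degeneracy as definitional.
* A family whose weights sum to zero under a sparse stratum estimate falls
  back to equal usage; an empty stratum falls back to the pooled frequency
  of its codon position. Both fallbacks are recorded on the returned
  objects.

**The estimator.** For dinucleotide h at frame position p, groups g are
amino acids (pos1/pos2) or ordered amino-acid pairs (bridge; adjacent codons
independent under the null, since a single-nucleotide null has no pair
coupling). With o_g the observed proportion of group occurrences carrying h
at p and e_g its null probability,

SSDU(h, p) = Σ_g n_g (o_g / e_g) / Σ_g n_g

over informative groups (0 < e_g < 1). Groups observed fewer than
`minGroupCount` times (default 10) are dropped: o/e ratios explode at tiny
n. The statistic is 1 in expectation under the null and is reported both as
a ratio and as log2 for heat maps.

**Calibration and a caveat on re-estimated frequencies.** When codons are
drawn from the stratified null and SSDU is evaluated *against that null's
frequencies*, the mean over dinucleotide-by-position cells is 1 within Monte
Carlo error at every composition (this is asserted in the test suite at
1e5 codons, mean within [0.98, 1.02]). When the stratum frequencies are
instead re-estimated from the analyzed data — the only option on real data —
calibration is exact for every group whose synonymous variation is confined
to one stratum with an amino-acid-specific allowed set (all twofold,
threefold and fourfold families at position 3), but not for groups whose
variation spans codon positions 1–2: the (1,1) and (1,2) strata pool sites
from many amino acids, so the restricted ratios a split-box family (Leu,
Ser, Arg) would need are contaminated by the others. On data generated from
a flat silent distribution this shifts the affected cells (a handful of
pos1 cells and the sixfold contributions to pos2/bridge cells) by amounts
that grow with compositional extremity. Interpretation guidance: treat SSDU
values for dinucleotides hosted only by Leu/Ser/Arg box choices with
caution, and prefer comparisons of the same cell across taxa, where the
distortion is shared.

# Expression-linked statistics

* TPM uses raw transcript lengths, not effective lengths, to avoid
  distorting short sequences; it sums to 10⁶ per cell by construction.
* All slopes come from ordinary least squares; significance comes from the
  Spearman rank correlation (robust to the heavy-tailed metrics involved),
  with Benjamini–Hochberg correction batched the way each analysis is read:
  per cell across the 59 multi-codon family frequencies for
  codon-versus-expression slopes, and across cells within each subset for
  neutrality plots. Labels "significantly positive/negative" use q < 0.05.
* log base 10 is used for TPM; transcripts with TPM = 0 are excluded from
  log regressions rather than pseudocounted.
* Expression deciles rank with ties sharing the lower bin (deterministic
  under heavy zero-ties); derived masks expose the bottom/top one and two
  deciles. Neutrality plots (GC12 on GC4) are fitted on all transcripts and
  on the bottom and top decile; cross-taxon amino-acid slopes (frequency on
  mean GC4, per amino acid) are fitted separately on bottom-two and top-two
  decile gene sets and require at least 5 taxa.

# Curation battery

Rules run in a fixed order — cross-contamination, within-cell
deduplication, structural filters, composition outliers, UTR eligibility —
each on the survivors of the previous stage; the battery is idempotent.
Thresholds (all overridable via `curationParams()`): cross-cell pairs at
≥ 99% nucleotide identity with coverage < 10 against a same-cell partner
> 20, or < 20 against > 100; same-cell pairs > 95% identity or sharing a
50 bp exact run (lower coverage loses; ties: shorter sequence, then
lexicographically later id); transcripts < 25% and same-cell paralogs < 50%
of the gene-family mean ungapped length; paralog clades approximated as
connected components of same-cell pairs ≥ 95% identical, keeping the
highest-coverage member; alignment rows with ≥ 30% gaps; joint GC3S–ENc
outliers (|robust z| > 3 on median/MAD, per cell, skipped under 20
transcripts) removed when coverage < 10 or a non-outlying same-cell paralog
with higher coverage exists; 5′/3′ UTRs eligible when strictly between 50
and 500 bp with a start-methionine (respectively stop-codon) anchor shared
with another alignment row.

Design decisions behind those rules: pairwise identity is taken from shared
non-gap columns of the gene-family alignment when one is supplied, and from
a global pairwise alignment (after a shared-k-mer prescreen) otherwise; the
50 bp exact-run test is a shared 50-mer on unaligned sequences; "clade
average" is interpreted as the per-family mean ungapped length (gene trees
are out of scope, and at this granularity the family is the clade); the
robust-z outlier rule is a reproducible stand-in for manual inspection of
GC3S–ENc scatter; ≥ is used for the 30% gap rule and nucleotide identity for
the 99% gate where the published procedure leaves both unstated.

# The synthetic-transcriptome generator

The generator exists so that every stage is testable end-to-end and so that
parameter-recovery claims are checkable against known truth. Per taxon it
draws amino acids i.i.d. from a shared profile (enriched Leu/Lys/Ile,
depleted M/H/C/W — normalized, realistic for broad eukaryote proteomes),
codons from the taxon's silent nucleotide distribution restricted to each
family (the same family-normalized product as the SSDU null), log-normal
lengths (default meanlog log 250 codons, sdlog 0.35) and expression (meanlog
2, sdlog 1.2), multinomial read counts with rates ∝ expression × length
(default 2e5 reads), log-normal k-mer coverage (meanlog log 50, sdlog 1),
i.i.d. UTRs (GC 0.35, within the 25–45% range typical of UTRs), and terminal
stops weighted TAA 0.55 / TAG 0.10 / TGA 0.35 (TAG underweighted, as
observed universally). The silent distribution maps a GC4 target with mild
strand asymmetry (A over T, C over G), giving the positive AT skew and
negative GC skew seen at real silent sites. The default panel spans GC4
targets {0.03, 0.10, 0.25, 0.45, 0.72}, one taxon per bias regime, 300
transcripts each.

Optional regimes:

* **selection** — the optimal codon's weight (default: the most AT-rich
  synonym, ties toward A) is multiplied by exp(s·log₁₀(expression)); this
  exponential tilt is a modeling convenience, not an empirical claim.
  Selection defaults to off so that the baseline panel is a pure
  composition-driven null.
* **boundary enrichment** — silent-site GC within a window at both CDS ends
  is shifted toward GC by a mixing weight; off by default for the same
  reason.
* **neutrality-plot regimes** — "silent-spread" draws a per-transcript GC
  level (uniform on [0.15, 0.85]) applied at third positions only, with
  positions 1–2 (including the Leu/Arg box choice) following the taxon-level
  distribution so that the spread is strictly silent; "all-positions-spread"
  applies the per-transcript level to every position with amino acids
  emergent. These produce neutrality slopes near 0 and near 1 respectively;
  the residual gap below 1 in the all-positions regime is attenuation from
  binomial sampling noise in per-transcript GC4.

Contamination injection copies donor transcripts into a recipient cell with
a small number of synonymous third-position substitutions (rate 0.4%, so
identity stays ≥ 99% and the frame and protein are untouched) and coverage
scaled by the event's ratio.

What the generator does **not** emulate: phylogenetic correlation among
taxa, indels and misassembly beyond coverage-asymmetric duplicates,
dinucleotide-level (context-dependent) mutation, expression-dependent UTR
composition, and genuine paralogy. Passing parameter-recovery tests
therefore demonstrates that the estimators measure what they claim under
the stated model, not that real transcriptomes satisfy that model.

# Problem sizes and numerical choices in the test suite

The shipped tests use sizes chosen to keep statistical resolution while
staying desk-scale: 300–500 transcripts per simulated cell for recovery
checks, 1e5 codons for SSDU calibration, 500 random tables for the ENc
oracle equivalence (agreement to 1e-9), 100 replicates for the
codon-selection sign-recovery check, and 20 replicates per neutrality
regime. Percentages are reported with R's default half-even rounding at two
decimals. Deterministic table output (fixed column order, %.6g floats,
key-sorted rows) makes pipeline reruns byte-identical under a fixed seed.

# Known limitations

* Identity from alignment columns ignores indel placement quality; the
  free-alignment fallback uses PID over alignment length, which penalizes
  length differences — intended for the near-identical pairs the rules
  target, not as a general distance.
* The paralog-clade surrogate (identity components) approximates what a
  gene tree would provide; on deeply duplicated families it can merge
  distinct paralog clades.
* Per-transcript ENc is NA below the length cutoff, so cell medians of ENc
  summarize the longer transcripts.
* The SSDU re-estimation caveat above.
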