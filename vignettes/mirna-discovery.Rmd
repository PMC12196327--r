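---
title: "Discovering and curating miRNAs from small RNA-seq: methods and design"
author: "mirforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and curating miRNAs from small RNA-seq: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the analysis model stage by stage, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and
does not emulate, the numerical choices that had to be made where the
underlying methods are ambiguous, and the known limitations.

# The analysis model

The pipeline reconstructs a small RNA-seq miRNA study end to end:

1. **Preprocess** — 3' adapter trimming, then removal of reads with mean
   Phred quality below 20, reads containing an ambiguous base, and reads
   shorter than 15 nt.
2. **Map** — ungapped alignment to the genome allowing at most one
   mismatch; all loci at the minimum mismatch count are reported and
   reads with more than five best loci are discarded as multi-mappers.
3. **Profile** — the 15–35 nt size distribution of mapped reads broken
   down by 5' base. A miRNA-dominated library shows a 22 nt peak with a
   strong preference for 5' U, the signature of Dicer products loaded
   into Argonaute.
4. **Discover** — read stacks (maximal runs of overlapping same-strand
   alignments with at least five reads) seed candidate precursors; two
   excision windows around the stack's modal read are folded; the
   candidate is trimmed to the inferred mature..star span and evaluated
   against six curation criteria with a three-of-six verdict.
5. **Quantify** — reads are assigned to curated matures by best overlap
   (at least mature length minus 2); shares are percentages of
   miRNA-assigned reads and sum to 100.
6. **Context and clusters** — overlapping precursors are reduced to the
   highest-count representative; each precursor receives exactly one
   genomic context with most-specific-first precedence (pseudogene >
   exonic > intronic > intergenic, overlap of one nucleotide suffices,
   strand-agnostic); precursors within 5 kb chain into clusters,
   reflecting the polycistronic organisation of many insect miRNA genes.
7. **Conservation** — each mature is matched against per-species
   reference catalogs by a deterministic ungapped shift-and-count
   matcher; a miRNA with no match in any catalog is called
   species-specific.
8. **Targets** — putative 3'UTRs are the 1000 nt immediately downstream
   of each annotated gene end (reverse-complemented for minus-strand
   genes); three independent predictors score each seed site and only
   sites positive under all three are consensus calls.

## Secondary structure

Hairpins are folded by Nussinov base-pair maximisation over AU, GC and GU
pairs with a minimum hairpin loop of 3 unpaired bases. This objective is
exactly solvable, self-contained, and its optimum can be verified by
exhaustive enumeration — which the test suite does for sequences up to
16 nt. A thermodynamic backend could be substituted behind the same
`HairpinStructure` contract; only criterion (i)'s thresholds would need
recalibration.

Two consequences of the pair-maximisation objective shaped the design:

* **Degenerate optima.** Many structures attain the maximal pair count.
  The traceback therefore resolves ties *stem-biased*: at every
  subinterval the leftmost base pairs its outermost score-optimal
  partner. A smallest-partner rule — the other natural choice — resolves
  the same optima into branched local hairpins, which misreads genuine
  precursor duplexes as multi-loop structures; the pair count (the
  oracle-checked quantity) is identical either way.
* **Random sequence folds well.** Unconstrained pair maximisation pairs
  most of any random sequence, so a high paired fraction does not by
  itself distinguish a hairpin from background. Both the excision-window
  choice and the star inference therefore look for a *consistent duplex*
  — see below — rather than for raw pairing density.

## Star inference and excision

Given a fold and the mature placement, the star arm is inferred from the
canonical Dicer geometry: the mature's pairing partners on the dominant
arm, filtered to a consistent antiparallel register (position + partner
approximately constant, spread at most 4 to tolerate small bulges), must
cover at least 60% of the mature; the star interval is the partner span
shifted to leave 2 nt 3' overhangs at both duplex ends. The inference
fails — deliberately — when partners scatter over both arms, the register
is inconsistent, or the star would fall outside the precursor.

Excision folds two windows around the modal read (long flank upstream,
70 nt, and long flank downstream; short flank 20 nt). A window whose fold
supports a star inference wins outright; paired fraction, then
terminal-loop count, then the upstream window break remaining ties. When
a star was inferred, the candidate is trimmed to the mature..star span —
the presumptive Drosha/Dicer product — and refolded, so the 60–80 nt
length criterion is evaluated on the precursor proper rather than on the
excision window (an untrimmed window is always about 90 nt longer than
the mature and could never satisfy it).

## The six curation criteria

All thresholds are inclusive at their boundaries.

| criterion | rule | default rationale |
|---|---|---|
| c1 | exactly one terminal loop and paired fraction ≥ 0.45 | quantifies "hairpin-like"; all generator hairpins pass, A/C decoys cannot |
| c2 | precursor length in [60, 80] nt | canonical pre-miRNA length |
| c3 | inferable star with 2–3 nt 3' overhangs, plus ≥ 1 read whose 5' end is within 1 nt of the star 5' end | biogenesis leaves both strands; structure-only evidence does not count |
| c4 | ≥ 70% of stack reads share the modal 5' end | Dicer processing precision |
| c5 | stack read-length histogram peaks in [20, 24] nt | mature miRNA size band |
| c6 | no overlap (≥ 1 nt) with annotated ncRNA or repeat | excludes fragments of other ncRNAs |

The verdict is *kept* iff at least three criteria hold. Unevaluable
criteria (for example c3 without any star-supporting read) count as not
met. The rule is monotone: adding a met criterion can never discard a
kept candidate; the test suite checks all 64 flag assignments.

# Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `minOverlap`, `maxErrRate` (trimming) | 3, 0.1 | nt, fraction | common adapter-trimmer defaults; exact upstream settings are unknowable |
| `minLen`, `minMeanQ` (filtering) | 15, 20 | nt, Phred | standard small-RNA read filters; "low quality" read as mean Phred |
| `k` (mapping seed) | 10 | nt | with first+last seeds, guarantees detection of any ≤1-mismatch locus for reads ≥ 20 nt; a 7-mer fallback extends the guarantee to 15 nt reads |
| `maxHits` | 5 | loci | community norm for miRNA discovery multi-mapper handling |
| `minReads` (stacks) | 5 | reads | low enough for modest expression, high enough to suppress degradation noise |
| `flankLong`, `flankShort` | 70, 20 | nt | a 60–80 nt hairpin around a ~22 nt mature fits either orientation |
| `minCriteria` | 3 | criteria | the three-of-six curation rule |
| `clusterGap` | 5000 | nt | clustering window; gap measured end-to-start, strand-agnostic |
| `utrFlank` | 1000 | nt | downstream-flank 3'UTR approximation under sparse annotation; not truncated at neighbouring genes |
| duplex weights | GC 3, AU 2, GU 1, mismatch −2 | score | relative pair stabilities at integer granularity |
| `p2` threshold | score ≥ 25 and ≤ 1 non-Watson-Crick seed position | score | calibrated so planted full-complement sites pass and shuffled controls rarely do |
| `p3` threshold | ddG ≤ −10 | score | same calibration; ddG = −(duplex score) + pairing score lost by opening the site |
| `accessWindow` | 70 | nt | local folding context around a site |

# The synthetic study

The generator is first-class, tested code; its defaults define the
reference conditions used throughout the tests and the acceptance script:
three 50 kb scaffolds at GC 0.38 with gene models (three exons, two
introns), ncRNAs, repeats and pseudogenes; 40 planted pre-miRNA hairpins
whose contexts follow the 50/38/11/1
intronic/intergenic/exonic/pseudogene split, including one sub-5 kb
cluster of six; 20 decoy loci; and 200,000 reads (180,000 miRNA-derived,
the rest decoy and uniform background) with a 13 nt 3' adapter, 2%
low-quality and 2% N-containing reads.

Per-miRNA counts follow a Zipf law with exponent 1.47, chosen once so
that the analytic rank-1 share over 40 ranks is about 42%, matching the
dominance of the most abundant miRNA in real insect small-RNA libraries.
Mature 5' ends are homogeneous at 0.9, 5' U frequency is 0.9, mature
lengths centre on 22 nt, and one tenth of a miRNA's reads come from the
star arm so that criterion c3 has observable evidence.

Hairpin construction is deliberately conservative: the star is the
reverse complement of the mature (minus the 2 nt overhang) with up to two
mutations kept away from the duplex ends; the loop, the overhang and the
mature's last two bases are drawn from {A, C} so the terminal loop region
cannot pair internally and the overhang cannot pair the mature 5' end;
candidate matures whose precursor does not fold to a single stem-loop, or
whose duplex becomes unreadable when embedded in random flanks, are
redrawn. These rejections model the fact that real miRNA arms sit in
stable, unambiguous hairpins; without them, pair-maximisation folding
misreads self-complementary arms.

Decoys form a falsifiable negative set. Each class violates four
criteria *by construction*, so the three-of-six rule must reject it
regardless of how stochastic evidence (such as a background read
accidentally supporting a star) lands: (a) A/C-only non-hairpin loci
served by heterogeneous-5' reads of off-peak lengths (fails c1, c2, c4,
c5); (b) genuine hairpins with a 12 nt loop, 56 nt total, inside
annotated repeats/ncRNAs (fails c2, c4, c5, c6); (c) 110 nt over-long
hairpins, likewise inside repeats (fails c2, c4, c5, c6).

**What the generator does not emulate:** isomiR biology and RNA editing,
position-dependent sequencing error, ligation biases, repeat families
beyond the annotated features (genome bases are i.i.d., which keeps the
one-mismatch mapper's multi-mapping behaviour predictable), expression
noise beyond multinomial sampling, and degradation fragments with
miRNA-like size profiles. Passing the synthetic acceptance checks
therefore demonstrates the correctness of the machinery under the stated
statistical structure, not performance on real libraries.

# Numerical and procedural choices

* **Coordinates.** All internal positions are 1-based closed on the plus
  strand, the GenomicRanges convention; conversion to 0-based half-open
  happens only at the BED boundary, and GFF3 import/export shifts
  coordinates exactly once.
* **T/U equivalence.** All matching and folding treat T and U as the
  same base; sequences are held in DNA space.
* **Ties.** Stack modal sequences break ties lexicographically; modal
  alignment intervals by frequency then smallest start; overlap removal
  by read count then smallest start; reads assignable to two matures go
  to the larger overlap and are dropped entirely on an exact tie; the
  conservation matcher breaks ties by mismatch count, then smallest
  absolute offset, then first catalog entry.
* **Degenerate inputs.** Empty FASTQ files yield empty read sets; empty
  alignment sets yield all-zero profiles and no stacks; stacks at
  scaffold edges get clipped windows; genes at scaffold edges yield
  shortened UTRs (one record per gene regardless); an empty catalog makes
  every miRNA species-specific.
* **Determinism.** Every stochastic component draws from streams derived
  from one master seed; identical configuration and seed reproduce every
  output file byte for byte, which the tests verify end to end.
* **Problem sizes.** The test suite exercises the full 200,000-read
  reference study once and reuses it across checks; oracle comparisons
  run at sizes where the oracle is exact (folding ≤ 16 nt, mapping on
  10 kb, clustering on hundreds of random fixtures). These sizes are the
  package's validation design: large enough to measure recovery rates,
  small enough that an exact oracle exists.

# Design decisions on genuinely open points

* "Low Phred score (< 20)" is read as *mean* read quality, the common
  read-level interpretation; per-base variants would interact with
  trimming in unspecified ways. Removal reasons are tallied with fixed
  precedence (quality, then N, then length) so reports are deterministic.
* Whether overlap removal keeps one member or drops all overlapping
  miRNAs is ambiguous in the field's phrasing; keeping the
  highest-count representative per connected component preserves the
  most evidence and is resolved greedily by descending count.
* Multi-mapper handling for the size profile keeps each mapped read once
  regardless of its locus count.
* The conservation thresholds (≤ 2 mismatches, or an identical seed with
  ≤ 4) stand in for sequence-similarity searches whose parameters are
  never stated in publications; they encode "similar in full or within
  the seed region" as a deterministic, testable rule.
* The three target predictors are simplified, fully specified stand-ins
  for published binaries; the scientific content retained is the strict
  three-way consensus, so the stand-ins are kept independent in kind:
  pattern (seed class), energy (weighted complementarity), and
  accessibility (opening cost in the local fold).
* No shell entry point is shipped: the exported functions
  (`runPipeline()`, `simulateAndRun()`, the per-stage functions) plus the
  acceptance script are the interface, which suits an R-package audience.

# Known limitations

* Base-pair maximisation over-folds random sequence, so uniformly tiled
  background reads pass the lenient three-of-six rule at a measurable
  rate; on the reference study roughly half of the reported loci are
  background-derived false positives (the recall and decoy metrics, not
  precision, are the acceptance quantities). This mirrors the well-known
  false-positive propensity of hairpin-based discovery and is the main
  motivation for the curation criteria in the first place; an energy
  model and a probabilistic score over star evidence would tighten it.
* The mapper is ungapped by design; indel-bearing reads are lost.
* The UTR model is a fixed downstream flank and ignores real UTR
  annotation, splicing and neighbouring genes.
* Conservation calling is sequence-only: no family (seed-clan)
  reasoning, no phylogenetic weighting.
* GO summarisation is term counting for word-cloud style reporting, not
  an enrichment test.
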