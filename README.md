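# mirforge

Small RNA-seq microRNA discovery, curation and target prediction for insect
genomes — as a fully testable, desk-scale R package.

## The problem

Characterising the miRNA repertoire of a non-model insect from small-RNA
deep sequencing involves a chain of steps that are usually spread over
half a dozen external tools: adapter trimming and read filtering, genome
mapping with at most one mismatch, detection of read stacks, excision and
folding of candidate precursor hairpins, manual curation of the candidates
against biogenesis criteria, quantification of mature miRNA abundance,
genomic-context classification and clustering, conservation calling against
reference catalogs, and seed-based target prediction over putative 3'UTRs.
`mirforge` implements that chain end-to-end in one package, for researchers
who want a reproducible pipeline whose every stage is unit-tested against
independent oracles and validated on synthetic data with known ground
truth.

Because real studies of this kind hinge on large external downloads
(sequencing archives, genome assemblies, miRBase), the package ships a
first-class synthetic-data generator that plants pre-miRNA hairpins — and
decoy loci engineered to fail curation — into simulated genomes, so the
whole analysis can be exercised and scored at desk scale.

## The methods at the core

* **Folding.** Candidate precursors are folded by Nussinov base-pair
  maximisation over Watson–Crick and G:U pairs with minimum hairpin loop 3:
  maximise the score `S(i,j) = max( S(i+1,j), max_k { w(i,k) + S(i+1,k-1) +
  S(k+1,j) } )`. The traceback is deterministic and stem-biased, and
  the optimal pair count is verified in the tests against exhaustive
  enumeration.
* **Mapping.** An ungapped seed-and-extend mapper (first/last k-mer seeds,
  Hamming verification, all best loci at ≤1 mismatch, multi-mappers above 5
  best loci discarded), checked against a naive all-positions scan.
* **Curation.** Six criteria with an inclusive three-of-six verdict:
  (i) hairpin-like fold (one terminal loop, paired fraction ≥ 0.45);
  (ii) precursor length 60–80 nt; (iii) a structure-predicted star with
  2–3 nt 3' overhangs supported by at least one read at the star 5' end;
  (iv) ≥ 70% of reads sharing the modal 5' end; (v) read-length peak in
  20–24 nt; (vi) no overlap with annotated ncRNAs or repeats.
* **Quantification.** Reads are assigned to curated matures by best
  overlap; abundances are reported as counts, reads-per-million, and
  shares that sum to 100%.
* **Context, clusters, conservation, targets.** Precursors are classified
  (pseudogene > exonic > intronic > intergenic), clustered at ≤ 5 kb gaps,
  called known/species-specific by a deterministic shift-and-count matcher
  with a seed-aware branch, and fed into a strict three-predictor consensus
  (seed-class pattern, weighted duplex complementarity, fold-based site
  accessibility) over 1000 nt downstream-flank 3'UTRs.

## Worked example

Fold a hairpin:

```r
library(mirforge)
foldHairpin("TGAGGTAGTAGGTTGTATAGTTAACCAACCACAACTATACAACCTACTACCTCAAA")
#> HairpinStructure of 56 nt: 22 pairs, 1 terminal loop(s), paired fraction 0.79
#>   TGAGGTAGTAGGTTGTATAGTTAACCAACCACAACTATACAACCTACTACCTCAAA
#>   ((((((((((((((((((((((..........)))))))))))))))))))))..)
```

Simulate a small study (two 25 kb scaffolds, 10 planted miRNAs, 6 decoys,
20,000 reads), run the full pipeline on the generated files, and score the
result against the ground truth:

```r
cfg <- simConfig(seed = 5, nScaffolds = 2, scaffoldLen = 25000,
                 nTrueMirnas = 10, nDecoys = 6, nMirnaReads = 16000,
                 nBackgroundReads = 4000, nClustered = 3)
res <- simulateAndRun(cfg, dir = file.path(tempdir(), "demo"))
ev <- res$evaluation
sprintf("recall %.2f | decoy acceptance %.2f | context accuracy %.2f",
        ev$discovery$recall, ev$discovery$decoy_acceptance,
        ev$context$accuracy)
#> "recall 1.00 | decoy acceptance 0.00 | context accuracy 1.00"
sprintf("rank-1 share %.1f%% (analytic %.1f%%)",
        ev$abundance$rank1_share_observed, ev$abundance$rank1_share_analytic)
#> "rank-1 share 49.1% (analytic 49.2%)"
head(res$report$top10, 3)
#>     name read_count     share
#> 1 mir-19       6780 49.066435
#> 2 mir-21       2516 18.208134
#> 3 mir-24       1304  9.436966
```

All ten planted hairpins were recovered, none of the six decoys passed
curation, every recovered precursor was assigned its true genomic context,
and the most abundant miRNA's share of miRNA-assigned reads (49.1%)
reproduces the analytic Zipf expectation for ten ranks at exponent 1.47.
`res$report` additionally holds the preprocessing tallies, the 15–35 nt
size/5'-base profile (peak at 22 nt, U-biased), per-scaffold counts,
cluster calls, conservation results, and consensus target sites; every
table is also written under `res$truth$dir`.

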