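---
title: "Methods: small RNA tag classification and novel miRNA discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA tag classification and novel miRNA discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mircascade)
```

## Overview

mircascade re-implements, as tested reusable components, the analysis used
to characterise a miRNAome from small RNA deep sequencing of melanocytic
libraries. Reads are trimmed and collapsed into counted *unique sequence
tags*; tags seen fewer than twice are discarded as likely sequencing
errors; the remainder are classified by a **subtractive cascade** of
perfect-match alignments — known pre-miRNA precursors first, then the
spliced transcriptome (to remove degraded mRNA), then the genome. Tags that
survive to the genome stage become candidate novel miRNAs if their genomic
neighbourhood can fold into a pre-miRNA hairpin and a stochastic
context-free grammar (SCFG) trained on known hairpins scores them above a
calibrated cutoff. Post-filters remove likely rRNA degradation products,
exon-overlapping matures (more than 2 nt of overhang), and 16-nt matures;
candidates exceeding 5 reads summed across libraries are *named*. Known
precursor tags are further annotated as mature, star or hairpin-region
reads, with isomiR end offsets and mature:star arm ratios. Expression is
summarised as relative proportions (count over total library reads) and
libraries are clustered by average-linkage agglomeration under the Pearson
correlation distance.

Every stage is exercised end-to-end on synthetic data: the package
generates a toy genome with gene models and planted loci whose ground
truth is known, so recovery of planted signal is a measurable property
rather than an anecdote.

## The subtractive cascade

Classification order is fixed: known precursors, transcriptome, genome. A
tag matching an earlier reference never reaches a later one, and tags
matching nothing are set aside ("unmatched") and excluded from all
downstream counts. All alignments are perfect matches — no mismatches, no
indels — which mirrors a deliberately stringent design: sequencing errors
and PCR artefacts are controlled by exactness plus the two-copy rule
rather than by an error model. The aligner is a k-mer seed index
(default k = 12) with full substring verification; since retained tags are
17–27 nt, one seed suffices and verification makes the search exactly
equivalent to a naive scan (a property the test suite asserts on hundreds
of random cases). Precursor and transcriptome searches are sense-strand
only (small RNA reads are sense to the mature); genome and rRNA searches
cover both strands.

Tags with more than `max_hits = 10` genomic locations are flagged
multimapped and excluded from candidate calling. The upstream protocol
left its multimapping policy unstated; exclusion avoids repeat-driven
false candidates and is configurable.

## Hairpin folding

The fold is a weighted Nussinov dynamic program: maximise the sum of pair
weights (GC = 3, AU = 2, GU = 1) over nested structures with hairpin loops
of at least `min_loop = 3` nt. It deliberately replaces full
nearest-neighbour thermodynamics: the pipeline uses folding only as a
binary *can this form a hairpin* gate, and a weighted-pair DP admits an
exhaustive-enumeration oracle, so its correctness is testable to the last
case. The traceback is deterministic — pairing is preferred over leaving a
base unpaired, closing the whole interval over bifurcating, smaller
partner index on remaining ties — and `is_hairpin()` accepts a fold with
at least 16 pairs, at least half its bases paired, and exactly one
terminal loop.

A mature tag sits on one arm of its precursor, so candidate windows are
asymmetric: 20 nt behind the tag and 70 nt ahead of it (in transcription
direction), once for each arm hypothesis. Folding a whole ~110 nt window
maximises pairing *globally*, and random flanking sequence both folds into
small hairpins of its own and lures stem bases into long-range pairs; a
genuine precursor can therefore vanish from the window-wide optimum. The
window assessment consequently scans putative precursor spans anchored on
the tag (from tag + 30 nt up to the full window), folds each, extracts the
*stem-loop component* — the unbranched chain of nested pairs around one
terminal loop — that overlaps the tag, trims outer chain pairs where
needed, and accepts the first span whose component meets the hairpin
criteria. This is the in-silico analogue of excising a putative precursor
before judging it, standard practice in discovery pipelines. A candidate
passes if either arm-hypothesis window yields a passing component. The
hairpin gate alone rejects roughly three quarters of random windows;
jointly with the SCFG gate, rejection of random sequence is near-total
(both rates are asserted in the tests).

## The SCFG classifier

The grammar formalises pre-miRNA anatomy as the analysis describes it: a
stem interrupted by symmetric and asymmetric bulges, with a loop at the
end. Nonterminals are S, Stem, SymBulge, AsymBulge and Loop; Stem emits
base pairs (16 emission probabilities), enters a bulge state or the loop;
bulge states emit unpaired flanks and return to Stem; Loop emits the
terminal-loop run. Two design constraints matter:

* **No silent cycles.** Bulge entry emits at least one base
  (`Stem -> a SymBulge b`, `Stem -> a AsymBulge`), and the only unary
  productions (`SymBulge -> Stem`, `AsymBulge -> Stem`, `Stem -> Loop`,
  `S -> Stem`) form an acyclic dependency order, so the inside dynamic
  program is exact with a finite computation per subinterval.
* **Deterministic training.** A dot-bracket structure parses into exactly
  one state path (paired columns to Stem, both-sides-unpaired to SymBulge,
  one-side-unpaired to AsymBulge, the terminal unpaired run to Loop), so
  production probabilities are simple smoothed relative frequencies;
  training needs no expectation–maximisation. Branched (multiloop)
  structures are rejected with the offending record named.

Scores are natural-log inside probabilities normalised by sequence length.
The original classifier's cutoff was never published, so the package
calibrates its own: the cutoff is the 95th-percentile normalized score of
dinucleotide-shuffled versions of the training hairpins
(Altschul–Erickson-style shuffling, preserving dinucleotide composition
exactly), i.e. a fixed 0.95 specificity against composition-matched
negatives. Candidates are scored on the excised precursor span from the
hairpin assessment.

## Known-miRNA annotation

A precursor-mapped tag is called mature or star when both of its ends lie
within `arm_tolerance = 4` nt of the annotated arm ends; everything else
is a hairpin-region read. The 4-nt window is a design choice: end
heterogeneity of a few nucleotides is the dominant isomiR mode and
published example variants fall inside it. Offsets are reported signed
(tag end minus arm end, 5' and 3' separately), forming the isomiR
spectrum. Arm ratios are computed from summed per-arm counts (all isomiRs
included): below 0.75 star-dominant, 0.75–2.2 equivalent (inclusive
bounds), above 2.2 mature-dominant, undefined when the star count is zero
— no pseudocount, because a ratio against zero observed reads is not
evidence. If a tag fits both arm windows (conceivable on tiny precursors)
the smaller total end offset wins, ties to mature. A miRNA is *present* in
a library when its mature or star count is at least one after tag
filtering; presence underlies the per-library, common-to-all and
unique-to-one tallies.

## Genomic context and mirtrons

UTRs are derived on the fly from transcript and CDS coordinates: on the
plus strand the 5' UTR is the exonic region left of the CDS start,
mirrored for minus-strand transcripts; non-coding transcripts have no
UTRs. For every transcript a candidate overlaps, its feature is the
maximal-overlap region among coding exon, 5' UTR, 3' UTR and intron;
intronic calls are upgraded to mirtron (typical: both precursor ends on
the intron's splice sites; atypical: exactly one end) with an exact,
configurable anchoring tolerance of 0 nt. Across transcripts the
highest-precedence feature wins: mirtron_typical > mirtron_atypical >
exon > five_utr > three_utr > intron > promoter > intergenic, with
transcript-id ties broken lexicographically. The precedence order
operationalises a narrative description ("more deeply embedded within an
intron") that was never formalised upstream; it is a package decision.
Promoters are 1000 nt upstream of the TSS, strand-aware — the upstream
analysis counted promoter loci without defining "promoter", so the length
is a configurable assumption. Exon overhang for the post-filter is
measured strand-agnostically against all annotated exons.

## Expression and clustering

Expression values are relative proportions: a row's count in a library
divided by that library's *total* raw reads. Libraries (columns) are the
clustered entities; the metric is `1 - r` with centred Pearson `r`
(zero-variance vectors get distance 1 with a warning), the linkage is
average (UPGMA), and ties merge the lexicographically smallest label pair
first, making the dendrogram fully deterministic. The implementation is an
explicit agglomeration (needed for the deterministic tie-break); its merge
heights are verified in the tests against both a brute-force agglomerator
that recomputes cluster distances from raw pairwise means and against
`stats::hclust`. Dendrograms are exported as Newick via ape. The top-10
report ranks rows per library by proportion and sizes the non-redundant
union of all listed names.

## The synthetic-data generator

The generator *defines* the study conditions; it is not a tuning knob.
Defaults: a 120 kb uniform-composition ACGT genome; 12 gene models with
3–4 exons (120–250 nt) and introns of 150–400 nt, the last gene
non-coding; 30 known miRNA loci (planted across coding exons, introns,
promoters and intergenic space), 16 novel loci (introns, promoters,
intergenic), 2 typical and 2 atypical mirtrons (intron lengths engineered
to match), 3 rRNA loci and 5 mRNA-decoy windows inside coding exons.
Planted novel loci are never exonic: an exonic novel miRNA would be
subtracted at the transcriptome stage and removed by the exon-overhang
filter *by construction*, so it could never be named; exon context is
exercised by known loci instead.

Precursors are built as a 20–24 nt arm, an 8–15 nt loop drawn from {A, C}
(A and C cannot pair with each other, so the terminal loop cannot fold
internally), and a reverse-complement arm carrying 1–2 mismatches placed
in the middle third — a perfect stem would make every arm tag also match
the opposite arm on the opposite strand. Each precursor is
rejection-sampled until it passes `is_hairpin()` under default criteria,
making the "every planted precursor folds" invariant true by
construction.

Twelve libraries of 50,000 reads are simulated as 6 expression profiles
with 2 replicates each; profile weights are independent log-normal draws
(sdlog 1.5) per locus, so replicate columns correlate near 1 while
profiles differ — a known recoverable clustering structure. Per-locus
mature:star ratios are drawn once at reference-build time, spanning
star-dominant (0.05–0.6), equivalent (0.8–2.0) and mature-dominant
(3–5000) classes at 15/15/70%. IsomiR end offsets follow a default table
with 30% 3'-shift mass versus 8% 5'-shift mass (3' heterogeneity dominates,
as in real libraries). Reads carry substitution errors at 0.001 per base,
a read-through 3' adapter on a 36-cycle layout with 18–26 nt inserts, and
5% uniform-random singleton noise which the two-copy filter must remove.
Insert-size bounds were never stated upstream; these are assumptions
flagged here and configurable in `read_sim_config()`.

What the generator does **not** emulate: quality-score structure (all 'I'
qualities), PCR duplication, indels, repeat-derived multimapping,
cross-mapping between paralogous miRNA families, and real genome base
composition. Passing the planted-recovery tests therefore demonstrates the
pipeline's internal correctness — conservation of counts, exactness of the
cascade, detectability of planted hairpins — not its performance on real
tissue libraries.

## Numerical choices and degenerate inputs

* Grammar probabilities must sum to 1 within 1e-9 per nonterminal;
  inside scores use log-sum-exp (no scaling needed at ≤ 200 nt).
* An entirely unobserved nonterminal under smoothing 0 falls back to a
  uniform rule distribution.
* Empty read sets, zero-read configurations, empty plant lists and
  zero-row manifests all return typed empty objects rather than errors.
* Interval arithmetic is 0-based half-open internally; GFF3 I/O converts
  to 1-based closed. Splice-site anchoring and exon-overhang boundaries
  are exact integer comparisons.
* Candidate naming order (descending total count, then coordinate), tag
  collapse order (descending count, then sequence), hit order
  (reference, start, strand) and clustering tie-breaks are all total
  orders, so every output is byte-deterministic for a given seed.

## Problem sizes

The shipped study conditions (12 libraries x 50,000 reads, 58 planted
loci, 120 kb genome) run end to end in about a minute on one CPU; the
oracle-equivalence checks (500 alignment cases, 200 exhaustive fold
enumerations at ≤ 25 nt, SCFG derivation enumeration at ≤ 12 nt,
brute-force agglomeration at 5 columns) complete in a few minutes. These
sizes were chosen so the whole evidence chain — oracle checks plus
end-to-end recovery — reruns quickly enough to be part of routine testing.

## Known limitations

* The weighted-pair fold ignores stacking energetics; marginal hairpins
  that a thermodynamic model would accept or reject differently will
  disagree. The gate criteria (16 pairs, half paired, one loop) were
  chosen for the synthetic precursor family and published example
  structures, not fitted to any test outcome.
* The SCFG cutoff is a specificity quantile against shuffled negatives,
  not a reproduction of the original tool's (unpublished) cutoff.
* Candidate loci are merged only when tag intervals overlap; the mature
  and star arms of one novel precursor therefore surface as two separate
  candidates (they are separate sequences), as in the upstream protocol.
* Perfect-match-only classification discards genuinely variant reads
  (SNPs, editing); this is inherited from the analysis design.
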