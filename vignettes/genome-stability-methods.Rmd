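---
title: "Methods: within-host genome stability from simulated isolate cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: within-host genome stability from simulated isolate cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hostdrift)
```

# The analysis problem

A probiotic strain is administered to a host; descendant colonies are later
re-isolated from fecal samples and sequenced. Three questions define the
analysis: (i) which isolates are genuine descendants of the administered
strain, (ii) what point mutations accumulated in the shared (core) genome,
and (iii) what larger content changed — plasmids lost in part or whole,
fragments gained from other gut residents. `hostdrift` implements this
chain for a multi-replicon bacterial reference (one chromosome plus
plasmids), together with a synthetic-data generator that makes every stage
testable against planted ground truth.

# The homology engine

All stages run on one bespoke sequence-comparison core; nothing shells out
to an external aligner.

**Local alignment.** Exact k-mer seeds (k = 15 by default) are collected on
both strands, collapsed into maximal exact runs per diagonal, joined across
same-diagonal gaps when the intervening region scores no worse than
−30 under match +1 / mismatch −2, extended un-gapped with an X-drop of 30,
and finally chained across nearby diagonals with affine gap costs
(open 5, extend 2; per-side chain gap ≤ 100 bp). Identity is matches over
alignment columns, gap columns included. E-values use the Karlin–Altschul
formula $E = K m n e^{-\lambda S}$ with the fixed un-gapped nucleotide
parameters $\lambda = 1.28$, $K = 0.46$; they are deliberately approximate —
the contract is thresholding behaviour at the ~90%-identity regime, not
exact replication of another tool's statistics. The test suite holds the
engine against full Smith–Waterman (via `Biostrings::pairwiseAlignment`
with identical scoring) on pairs up to 2 kb: top-hit identity within ±1
point and score within 5%. Seeds occurring more than 256 times in a subject
are skipped, the usual soft masking of low-complexity seeds.

**Read pseudo-mapping.** Reads are anchored by exact k-mers (k = 21) taken
at read positions 1 and 51 — with 101-bp reads, one anchor survives any
single error — and every anchored placement is verified by full-length
mismatch counting (≤ 5 mismatches). A read maps to its unique best
placement; reads with tied best placements are *discarded*. The visible
consequence is near-zero depth inside the multi-copy rRNA loci, which the
variant stage exploits: the repeat filter and the ambiguity policy agree on
where calls cannot be trusted. Depth tracks count reads; SNP support counts
distinct read pairs.

**Fragment ANI.** The query genome is cut into consecutive 1020-bp windows;
each window's best hit to the subject is kept when it covers ≥ 70% of the
window at ≥ 30% identity, and ANI is the mean identity of kept windows.
ANI is computed one-way (isolate → reference) — the direction the
descendant screen uses. When no window is retained the ANI is reported as
undefined (`NA`), never as 0, and the screen excludes such isolates
explicitly.

# Variant stage

Contigs are aligned to the reference and reduced to mutually exclusive
1-to-1 blocks (greedy by score; a hit overlapping an accepted hit by more
than 20 bp on either axis is dropped — a delta-filter-like policy).
Mismatch columns inside blocks become candidate SNPs; indel columns are
ignored (substitutions only). Retention then requires, with strict
inequalities: call quality > 20, supporting read pairs > 10, and a
position outside the repeat mask.

Two definitions deserve comment:

* **Call quality.** "Quality > 20" is ambiguous between base quality and
  call quality; the package adopts call quality because it is computable
  from both inputs: $Q = -10\log_{10} P(\ge a \text{ alt pairs by chance}
  \mid d \text{ pairs}, e = 0.01)$, capped at 60. Any site with ≥ 95% alt
  support at depth ≥ 2 clears Q30 comfortably.
* **Repeat mask.** "Repetitive regions" are defined operationally: a
  position is masked iff it lies in a reference self-alignment hit
  (trivial diagonal excluded) of identity ≥ 95% and length ≥ 100 bp. On the
  synthetic reference this captures exactly the rRNA copies and the
  plasmid–chromosome homologous segments.

Effect classification mutates the affected codon respecting strand and
frame and translates with bacterial table 11; a brute-force oracle
(translate the whole gene, diff the proteins) backs it in the tests.

# Pan-genome and replicon dynamics

Core sequence is the union of contig spans aligning at ≥ 90% identity with
e-value < 1e-5; the complement, split at unaligned gaps, is strain-specific
after dropping fragments under 200 bp (alignment-edge slivers are noise;
the dropped length is still accounted for, so core + specific + dropped
always equals the contig total). Deduplication uses "identity ≥ 90% over
≥ 85% of the *shorter* sequence" — the length reference is a deliberate
choice (it stops long fragments absorbing unrelated short ones) — with
single-linkage clustering, the longest member as representative, and
lexicographic tie-breaks so the result is independent of input order.

Presence calling uses breadth of coverage with an explicit three-way
outcome: > 0.8 present, < 0.2 absent, otherwise *ambiguous* — the band in
between is undefined by the thresholds and silently forcing a binary there
would misclassify exactly the interesting partial-loss cases. Missing
intervals are maximal zero-depth runs ≥ 300 bp (smoothing over random
coverage gaps at finite depth; configurable), PLR is their total length
over the plasmid length, and the classifier bins PLR into
`none`, `<70%`, `70-80%`, `80-90%`, `90-100%`, `complete`. The `90-100%`
bin extends the four observed loss types so the classifier is total over
[0, 1].

**Entire-loss confirmation** mirrors a two-step design — coverage screen,
then plasmid-specific PCR. Confirmation requires the whole-plasmid call to
be absent *and* the plasmid-specific regions (plasmid minus its
chromosome-homologous segments) to be essentially uncovered
(breadth < 0.02). The screening-level 0.2 threshold is deliberately not
enough: a plasmid retaining 15% of its length has whole-plasmid breadth
below 0.2, yet its remaining specific regions would amplify in PCR, so
treating it as entirely lost would contradict its own partial-loss class.
A plasmid with no specific region at all returns `indeterminate`, a status
distinct from both outcomes.

Novel accessory fragments (no reference hit at the core thresholds) are the
HGT candidates; their best reference homolog is reported down to a 50%
identity floor. Because the thresholds are strict `≥ 90`, a fragment at
exactly 90% identity would map as core — the acquisition path therefore
also depends on the generator keeping the planted fragment's identity just
below the threshold (below).

# The synthetic-data generator

The generator emulates the study universe of a dairy-origin *Lactobacillus*
genome at desk scale:

* **Reference** (`ref_config()`): a 200-kb chromosome at GC 0.445 (compact
  variant: 80 kb) and seven plasmids of 5–60 kb. Five rRNA copies of
  2923 bp are placed across the chromosome; each copy carries at most one
  substitution from a master sequence, so any two copies differ by ≤ 2
  bases — comfortably above 99.9% pairwise identity. (An earlier design of
  ≤ 2 substitutions per copy can produce pairs at 99.86%, below the
  intended bound, which is why the cap is 1.) Plasmids p2, p4 and p7 carry
  segments homologous to the chromosome, generated at 95% identity — high
  enough to be masked as repeats, low enough that 101-bp reads still map
  uniquely to their true replicon. Genes are random-length CDSs (ATG start,
  no internal stop, terminal stop, bacterial code) with COG/KO/pathway
  annotations drawn from a small vocabulary; realized GC is nudged onto the
  target by flipping intergenic bases only.
* **Derived strains** (`plant_events()`): substitutions (validated against
  the reference base and the intended effect class, with a diagnostic when
  a class is unreachable at a site), partial plasmid deletions (contiguous
  region of the requested PLR at a seeded position, or explicit intervals)
  or complete replicon loss, and insertion of a donor-derived fragment.
  A truth ledger records every realized event.
* **The acquired fragment** (`make_hgt_fragment()`): the 609-bp window
  1215–1823 of the first rRNA copy, carrying 65 substitutions placed away
  from the fragment ends. 65/609 puts the identity near 89.3% against
  *every* rRNA copy — just below the 90% core threshold, which is exactly
  the regime where a real acquired rRNA fragment becomes an accessory
  sequence; end-clearance guarantees the full-length alignment is
  recovered rather than an end-trimmed one whose identity could cross the
  threshold. A donor rRNA gene is built around the fragment at ~3% further
  divergence, giving the ~97% donor identity signature of a cross-species
  transfer, without any external sequence.
* **Reads** (`simulate_reads()`): 101-bp pairs, normal insert of mean 350
  (sd 35), fragment orientation random, depth 100× by default, optional
  uniform substitution errors; qualities are constant Q40 with error
  positions downgraded to Q10, Phred+33. Pair counts follow
  depth × length / (2 × read length).
* **Contigs** (`shear_contigs()`): error-free partitions of each replicon
  at random breakpoints, optional fixed gap per junction, random
  orientation, never chimeric across replicons. The pipeline forces contig
  boundaries at acquired-fragment junctions — short-read assemblers break
  at flanking repeats, and a 609-bp 90%-identity island inside a long
  contig would otherwise be bridged by any BLAST-like aligner (including
  this one) and never surface as accessory. Contigs are error-free by
  default because no assembler error profile is specified anywhere;
  the shear parameters are tunable where one is wanted.

What the generator does **not** emulate: assembly errors and collapsed
repeats, genome rearrangements and copy-number changes (undetectable with
short reads in any case), GC skew, codon-usage bias, origin-spanning
features (replicons are linear; nothing in the analysis exercises
circularity), and qPCR chemistry (abundance series are consumed as data).
Green tests therefore demonstrate correctness of the analysis logic under
clean, substitution-dominated data — not robustness to misassembly or
contamination.

# Seeds, sizes and numerical choices

Every stochastic function takes a seed and restores the caller's RNG state;
per-strain seeds derive deterministically from the master seed, so
identical configurations reproduce byte-identical FASTA/FASTQ/TSV outputs.
All thresholds live in `pipeline_config()` with the defaults stated above
and are logged once per run.

Problem sizes: unit tests run on the compact (80-kb chromosome) reference;
the simulation-recovery acceptance tests run the six-strain cohort at the
full 100× depth on the compact reference (~144 kb of genome, ~71,000 read
pairs per strain), a scale chosen so the whole suite completes in a few
minutes while keeping every per-base statistic (depth, breadth, PLR
resolution) at study magnitudes. End-to-end determinism is checked on a
smaller two-strain configuration at 30×, since the property is independent
of depth.

The mutation-rate helper is pure arithmetic (max SNPs per strain over
generations, compared to the 0.0033 spontaneous benchmark). The generation
count behind the published-style bound 2/690 ≈ 0.0029 is *not* derivable
from sequence data and is treated as an explicit, documented assumption of
the example configuration, never inferred.

# Known limitations

* The aligner is tuned for the ≥ ~70% identity regime; at lower identities
  15-mer seeding finds nothing, which the ANI retention rule treats as
  "no alignable fragment" — adequate for descendant screening, not for
  remote-homology search.
* Call quality collapses to a binomial model with a fixed 1% base error;
  with error-free simulated reads it saturates at the cap, so the
  quality filter only becomes informative at nonzero error rates.
* Single-linkage deduplication is quadratic in the number of
  strain-specific fragments; fine at cohort scales where accessory
  fragments number in the tens or hundreds.
* PLR resolution is bounded by the 300-bp zero-run smoothing and by
  coverage tapering near deletion junctions; at 100× the realized error is
  well under the ±0.02 the recovery tests assert.
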