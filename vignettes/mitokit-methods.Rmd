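---
title: "Methods: comparative analysis of multipartite organelle genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative analysis of multipartite organelle genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitokit)
```

# Scope and data model

`mitokit` analyses multichromosomal plant mitogenomes: ordered sets of
named isoform sequences over `{A,C,G,T,N}`, each with a circularity flag
(`organelle_genome()`). Sequences are stored linearized as deposited;
operations that must honour circularity (repeat detection, flank
extraction) handle the origin themselves. All internal coordinates are
0-based half-open on the forward strand; GFF3 I/O is 1-based inclusive and
BED output 0-based half-open, matching each format's convention. Ambiguity
codes other than `N` are rejected by default and can be normalized to `N`
(`normalize_ambiguous = TRUE`), because every identity computation
downstream needs a defined alphabet; `N` never counts as a match and is
excluded from GC denominators.

# The internal aligner

All homology searches (self-comparison for repeats, mitogenome vs plastome
for MTPTs, genome vs genome for similarity, reads vs flank configurations)
go through one seed-and-extend local aligner:

1. exact k-mer seeds against a hashed subject index (default `k = 13`,
   valid range 9–15; k-mers occurring more than `max_occ = 400` times are
   not used, which keeps microsatellite-dense regions from flooding the
   anchor list);
2. same-diagonal seed merging, then collinear chaining across diagonals
   (gap up to `chain_gap = 500` bp);
3. piecewise alignment: exact base comparison along each merged segment and
   small exact global (Gotoh) alignments across inter-segment gaps;
4. ungapped X-drop extension at both chain ends (`xdrop = 50`). The budget
   is deliberately generous so extension can traverse local substitution
   clusters inside diverged homologies; the reported endpoint is still the
   running score maximum, so a larger budget widens the search, not the
   hit.

Scoring defaults are megablast-like: match +1, mismatch −2, gap open 2,
gap extend 1 (a gap of length L costs 2 + L). Expectation values use the
Karlin–Altschul formula E = K·m·n·exp(−λ·score) with the ungapped
constants for this matrix, λ = 1.28 and K = 0.46, and raw sequence lengths
as effective lengths (no edge correction). This calibration matters: with
these constants a 30 bp exact repeat on a ~100 kb genome clears the
E < 1e−5 reporting threshold, so the shortest repeats the pipeline is
specified to find remain reportable. Both the scoring and the constants
live in `scoring_scheme()` and can be replaced.

Two refinements keep reported hits consistent with their identity
threshold:

* **Identity-window decomposition.** Score-optimal extension can append a
  few chance-matching background bases to a short hit and dilute its
  identity just below the threshold; and the two arms of a closely spaced
  inverted repeat always lie on the same anti-diagonal, so the chainer —
  and even the exact local alignment — can join arm + spacer + arm into
  one low-identity alignment whenever the spacer costs less than an arm
  scores. Any hit failing the identity threshold is therefore decomposed
  into its maximal identity-passing windows: the longest window whose
  identity meets the threshold is found by a prefix-sum/prefix-minimum
  sweep and the procedure recurses on both remainders, so a merged
  palindrome yields both arms as separate hits. Gapless hits are
  decomposed directly on their match vector; gapped hits are first
  re-aligned with the exact Smith–Waterman routine and decomposed through
  its per-column operations. Reported intervals are always trimmed to
  aligned columns, which is also the identity denominator.
* **Containment de-duplication.** A hit whose query and subject intervals
  both lie inside a higher-scoring hit on the same strand is dropped.

`local_align()` is the exact affine-gap Smith–Waterman reference (full
dynamic programming with byte traceback, capped at 5000 bp per sequence).
It exists as the validation oracle: the test suite checks it against an
independent full-matrix R implementation and against
`Biostrings::pairwiseAlignment()`, and then requires the seeded aligner to
score within 5% of it on planted homologies. Ties in the seeded aligner
(chain extraction order, window choice) are broken deterministically, so
identical inputs give identical hit tables.

`read_blast_tab()`/`write_blast_tab()` translate between the internal hit
table and BLAST tabular (`outfmt 6`), converting the 1-based, possibly
reversed subject coordinates. For exact replication of numbers derived
from deposited accessions, run BLASTN externally and feed its tabular
output into the downstream operations; every statistic in the package is
computed from the hit table, not from the aligner internals.

# Repeats, SSRs and plastome repeat types

`find_dispersed_repeats()` aligns every isoform pair (including
self-alignment, both strands), removes the trivial full-length self-match
and mirror duplicates (keeping the pair whose (isoform, start) is
lexicographically smaller), and classifies pairs by aligned length with
100 and 1000 assigned to the intermediate class — the closed interval
reading of the 100–1000 bp class gives a consistent partition. Circular
isoforms are scanned with an origin-extended copy (the sequence plus up to
20 kb of its own prefix); hits living entirely in the extension are
dropped and intervals ending past the isoform length wrap the origin.
`deduplicate_repeat_content()` projects every copy interval onto the
genome and unions overlaps per isoform (`IRanges::reduce()`), so the
repeat content in bp and as a genome fraction counts no base twice.

`find_ssrs()` reports maximal perfect tandem runs of 1–6 bp motifs
(mononucleotides at ≥ 8 copies, longer motifs at ≥ 5, the thresholds used
with MISA for these genomes). Only full motif copies count, so a locus is
exactly `motif` repeated `count` times; runs whose motif is itself
periodic are reported only at the primitive motif; overlapping candidates
are resolved in favour of the longer locus; the observed motif is reported
alongside its canonical (lexicographically minimal) rotation. Compound
(interrupted) microsatellites are out of scope.

`find_plastome_repeats()` reports all maximal pairs of equal-length
substrings within Hamming distance 3 (length ≥ 20 bp) under the four
orientation relations — forward, reverse, complement, palindromic —
by walking every diagonal of the appropriately transformed sequence and
emitting windows bounded by the (d+1)-th mismatch on each side. Maximality
means a window absorbs up to the full mismatch budget from its
surroundings, so an exactly planted duplicate in random background
surfaces inside a slightly larger window at Hamming distance 3 (set
`max_hamming = 0` to see it verbatim). The scan is quadratic in sequence
length and intended for plastome-scale input; the test suite checks it
column-for-column against an independent diagonal scan.

# Recombination frequency from long reads

For each repeat pair, `build_configurations()` extracts the ±2000 bp
flanks of both copies. Flanks are *single-copy* by construction: they are
shortened where they would overlap any other detected repeat interval (the
partner copy included) and truncated at linear isoform ends (wrapped on
circular isoforms), with shortened flanks flagged. The two original
configurations are left + copy + right of each copy; the alternative
configurations exchange flanks as a crossover would. For direct repeats
that is left(A)+repeat+right(B) and left(B)+repeat+right(A); for inverted
repeats the crossover inverts the intervening segment, so the alternatives
are left(A)+repeat+revcomp(left(B)) and revcomp(right(A))+repeat+right(B).

`assign_reads()` aligns every read (both strands) to all four
configurations. A read supports a configuration iff its best alignment
there spans the full repeat copy plus at least `min_anchor = 100` bp into
both flanks at identity ≥ `min_read_identity = 0.8`. Reads spanning only
one flank, qualifying nowhere, or whose best original-class and
alternative-class scores tie are ambiguous. The anchor default exceeds
typical Nanopore indel noise so a junction cannot be crossed by chance;
both parameters are arguments. The frequency is
n_alt / (n_orig + n_alt); ambiguous reads never enter the formula, and a
zero denominator yields `NA`, never 0.

`recombination_scan()` runs the whole procedure per pair. Pairs longer
than the longest read minus two anchors are reported "unassessable" rather
than frequency 0, since no read could span them. A pair is flagged
recombinationally active when it has ≥ 2 alternative-supporting reads and
frequency > 0.01 — a deliberate guard against single chimeric reads; the
cutoff is a package default, stated here because published analyses of
this design report active-pair counts without stating one.

# Plastid-derived sequence and the binned correlation

`detect_cp_segments()` keeps mitogenome-vs-plastome hits with identity
> 80%, merges them on the mitochondrial side with gap tolerance 0 (strict
overlap/adjacency; the tolerance is configurable because merging policy
changes totals), and keeps merged segments longer than 200 bp. A merged
segment's identity is the length-weighted mean of its component hits and
its plastome interval is the span of their donor intervals. A plastid gene
is *intact* in a segment iff its full donor interval lies inside the
segment's plastome interval; partial overlaps are listed as fragments.
Segment length histograms default to the 200–500 / 501–1000 / 1001–1500 /
1501–3000 / > 3000 bp bins.

`bin_table()` concatenates the isoforms in order, cuts the result into
non-overlapping 3000 bp bins and drops a trailing shorter bin (unequal bin
lengths would bias both GC and counts). A feature increments every bin it
overlaps; counting only the start bin is available as
`count_mode = "start"`. `binned_feature_correlation()` computes two-sided
Pearson correlations of per-bin transfer counts against GC and against
repeat counts; zero variance in a variable yields `NA` with a diagnostic,
and fewer than 3 bins is an error. Bin tables from several genomes can be
pooled explicitly (pass a list of genomes, or a pre-bound bin table) —
published per-species versus pooled usage is ambiguous, so both are
provided and pooling is never implicit.

# Comparative statistics

`pairwise_similarity()` reports, for both directions, the merged hit
coverage divided by genome length; the two fractions differ when genome
sizes differ, and a single published percentage is interpreted as coverage
of the named query genome. `gene_clusters()` takes genes (exons of one
gene as one feature) in annotation order and forms maximal runs whose
intergenic gaps are ≤ 5 kb; without a gap cap, pure adjacency would chain
entire isoforms, and 5 kb is generous against typical organellar
intergenic spacers while still separating unrelated neighbourhoods.
Matching between genomes (`shared_clusters()`) requires the ordered
gene-name list to be identical or exactly reversed, each cluster matched
at most once.

`rscu()` computes count(c)·k / Σ counts over each amino acid's k
synonymous codons, so uniform usage gives exactly 1; stop codons are
excluded by default, duplicate gene copies (identical names) are counted
once by default (switchable), and a CDS with an internal in-frame stop is
skipped with a warning. Amino acids with zero total leave their codons
`NA` rather than 0. `find_orfs()` scans all six frames for ATG-to-stop
spans longer than 300 bp (stop included), reporting only the longest ORF
per stop and frame, with coordinates mapped to the forward strand.

# Phylogenomic matrices

`mask_cp_derived()` excises (merged) plastid-derived intervals from each
isoform and emits an old-to-new coordinate map; the removed total equals
the merged segment total. `filter_columns()` removes alignment columns
whose gap-plus-`N` fraction exceeds 0.5 — the column reading of a "more
than 50% missing data" rule; `block_missing_fraction()` supports the
whole-alignment reading, and a pipeline can apply both. The filter is
idempotent. `build_supermatrix()` concatenates locus blocks, fills taxa
missing from a block with all-gap rows, and records a partition map that
tiles the columns exactly; FASTA, relaxed PHYLIP and NEXUS(+charsets)
writers are byte-stable. Tree inference itself is out of scope — the
matrices are written for external ML/BI programs — but
`rf_distance()` compares two inferred newick topologies
(Robinson–Foulds, via ape/phangorn) as a convenience.

# The synthetic-data generator

`generate_mitogenome()` emulates the organisation this package targets:
by default 22 circular isoforms of 20–125 kb with i.i.d. background at GC
0.43 (the observed isoform range in these mitogenomes is roughly
40–46%), dispersed repeat pairs in all three size classes at > 95%
identity (direct and inverted, within and across isoforms), plastid
inserts of 0.2–10 kb at 85–99% identity copied from a generated
quadripartite plastome, SSR loci, and gene features arranged in cluster
templates. Planted features never overlap; a plan that cannot fit fails
before any output; a fixed seed gives byte-identical output from a single
RNG stream.

Choices that make the truth usable as an oracle:

* **Substitutions only** for identity control, so planted identity is an
  exact Hamming count; indels appear only in read simulation.
* **Placement of substitutions** is i.i.d. uniform, re-drawn when a
  terminal window of the feature would fall below the +1/−2 score
  break-even density (more than t/3 substitutions in the outer t bases).
  Such an edge is trimmed off *any* score-optimal local alignment, so the
  planted boundary would be unrecoverable by construction rather than by
  detector error; the outermost 3 bp of repeat copies are kept intact for
  the same reason. Evenly spaced (stratified) placement is deliberately
  not used: at 85% identity it leaves no exact 13-mer anywhere, defeating
  seeded detection altogether.
* **Gene-cluster blocks** are placed with a 5.1 kb margin so distinct
  planted templates cannot chain under the 5 kb cluster-adjacency rule.
* **SSR loci** are planted with guard bases so runs cannot extend into the
  background.

`generate_plastome()` builds LSC + IR\_A + SSC + IR\_B with IR\_B exactly
the reverse complement of IR\_A (default region lengths 84,962 / 26,128 /
14,001 bp with region GC targets 0.36 / 0.43 / 0.30) and plants plastid
genes in the single-copy regions.

`simulate_reads()` draws reads from "original" templates with probability
1−f and "alternative" templates with probability f, at uniform starts and
random strand, with log-normal lengths (mode ≈ 3 kb, truncated to
1–50 kb, 10-kb-library-like) and substitution/insertion/deletion errors
at 50/25/25 of the error rate. Reads longer than their template are
truncated with one summary warning. Per-read truth labels make f
recoverable against a binomial oracle.

What the generator does **not** emulate: realistic Nanopore error
profiles (homopolymer bias), transposable elements, RNA editing,
heteroplasmy, structural variants beyond the planted repeats/MTPTs, and
compositional heterogeneity along an isoform. Passing the planted-truth
tests therefore demonstrates correctness of the detection logic under the
stated feature model, not performance on arbitrary real data — for real
accessions the BLAST adapter path exists precisely so hit generation can
be swapped out.

# Validation strategy and problem sizes

The test suite is oracle-driven throughout: Smith–Waterman against an
independent full-matrix DP and `Biostrings::pairwiseAlignment()`; the
seeded aligner against Smith–Waterman (score ratio ≥ 0.95 on planted
homologies ≤ 2 kb); the SSR scanner and the plastome-repeat scanner
against naive independent scanners (exact equality); Pearson correlations
against a two-pass textbook implementation (1e−12); RSCU against a
per-codon tally and `seqinr::uco()`; and end-to-end planted-feature
recovery — 100% of planted repeats (≥ 95% identity, ≥ 30 bp) and MTPTs
(≥ 85%, ≥ 300 bp) on ten seeded genomes of 3–5 isoforms and ~150–300 kb,
with boundary error at most the seed length (13 bp). Recombination
recovery uses 2000 simulated reads per setting over
f ∈ {0, 0.1, 0.3, 0.5} at 5% error, requiring estimates within three
binomial standard errors of f (with the informative-read count as n) and
strict monotonicity across the grid. These sizes keep a full run of suite
plus acceptance script within a few minutes on one CPU while leaving
every detection threshold at its production default.

# Known limitations

* The aligner is a compact BLASTN-style search, not a BLASTN
  reimplementation: no length adjustment or sum statistics, and hit sets
  on real accessions will differ in detail from BLASTN's (use the tabular
  adapter for exact replication).
* The plastome repeat scan is O(n²) and meant for plastome-scale
  sequences, not megabase genomes.
* Recombination assignment requires reads to span repeat + anchors; large
  repeats (beyond the read-length distribution) are honestly reported
  unassessable rather than given a frequency of zero.
* `assign_reads()` treats the four configurations as the only hypotheses;
  reads from genuinely different loci that happen to align are filtered
  only by the identity and anchor rules.
* Cluster detection depends on annotation completeness and the 5 kb gap
  default; matching published cluster counts for a specific annotation
  set is not guaranteed and the parameter should be reported with any
  result.
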