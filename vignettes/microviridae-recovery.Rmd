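---
title: "Recovering and comparing circular Microviridae genomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering and comparing circular Microviridae genomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microvir)
```

## The problem

Microviridae are small icosahedral ssDNA phages with circular genomes of
roughly 4-6 kb. In viromes amplified by rolling circle amplification they
assemble readily, but three artifacts stand between an assembly and a
comparable genome set:

1. **Circularity is hidden.** Assemblers emit linear contigs. When a
   contig traverses the whole circle and overruns its own start, the
   overrun duplicates the contig's beginning as a *terminal direct
   repeat* — the diagnostic signature of a complete circular genome.
2. **No shared origin.** Each assembly starts its traversal at an
   arbitrary rotation (and strand), so naive sequence comparison between
   two copies of the same circle can report low identity.
3. **Redundancy.** The same phage species is assembled independently in
   several samples; community analyses need one representative per
   species.

`microvir` resolves these in order: detect the terminal repeat, trim to a
unit-length genome, reorient every genome to the start codon of its major
capsid protein (MCP, the family's marker gene), dereplicate at the 95%
nucleotide-identity species demarcation, and only then compare samples by
presence/absence of the representative genomes.

## Stage by stage

### Terminal-repeat detection and trimming

`detect_terminal_repeat()` uses exact-seed-and-extend: the contig's first
`min_repeat_nt` bases (default 10 nt) are matched across the contig
(tolerating one mismatch inside the seed so a single error in the first
bases cannot hide the repeat), every match reaching the contig end defines
a candidate repeat, each candidate is verified over its full length, and
the **longest** repeat with mismatch fraction at most `max_mismatch_rate`
(default 0.02) wins. Candidates are capped at half the contig length so
the two repeat copies cannot overlap; degenerate bases count as
mismatches. `trim_to_unit()` then removes the trailing copy, leaving one
full traversal. The unit genome keeps the contig's rotation — canonical
orientation is deferred to MCP anchoring, keeping the two concerns
separate. Unit genomes outside 1-8 kb are rejected (`size_filter()`,
bounds inclusive: the envelope is conventionally quoted as a closed
range).

### ORF calling on a circle

`call_orfs()` reports, per (stop codon, frame, strand), the *maximal* ORF:
the one starting at the first start codon after the previous in-frame
stop. ORFs overlapping in different frames or strands are all reported —
microviruses famously overlap genes — but nested in-frame starts sharing a
stop are not enumerated separately, since they would multiply-count every
gene in downstream synteny fingerprints. The circle is unrolled three
times and starts are taken from the middle copy, which gives every
candidate a full circle of upstream context (so the previous stop is
always visible) and a full circle downstream (so origin-spanning ORFs are
found); results are reported once with 0-based positions on the genome.
Start codons are ATG-only by default (GTG/TTG can be supplied via
`start_codons` — the standard bacterial code, translation table 11, is
used throughout). The length threshold is **strict**: an ORF must encode
*more than* `orf_min_aa` (default 80) amino acids, stop codon excluded.

### MCP identification and anchoring

Every ORF is scored against a reference panel of MCP proteins by
Smith-Waterman local alignment (BLOSUM62, gap open 11 / extend 1); the
highest-scoring ORF is the MCP, ties broken by panel order. A supplied
decoy panel (e.g. cellular proteins) that outscores the MCP panel excludes
the genome as a likely false positive; genomes hitting neither panel go to
an "unclassified" bin rather than erroring. The in-package search uses a
raw score floor (default 50) plus percent identity rather than e-values,
because e-value calibration needs database-size statistics that a small
panel cannot provide; the classical e-value cutoffs (1e-4 for the MCP
screen, 1e-3 for the cellular screen) apply when importing external BLAST
tabular results via `read_blast_tab()`. An MCP whose best identity falls
*strictly below* 70% is flagged as a novel-clade candidate.

`anchor_to_mcp()` rotates the genome so it begins at the MCP start codon,
reverse-complementing first when the MCP lies on the minus strand, and
remaps all ORF coordinates. The operation preserves genome length and is
idempotent.

### Identity and dereplication

`pairwise_identity()` aligns two genomes globally with affine gaps
(match +1 / mismatch -1, gap open 10 / extend 0.5 per nucleotide;
BLOSUM62 with open 11 / extend 1 for proteins) and reports
matches / alignment columns x 100, maximized over the strand of the
second genome. Terminal gap columns are excluded from the denominator and
internal gap columns count as mismatches — identity conventions differ
between tools, so this choice is explicit and the alignment parameters
are configurable. MCP-anchored genomes are already rotation-normalized;
for unanchored input a coarse rotation grid (`anchored = FALSE`) searches
the rotation space.

`dereplicate()` clusters greedily: genomes are processed longest-first
(lexicographic id tie-break); each joins the first cluster whose
representative it matches at **>= 95.0%** (join-at-threshold follows
common dereplication practice), else founds a new cluster. Because a full
affine-gap alignment of two 4.3 kb genomes costs about a second, the
decision is prescreened the way dedicated dereplication tools do it:

* an exact 15-mer containment filter (both strands). At 95% identity a
  genome retains at least `(g - 14) - 15 * 0.05 g` intact 15-mers — over
  25% of them even if every substitution breaks distinct 15-mers — while
  unrelated genomes share a fraction of order `g^2 / 4^15 ~ 10^-5`. The
  default skip cutoff of 0.05 therefore sits two orders of magnitude
  above random sharing and five-fold below the worst case at the
  threshold, so the prescreen cannot change a 95% decision;
* an ungapped comparison for equal-length candidates: ungapped identity
  is a lower bound on alignment identity, so reaching the threshold
  ungapped is a sufficient join condition.

Only pairs passing the k-mer screen but failing the fast bound pay for the
full alignment. `pairwise_identity()` itself never shortcuts.

### Synteny fingerprints

`synteny_fingerprint()` reduces an anchored genome to the ordered family
labels of its ORFs, sorted by start-codon position from the MCP —
overlapping genes are ordered by their starts, so the fingerprint is
invariant to intergenic spacing and synonymous change. Unlabeled ORFs
render as `HYP`. Strand is recorded but ignored by default when comparing
fingerprints (gene *order* is the conventional comparison; a flag includes
strand). `count_organizations()` counts distinct fingerprints per
phylogenetic group.

### Occupancy and community structure

`recruit_reads()` maps reads as exact substrings (both strands, origin
wrap allowed) and computes breadth of coverage: the fraction of genome
positions covered by at least one read. Presence in a sample requires
breadth **strictly greater** than 75%; depth is recorded but never used —
RCA amplification biases read counts for circular ssDNA templates, so
abundance is deliberately ignored. Real alignments can be imported from
SAM via `read_sam_coverage()` (CIGAR-aware union of aligned blocks), and
multi-mapping reads count toward every genome they match, since each
genome's breadth is computed independently.

The binary occupancy matrix feeds three dissimilarities, computed with
vegan on presence/absence data — with `a` shared presences and `b`, `c`
exclusive presences: Bray-Curtis `(b+c)/(2a+b+c)`, Jaccard
`(b+c)/(a+b+c)`, Euclidean `sqrt(b+c)`. On binary data Jaccard equals
`2*BC/(1+BC)` exactly, an identity the test suite asserts to 1e-12, and
all three indices rank sample pairs identically. Two empty samples have
dissimilarity 0 by convention, an empty against a non-empty sample 1 (the
convention is logged; configurable handling is deliberately *not* hidden
behind silent NA). Dendrograms use average linkage (UPGMA) by default —
no linkage is canonical for this analysis, and the congruence of the
three indices' trees is a theorem only under single linkage for
monotone-related indices, which is how the test suite checks it. Samples
are sorted lexicographically before clustering so tie-breaks are
deterministic; trees export as Newick with merge heights as branch
lengths.

## The synthetic-data generator

`simulate_community()` and its parts exist so every stage is testable
without external data. Design choices:

* **Genome envelope.** Lengths are drawn uniformly from 3,900-5,800 nt,
  the size range of complete microvirus genomes; each genome carries one
  MCP (planted from the reference panel at a configurable amino-acid
  divergence, default 10%) plus accessory genes (a replication-protein
  sized gene of 250-350 aa and a small 90-150 aa gene, random strands) in
  a configurable order. Intergenic filler is uniform random A/C/G/T — the
  simplest null background; no attempt is made to match real base
  composition or intergenic statistics.
* **Exact recoverability.** Each gene cassette is preceded by an in-frame
  *guard stop codon*, so the maximal-ORF convention recovers the planted
  start codon exactly; realizations are resampled from the seeded stream
  until the called ORF set equals the planted set (random filler
  occasionally spawns >80 aa ORFs; several retries per genome are
  normal). Generation is byte-for-byte reproducible from the template
  seed.
* **Variants.** `mutate_genome()` substitutes exactly
  `round(fraction * length)` positions, chosen without replacement under
  the seed. By default substitutions avoid planted start/stop/guard
  codons *and never create a premature in-frame stop* inside a planted
  gene, so truth annotations stay recoverable on variants; unconstrained
  mutation is a flag away. Within-cluster divergence defaults to 2%
  (safely inside the 95% species cutoff); distinct clusters are
  independent random genomes.
* **Coverage.** `simulate_coverage()` draws error-free reads as exact
  substrings (circular wrap allowed) until breadth reaches the target,
  truncating a read that would overshoot the +/-2 percentage-point band.
  Present genomes target 80-95% breadth and absent ones at most 55%, so
  simulated communities stay clear of the 75% decision boundary — the
  generator tests the bookkeeping, not the boundary, which has its own
  exact tests. Reads are error-free because presence is breadth-driven;
  sequencing-error models would test the mapper, not the rule.

What passing these tests does **not** show: performance on real viromes
with sequencing errors, chimeric RCA artifacts, uneven coverage,
incomplete assemblies, or MCPs diverged far beyond the panel. The
generator's truth recovery validates the pipeline's logic and
conventions, not its robustness to real-data noise.

## Numerical and degenerate-input conventions

* Thresholds are strict or inclusive exactly as stated: ORF length
  `> 80` aa, breadth `> 0.75`, novelty `< 70%`, cluster join `>= 95%`,
  size bounds inclusive.
* Internal coordinates are 0-based (`begin` is the forward-strand offset
  of the start codon's first base on the ORF's own strand); GFF3 output
  is 1-based inclusive, with origin-spanning ORFs emitted as two
  part-features sharing an ID and circularity declared on the region
  feature.
* Contigs shorter than twice the minimum repeat, genomes without ORFs,
  empty read sets, and empty FASTA inputs all produce verdicts or empty
  results, not errors; infeasible gene plans, out-of-range thresholds,
  duplicate ids and ragged tables error early with the offending value.
* Problem sizes in the tests and acceptance script (200 round-trip
  circles; 60 genomes / 20 clusters for dereplication; 15 genomes /
  5 clusters / 4 samples end-to-end; 1,000 random matrices for the metric
  identities) were chosen as the smallest scales at which each property
  is meaningfully exercised across its combinatorial range.

## Known limitations

* The exact-substring mapper is for error-free synthetic reads; real data
  should come in as SAM alignments.
* The rotation fallback for unanchored genomes is a coarse grid, not an
  exhaustive search; genomes without a recognizable MCP are better
  compared after manual anchoring.
* Phylogenetic placement (tree building, branch supports) is out of
  scope; `mcp_identity_matrix()` provides the identity substrate, and the
  group labels come from best panel hits, not from trees.
* The shipped reference panel is synthetic (see
  `inst/extdata/synthetic_mcp_panel.faa`): it exercises the machinery but
  cannot classify real sequences. Real analyses must supply a curated MCP
  panel.
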