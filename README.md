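# microvir

Recovery, curation and comparison of complete circular *Microviridae*
genomes from metagenomic assemblies.

## The problem

*Microviridae* are small ssDNA phages with circular genomes of ~4–6 kb
that dominate many gut viromes alongside the tailed *Caudovirales*.
Rolling-circle-amplified viromes assemble these genomes readily, but the
assemblies arrive as linear contigs at arbitrary rotations and strands,
with the same phage species assembled independently across samples. This
package turns such assemblies into a comparable genome set and analyzes
the resulting communities. It is aimed at virome researchers who have
assembled contigs, a curated panel of major capsid protein (MCP)
references, and per-sample reads, and who want species-level genome
catalogs and presence/absence community structure.

The pipeline:

1. **Circular detection** — a contig that overran its circular template
   carries a *terminal direct repeat* (its first L bases equal its last
   L bases). `detect_terminal_repeat()` finds the longest such repeat by
   exact-seed-and-extend; `trim_to_unit()` removes the duplicated
   terminus, leaving one full traversal; genomes outside 1–8 kb are
   dropped.
2. **Annotation** — `call_orfs()` finds maximal ORFs (> 80 aa, both
   strands, origin-spanning ORFs included) on the circle;
   `identify_mcp()` scores each ORF against the MCP panel by local
   alignment (the family's classification marker), screens against
   decoy/cellular panels, and flags MCPs under 70% identity as
   novel-clade candidates; `anchor_to_mcp()` reorients every genome to
   begin at the MCP start codon.
3. **Dereplication** — `pairwise_identity()` computes strand-normalized
   global-alignment identity; `dereplicate()` clusters greedily at the
   95% nucleotide-identity phage species demarcation
   (identity = matches / alignment columns; join at ≥ 95%).
4. **Synteny** — `synteny_fingerprint()` reduces each anchored genome to
   its ordered gene-family labels; `count_organizations()` counts
   distinct genome organizations per phylogenetic group.
5. **Occupancy** — `recruit_reads()` (or `read_sam_coverage()` for real
   alignments) computes breadth of coverage per genome and sample; a
   genome is *present* when reads cover **> 75%** of its positions
   (depth is never used: RCA biases read counts for circular ssDNA).
6. **Community** — from the binary occupancy matrix: Bray–Curtis
   `(b+c)/(2a+b+c)`, Jaccard `(b+c)/(a+b+c)` and Euclidean `sqrt(b+c)`
   dissimilarities (with `a` shared and `b`, `c` exclusive presences),
   Venn partitions, per-sample richness, and average-linkage dendrograms
   exported as Newick.

A seeded synthetic-data module (`simulate_community()`,
`generate_genome()`, `make_assembly_contig()`, `mutate_genome()`,
`simulate_coverage()`) generates microvirus-like communities with known
truth — planted genes, planted clusters, planted occupancy — so the whole
pipeline is testable end to end without external data. See the methods
vignette (`vignettes/microviridae-recovery.Rmd`) for the design decisions
and their rationale.

## Worked example

```r
library(microvir)

# a seeded community: 4 planted species x 2 variants, 4 samples
comm <- simulate_community(n_clusters = 4, variants_per_cluster = 2,
                           sample_ids = c("SC", "MC", "HC", "MB"),
                           seed = 2026)
run <- run_pipeline(comm$contigs, comm$panel,
                    reads_by_sample = comm$reads)
#> detect-circles: 8 contigs -> 8 circular
#> size-filter: 8 circular -> 8 within [1000, 8000] nt
#> annotate: 8 genomes -> 8 MCP-anchored (0 unclassified/excluded)
#> dereplicate: 8 genomes -> 4 clusters at 95% identity
#> synteny: 8 fingerprints, 2 distinct organizations overall
#> occupancy: 4 genomes x 4 samples, 7 presences
#> community: richness SC=1, MC=1, HC=2, MB=3
```

Every stage logs its input/output bookkeeping. The occupancy matrix is
binary presence (breadth > 75%) of each dereplicated representative in
each sample, and matches the simulation's planted truth exactly:

```r
run$occupancy
#>        SC MC HC MB
#> CGM001  1  0  1  0
#> CGM002  0  0  0  1
#> CGM003  0  0  0  1
#> CGM004  0  1  1  1

run$richness
#>   sample_id n_genomes n_unique
#> 1        SC         1        0
#> 2        MC         1        0
#> 3        HC         2        0
#> 4        MB         3        2
```

`n_genomes` counts species present per sample; `n_unique` counts those
found nowhere else. Community structure from the binary matrix:

```r
round(run$dissimilarity$bray_curtis$values, 3)
#>       SC    MC    HC  MB
#> SC 0.000 1.000 0.333 1.0
#> MC 1.000 0.000 0.333 0.5
#> HC 0.333 0.333 0.000 0.6
#> MB 1.000 0.500 0.600 0.0

run$dendrogram$newick
#> (SC:0.389,(MB:0.275,(HC:0.167,MC:0.167):0.108):0.114);
```

The MCP call for a representative carries its best panel hit, group label
and the novelty flag, and its synteny fingerprint is the gene order from
the MCP:

```r
run$annotations$CGM001$mcp_call
#> MCP call for CGM001: ok
#>   ORF CGM001_orf03 -> Gokushovirinae_ref1 (Gokushovirinae),
#>   identity 90.0%, novel candidate: FALSE

run$fingerprints$CGM001
#> CGM001 [Gokushovirinae]: MCP|HYP|HYP
```

An identity of 90% to a known Gokushovirinae reference is well above the
70% novelty cutoff, so this genome is not flagged; fingerprints list each
ORF's family label in start-codon order from the MCP (`HYP` =
hypothetical/unlabeled).

A command-line wrapper (`inst/scripts/microvir`) exposes the stages as
subcommands (`simulate`, `detect-circles`, `annotate`, `dereplicate`,
`synteny`, `occupancy`, `community`, `run-all`) over the same functions,
with a JSON config file and flag overrides.

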