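th <- microvir_thresholds()

# A toy circle holding exactly one ORF of n_aa (incl. Met), padded with
# ORF-free filler (GCT codons encode Ala; poly-C/G filler has no ATG and
# creates no spurious ORFs on either strand).
one_orf_circle <- function(n_aa, filler = 300) {
  paste0("TAA", "ATG", strrep("GCT", n_aa - 1), "TAA", strrep("C", filler))
}

test_that("the >80 aa ORF length threshold is strict", {
  expect_equal(nrow(call_orfs(one_orf_circle(80), th)), 0)
  orfs <- call_orfs(one_orf_circle(81), th)
  expect_equal(nrow(orfs), 1)
  expect_equal(orfs$length_aa, 81)
  expect_equal(orfs$begin, 3)
})

test_that("sequences without a start codon yield no ORFs", {
  expect_equal(nrow(call_orfs(strrep("C", 600), th)), 0)
})

test_that("origin-spanning ORFs are recovered after rotation", {
  g <- toy_genome(31, length_nt = 2400, mcp_aa = 400)
  # rotate so the MCP spans the origin
  rot <- microvir:::rotate_seq(g$sequence, g$truth$begin + 600L)
  orfs <- call_orfs(rot, th)
  expect_equal(nrow(orfs), 1)
  expect_true(orfs$wraps_origin)
  expect_equal(orfs$length_aa, 400)
  expect_identical(orfs$protein, g$truth$protein)
})

test_that("local panel search finds the right member with sane identity", {
  panel <- synthetic_mcp_panel(seed = 77)
  q <- panel$sequence[3]
  hit <- translated_search(q, panel)
  expect_true(hit$hit)
  expect_identical(hit$protein_id, panel$protein_id[3])
  expect_equal(hit$identity_pct, 100)
  # 35% of residues substituted -> identity ~65% (+-2 points)
  set.seed(5)
  q2 <- microvir:::mutate_protein(q, 0.35)
  hit2 <- translated_search(q2, panel)
  expect_identical(hit2$protein_id, panel$protein_id[3])
  expect_gt(hit2$identity_pct, 63)
  expect_lt(hit2$identity_pct, 67)
  # garbage query scores below the floor
  set.seed(6)
  junk <- microvir:::random_protein(60)
  expect_false(translated_search(junk, panel, score_floor = 100)$hit)
  expect_error(translated_search("", panel), "empty")
})

test_that("the MCP is identified, group propagated, and decoys screened", {
  panel <- synthetic_mcp_panel(seed = 77)
  set.seed(9)
  mcp <- microvir:::mutate_protein(panel$sequence[1], 0.10)
  plan <- data.frame(family = c("MCP", "REP"),
                     length_aa = c(nchar(mcp), 300), strand = c("+", "+"))
  tpl <- genome_template("T1", 3200, plan, seed = 15, length_range = NULL)
  g <- generate_genome(tpl, proteins = list(MCP = mcp))
  orfs <- call_orfs(g, th)
  call <- identify_mcp(g, orfs, panel, th)
  expect_identical(call$status, "ok")
  expect_equal(orfs$length_aa[call$orf_index], nchar(mcp))
  expect_identical(call$group_label, panel$group_label[1])
  expect_false(call$novel_candidate)  # ~90% identity is not novel
  # planting a decoy protein as the "MCP" gets the genome excluded
  decoy <- synthetic_mcp_panel(seed = 991,
                               group_labels = c("cellular_a", "cellular_b"))
  set.seed(10)
  g2 <- generate_genome(
    genome_template("T2", 3200, plan, seed = 16, length_range = NULL),
    proteins = list(MCP = decoy$sequence[1]))
  orfs2 <- call_orfs(g2, th)
  call2 <- identify_mcp(g2, orfs2, panel, th, decoy_panel = decoy)
  expect_identical(call2$status, "excluded")
  # a genome hitting nothing lands in the unclassified bin
  g3 <- toy_genome(52, length_nt = 1500, mcp_aa = 150)
  orfs3 <- call_orfs(g3, th)
  call3 <- identify_mcp(g3, orfs3, panel, th, score_floor = 120)
  expect_identical(call3$status, "unclassified")
})

test_that("a deeply divergent MCP is flagged as a novel-clade candidate", {
  panel <- synthetic_mcp_panel(seed = 77)
  set.seed(11)
  mcp <- microvir:::mutate_protein(panel$sequence[1], 0.35)
  plan <- data.frame(family = "MCP", length_aa = nchar(mcp), strand = "+")
  g <- generate_genome(genome_template("T3", 2600, plan, seed = 18,
                                       length_range = NULL),
                       proteins = list(MCP = mcp))
  call <- identify_mcp(g, call_orfs(g, th), panel, th)
  expect_identical(call$status, "ok")
  expect_lt(call$best_identity_pct, th$mcp_novelty_pct)
  expect_true(call$novel_candidate)
})

test_that("MCP anchoring rotates, strand-normalizes, and is idempotent", {
  plan <- data.frame(family = c("MCP", "REP"), length_aa = c(350, 250),
                     strand = c("-", "+"))
  g <- generate_genome(genome_template("A1", 2800, plan, seed = 23,
                                       length_range = NULL))
  orfs <- call_orfs(g, th)
  mcp_i <- which(orfs$length_aa == 350)
  anc <- anchor_to_mcp(g, orfs, mcp_i)
  s <- microvir:::genome_sequence(anc$genome)
  expect_equal(nchar(s), 2800)
  expect_identical(substr(s, 1, 3), "ATG")
  expect_equal(anc$orfs$begin[anc$orfs$length_aa == 350], 0)
  expect_identical(anc$orfs$strand[anc$orfs$length_aa == 350], "+")
  # GC content and ORF length multiset preserved (strand flips swap A/T)
  gc <- function(x) sum(strsplit(x, "")[[1]] %in% c("G", "C"))
  expect_identical(gc(s), gc(g$sequence))
  expect_identical(sort(anc$orfs$length_aa), sort(orfs$length_aa))
  # remapped coordinates agree with a fresh ORF call on the anchored genome
  oc <- call_orfs(anc$genome, th)
  expect_setequal(paste(oc$begin, oc$strand, oc$length_aa),
                  paste(anc$orfs$begin, anc$orfs$strand, anc$orfs$length_aa))
  # idempotence
  anc2 <- anchor_to_mcp(anc$genome, anc$orfs,
                        which(anc$orfs$length_aa == 350))
  expect_identical(microvir:::genome_sequence(anc2$genome), s)
  # identity case: MCP already at 0 on +
  plan2 <- data.frame(family = "MCP", length_aa = 400, strand = "+")
  g2 <- generate_genome(genome_template("A2", 1500, plan2, seed = 24,
                                        length_range = NULL))
  rot <- microvir:::rotate_seq(g2$sequence, g2$truth$begin)
  orfs2 <- call_orfs(rot, th)
  anc3 <- anchor_to_mcp(rot, orfs2, 1)
  expect_identical(microvir:::genome_sequence(anc3$genome), rot)
})
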