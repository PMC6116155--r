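th <- microvir_thresholds()

test_that("generated genomes have the requested size and recoverable planted ORFs", {
  plan <- data.frame(family = c("MCP", "REP"), length_aa = c(500, 300),
                     strand = c("+", "+"))
  g <- generate_genome(genome_template("G1", 4300, plan, seed = 7))
  expect_equal(nchar(g$sequence), 4300)
  expect_equal(nrow(g$truth), 2)
  orfs <- call_orfs(g, th)
  expect_equal(nrow(orfs), 2)
  expect_setequal(paste(orfs$begin, orfs$strand, orfs$length_aa),
                  paste(g$truth$begin, g$truth$strand, g$truth$length_aa))
  # planted proteins are recovered verbatim
  expect_setequal(orfs$protein, g$truth$protein)
})

test_that("genome generation is deterministic and validates its plan", {
  plan <- data.frame(family = c("MCP", "REP"), length_aa = c(500, 300),
                     strand = c("+", "-"))
  tpl <- genome_template("G1", 4300, plan, seed = 7)
  expect_identical(generate_genome(tpl)$sequence,
                   generate_genome(tpl)$sequence)
  # infeasible plan: ~6,000 nt of coding in a 4,000 nt genome
  big <- data.frame(family = c("MCP", "REP"), length_aa = c(1000, 990),
                    strand = c("+", "+"))
  expect_error(generate_genome(genome_template("G2", 4000, big, seed = 1)),
               "sizing")
  # exactly one MCP required
  expect_error(genome_template("G3", 4300,
                               data.frame(family = c("REP"), length_aa = 300,
                                          strand = "+"), seed = 1),
               "MCP")
  # size envelope enforced unless disabled
  expect_error(genome_template("G4", 1200, plan, seed = 1), "range")
  expect_s3_class(genome_template("G4", 10000, plan, seed = 1,
                                  length_range = NULL), "genome_template")
})

test_that("assembly contigs carry the constructed terminal repeat", {
  circle <- random_circle(4000, seed = 3)
  contig <- make_assembly_contig(circle, overrun_nt = 120, start_offset = 0)
  expect_equal(nchar(contig), 4120)
  expect_identical(substr(contig, 1, 120), substr(contig, 4001, 4120))
  # zero overrun: a pure rotation, no terminal repeat added
  rot <- make_assembly_contig(circle, 0, start_offset = 555)
  expect_equal(nchar(rot), 4000)
  expect_true(microvir:::rotation_equivalent(circle, rot))
  expect_error(make_assembly_contig(circle, 4000), "overrun")
})

test_that("mutation substitutes exactly round(fraction x length) positions", {
  circle <- random_circle(4000, seed = 8)
  expect_identical(mutate_genome(circle, 0, seed = 1), circle)
  m1 <- mutate_genome(circle, 0.05, seed = 1)
  expect_equal(microvir:::hamming(circle, m1), 200)
  m2 <- mutate_genome(circle, 0.05, seed = 2)
  expect_equal(microvir:::hamming(circle, m2), 200)
  pos1 <- which(strsplit(circle, "")[[1]] != strsplit(m1, "")[[1]])
  pos2 <- which(strsplit(circle, "")[[1]] != strsplit(m2, "")[[1]])
  expect_false(identical(pos1, pos2))
  expect_error(mutate_genome(circle, 0.6), "0.5")
})

test_that("protected mutation keeps planted genes intact", {
  g <- toy_genome(21, length_nt = 3000, mcp_aa = 400)
  m <- mutate_genome(g, 0.05, seed = 5)
  expect_equal(microvir:::hamming(g$sequence, m$sequence), 150)
  orfs <- call_orfs(m, th)
  # the planted MCP survives with exact coordinates
  expect_true(any(orfs$begin == g$truth$begin &
                  orfs$strand == g$truth$strand &
                  orfs$length_aa == g$truth$length_aa))
})

test_that("simulated coverage hits the target breadth band", {
  circle <- random_circle(4000, seed = 5)
  s0 <- simulate_coverage(circle, 0, read_length = 150)
  expect_length(s0$reads, 0)
  expect_equal(s0$realized_breadth, 0)
  s1 <- simulate_coverage(circle, 1, read_length = 150)
  expect_equal(s1$realized_breadth, 1)
  s <- simulate_coverage(circle, 0.76, read_length = 150, seed = 9)
  expect_gte(s$realized_breadth, 0.74)
  expect_lte(s$realized_breadth, 0.78)
  # reads are exact substrings of the circle (wrap allowed)
  doubled <- paste0(circle, circle)
  expect_true(all(vapply(s$reads, function(r) grepl(r, doubled, fixed = TRUE),
                         logical(1))))
  # deterministic under a seed
  s2 <- simulate_coverage(circle, 0.76, read_length = 150, seed = 9)
  expect_identical(unname(s$reads), unname(s2$reads))
  expect_error(simulate_coverage(circle, 0.76, read_length = 4000), "read_length")
  expect_error(simulate_coverage(circle, 1.5), "target_breadth")
})

test_that("a simulated community carries a coherent truth scaffold", {
  comm <- simulate_community(n_clusters = 3, variants_per_cluster = 2,
                             sample_ids = c("S1", "S2"), seed = 13)
  expect_length(comm$genomes, 6)
  expect_length(comm$representatives, 3)
  expect_true(all(colSums(comm$truth_occupancy) >= 1))
  expect_true(all(comm$truth_occupancy %in% c(0, 1)))
  # present clusters have breadth above the threshold margin, absent below
  occ <- comm$truth_occupancy
  br <- comm$breadth_truth
  expect_true(all(br[occ == 1] > 0.77))
  expect_true(all(br[occ == 0] < 0.73))
  # deterministic under the seed
  comm2 <- simulate_community(n_clusters = 3, variants_per_cluster = 2,
                              sample_ids = c("S1", "S2"), seed = 13)
  expect_identical(comm$genomes[[1]]$sequence, comm2$genomes[[1]]$sequence)
  expect_identical(comm$truth_occupancy, comm2$truth_occupancy)
})
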