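th <- microvir_thresholds()

# Annotate and anchor a generated genome, labeling accessory ORFs from a
# panel built out of the genome's own planted proteins.
fingerprint_of <- function(g, group = "Gokushovirinae") {
  panel <- data.frame(protein_id = "MCP_ref", group_label = group,
                      sequence = g$truth$protein[g$truth$family == "MCP"],
                      stringsAsFactors = FALSE)
  acc_rows <- g$truth$family != "MCP" & g$truth$family != "HYP"
  accessory <- if (any(acc_rows)) {
    data.frame(protein_id = g$truth$family[acc_rows],
               group_label = g$truth$family[acc_rows],
               sequence = g$truth$protein[acc_rows],
               stringsAsFactors = FALSE)
  } else NULL
  ann <- annotate_genome(g, panel, th, accessory_panel = accessory)
  expect_identical(ann$status, "ok")
  synteny_fingerprint(ann$genome, ann$orfs, group_label = group)
}

test_that("planted gene plans are recovered as fingerprints", {
  plan <- data.frame(family = c("MCP", "REP", "HYP"),
                     length_aa = c(420, 300, 120),
                     strand = c("+", "+", "-"))
  g <- generate_genome(genome_template("F1", 4000, plan, seed = 33))
  fp <- fingerprint_of(g)
  expect_identical(fp$key, "MCP|REP|HYP")
  expect_identical(fp$labels[1], "MCP")
  # strand-aware comparison is available behind a flag
  panel <- data.frame(protein_id = "MCP_ref", group_label = "x",
                      sequence = g$truth$protein[1])
  ann <- annotate_genome(g, panel, th)
  fp2 <- synteny_fingerprint(ann$genome, ann$orfs, include_strand = TRUE)
  expect_match(fp2$key, "-", fixed = TRUE)
})

test_that("fingerprints ignore intergenic spacing", {
  plan <- data.frame(family = c("MCP", "REP"), length_aa = c(420, 300),
                     strand = c("+", "+"))
  prots <- list(MCP = microvir:::with_seed(1, microvir:::random_protein(420)),
                REP = microvir:::with_seed(2, microvir:::random_protein(300)))
  g1 <- generate_genome(genome_template("S1", 4000, plan, seed = 41),
                        proteins = prots)
  g2 <- generate_genome(genome_template("S2", 4600, plan, seed = 42),
                        proteins = prots)
  expect_false(identical(g1$truth$begin, g2$truth$begin))
  fp1 <- fingerprint_of(g1)
  fp2 <- fingerprint_of(g2)
  expect_identical(fp1$key, fp2$key)
})

test_that("overlapping ORFs are ordered by start-codon position", {
  orfs <- data.frame(
    orf_id = c("a", "b", "c"), begin = c(0L, 150L, 100L),
    strand = c("+", "+", "-"), length_aa = c(200L, 180L, 150L),
    length_nt = c(603L, 543L, 453L), wraps_origin = FALSE,
    protein = "M", family_label = c("MCP", "VP2", "VP3"),
    stringsAsFactors = FALSE)
  fp <- synteny_fingerprint(list(genome_id = "x"), orfs)
  expect_identical(fp$key, "MCP|VP3|VP2")
})

test_that("unanchored genomes are rejected", {
  orfs <- data.frame(orf_id = "a", begin = 12L, strand = "+",
                     length_aa = 100L, length_nt = 303L,
                     wraps_origin = FALSE, protein = "M",
                     family_label = "MCP", stringsAsFactors = FALSE)
  expect_error(synteny_fingerprint(list(genome_id = "x"), orfs), "anchored")
})

test_that("distinct organizations are counted per group", {
  mk <- function(id, key, group) {
    structure(list(genome_id = id, labels = strsplit(key, "|", fixed = TRUE)[[1]],
                   strands = "+", group_label = group, key = key),
              class = "synteny_fingerprint")
  }
  fps <- list(mk("g1", "MCP|REP", "A"), mk("g2", "MCP|REP", "A"),
              mk("g3", "MCP|HYP|REP", "A"), mk("g4", "MCP|REP", "B"),
              mk("g5", "MCP|REP", "B"))
  counts <- count_organizations(fps)
  expect_equal(counts$n_organizations[counts$group == "A"], 2)
  expect_equal(counts$n_organizations[counts$group == "B"], 1)
  # order invariance
  counts2 <- count_organizations(rev(fps))
  expect_identical(counts, counts2)
  # a group with no fingerprints counts zero organizations
  asg <- c(g1 = "A", g2 = "A", g3 = "A", g4 = "B", g5 = "B", ghost = "C")
  counts3 <- count_organizations(fps, group_assignments = asg)
  expect_equal(counts3$n_organizations[counts3$group == "C"], 0)
  # missing group labels are an error
  fps_na <- list(mk("g1", "MCP", NA_character_))
  expect_error(count_organizations(fps_na), "group")
})
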