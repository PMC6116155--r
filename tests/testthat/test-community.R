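test_that("binary dissimilarities follow the set formulas", {
  m <- matrix(0L, 4, 2, dimnames = list(paste0("g", 1:4), c("A", "B")))
  m[c("g1", "g2", "g3"), "A"] <- 1L
  m[c("g2", "g3", "g4"), "B"] <- 1L
  bc <- binary_dissimilarity(m, "bray_curtis")$values["A", "B"]
  jc <- binary_dissimilarity(m, "jaccard")$values["A", "B"]
  eu <- binary_dissimilarity(m, "euclidean")$values["A", "B"]
  expect_equal(bc, 2 / 6)
  expect_equal(jc, 2 / 4)
  expect_equal(eu, sqrt(2))
  # identical samples -> 0; disjoint samples -> 1 for BC and Jaccard
  m2 <- cbind(m, C = m[, "A"])
  expect_equal(binary_dissimilarity(m2, "bray_curtis")$values["A", "C"], 0)
  m3 <- matrix(c(1L, 0L, 0L, 1L), 2, dimnames = list(c("g1", "g2"), c("X", "Y")))
  expect_equal(binary_dissimilarity(m3, "bray_curtis")$values["X", "Y"], 1)
  expect_equal(binary_dissimilarity(m3, "jaccard")$values["X", "Y"], 1)
  expect_error(binary_dissimilarity(m, "hamming"), "arg")
})

test_that("vegan-backed dissimilarities match an independent oracle", {
  for (i in 1:25) {
    m <- random_occupancy(10, 4, seed = 400 + i)
    for (ix in c("bray_curtis", "jaccard", "euclidean")) {
      got <- suppressMessages(binary_dissimilarity(m, ix))$values
      for (a in 1:3) for (b in (a + 1):4) {
        want <- set_formula_dissim(m[, a] == 1, m[, b] == 1, ix)
        expect_equal(got[a, b], want, tolerance = 1e-12,
                     info = sprintf("seed %d %s %d-%d", 400 + i, ix, a, b))
      }
    }
  }
})

test_that("empty samples follow the documented convention", {
  m <- matrix(0L, 3, 3, dimnames = list(paste0("g", 1:3), c("A", "B", "C")))
  m[, "A"] <- 1L
  expect_message(d <- binary_dissimilarity(m, "bray_curtis"), "empty")
  expect_equal(d$values["B", "C"], 0)  # empty vs empty
  expect_equal(d$values["A", "B"], 1)  # empty vs non-empty
})

test_that("Venn partitions follow set algebra and sum to the union", {
  m <- matrix(0L, 4, 2, dimnames = list(paste0("g", 1:4), c("A", "B")))
  m[c("g1", "g2", "g3"), "A"] <- 1L
  m[c("g2", "g3", "g4"), "B"] <- 1L
  v <- venn_partition(m, c("A", "B"))
  expect_equal(unname(v$regions["unique_A"]), 1)
  expect_equal(unname(v$regions["unique_B"]), 1)
  expect_equal(unname(v$regions["shared"]), 2)
  expect_equal(sum(v$regions), v$union_size)
  # A == B: everything shared
  m2 <- cbind(m[, "A", drop = FALSE], B = m[, "A"])
  v2 <- venn_partition(m2, c("A", "B"))
  expect_equal(unname(v2$regions["shared"]), 3)
  expect_equal(sum(v2$regions[c("unique_A", "unique_B")]), 0)
  # three pairwise-disjoint sets: only the unique regions are filled
  m3 <- diag(3L)
  dimnames(m3) <- list(paste0("g", 1:3), c("A", "B", "C"))
  v3 <- venn_partition(m3, c("A", "B", "C"))
  expect_equal(sum(v3$regions), 3)
  expect_equal(unname(v3$regions["all_shared"]), 0)
  expect_true(all(v3$regions[grepl("unique", names(v3$regions))] == 1))
  expect_error(venn_partition(m3, c("A", "B", "C", "D")), "3 sets|unknown")
  # random matrices: regions always sum to the union size
  for (i in 1:20) {
    mm <- random_occupancy(12, 3, seed = 500 + i)
    vv <- venn_partition(mm, colnames(mm))
    expect_equal(sum(vv$regions),
                 sum(rowSums(mm) > 0))
  }
})

test_that("dendrograms merge identical samples first and stay ultrametric", {
  m <- matrix(0L, 6, 3, dimnames = list(paste0("g", 1:6), c("A", "B", "C")))
  m[1:4, "A"] <- 1L
  m[1:4, "B"] <- 1L
  m[5:6, "C"] <- 1L
  den <- sample_dendrogram(binary_dissimilarity(m, "bray_curtis"))
  expect_equal(den$hclust$height[1], 0)       # identical pair merges at 0
  first_pair <- sort(den$hclust$labels[-den$hclust$merge[1, ]])
  expect_identical(first_pair, c("A", "B"))
  expect_true(ape::is.ultrametric(den$phylo))
  expect_error(sample_dendrogram(binary_dissimilarity(m[, 1:2, drop = FALSE],
                                                      "bray_curtis")),
               "3 samples")
})

test_that("jaccard and bray-curtis single-linkage trees are congruent", {
  m <- random_occupancy(15, 5, seed = 601)
  t_bc <- sample_dendrogram(binary_dissimilarity(m, "bray_curtis"),
                            linkage = "single")$phylo
  t_jc <- sample_dendrogram(binary_dissimilarity(m, "jaccard"),
                            linkage = "single")$phylo
  expect_equal(ape::dist.topo(ape::unroot(t_bc), ape::unroot(t_jc)), 0,
               ignore_attr = TRUE)
})

test_that("average-linkage agglomeration matches a brute-force oracle", {
  m <- random_occupancy(12, 4, seed = 602)
  dm <- binary_dissimilarity(m, "bray_curtis")
  den <- sample_dendrogram(dm, linkage = "average")
  got <- as.matrix(stats::cophenetic(den$hclust))
  want <- upgma_cophenetic_oracle(dm$d)
  expect_equal(got[rownames(want), colnames(want)], want, tolerance = 1e-12)
})

test_that("richness reports presence and uniqueness per sample", {
  ones <- matrix(1L, 3, 3, dimnames = list(paste0("g", 1:3), c("A", "B", "C")))
  r1 <- richness_report(ones)
  expect_equal(r1$n_genomes, c(3, 3, 3))
  expect_equal(r1$n_unique, c(0, 0, 0))
  eye <- diag(3L)
  dimnames(eye) <- dimnames(ones)
  r2 <- richness_report(eye)
  expect_equal(r2$n_genomes, c(1, 1, 1))
  expect_equal(r2$n_unique, c(1, 1, 1))
  # column-sum oracle on a random truth matrix
  m <- random_occupancy(20, 4, seed = 603)
  expect_equal(richness_report(m)$n_genomes, unname(colSums(m)))
})
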