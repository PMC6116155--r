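th <- microvir_thresholds()

mk_profile <- function(covered, length, gid = "g1", sid = "s1") {
  structure(list(genome_id = gid, sample_id = sid,
                 covered_positions = covered, genome_length = length,
                 breadth = covered / length, mean_depth = 1,
                 depth = integer(0)),
            class = "coverage_profile")
}

test_that("presence needs breadth strictly above 75%", {
  expect_equal(call_presence(mk_profile(3100, 4000), th), 1L)  # 77.5%
  expect_equal(call_presence(mk_profile(3000, 4000), th), 0L)  # 75.0%
  expect_equal(call_presence(mk_profile(0, 4000), th), 0L)
})

test_that("the exact mapper agrees with the coverage generator", {
  circle <- random_circle(3000, seed = 201)
  sim <- simulate_coverage(circle, 0.76, read_length = 120, seed = 202)
  prof <- recruit_reads(sim$reads, circle, sample_id = "s1",
                        genome_id = "g1")
  expect_equal(prof$breadth, sim$realized_breadth)
  expect_identical(prof$depth > 0, sim$covered)
  # tiling reads give breadth 1, empty read sets give 0
  tiling <- simulate_coverage(circle, 1, read_length = 100)
  expect_equal(recruit_reads(tiling$reads, circle)$breadth, 1)
  expect_equal(recruit_reads(character(0), circle)$breadth, 0)
  # reverse-complemented reads still recruit (strand-insensitive mapping)
  rc_reads <- vapply(sim$reads[1:5], revcomp, character(1))
  prof_rc <- recruit_reads(rc_reads, circle)
  prof_fw <- recruit_reads(sim$reads[1:5], circle)
  expect_equal(prof_rc$breadth, prof_fw$breadth)
})

test_that("reads longer than the genome are skipped with a warning", {
  circle <- random_circle(500, seed = 203)
  long_read <- paste0(circle, "ACGT")
  expect_warning(prof <- recruit_reads(c(r1 = long_read), circle), "skipped")
  expect_equal(prof$breadth, 0)
})

test_that("presence is monotone under added reads", {
  circle <- random_circle(2000, seed = 204)
  sim <- simulate_coverage(circle, 0.9, read_length = 100, seed = 205)
  breadths <- vapply(seq_along(sim$reads), function(k) {
    recruit_reads(sim$reads[seq_len(k)], circle)$breadth
  }, numeric(1))
  expect_true(all(diff(breadths) >= 0))
})

test_that("occupancy matrices cover the full grid with binary entries", {
  profs <- list(mk_profile(3900, 4000, "g1", "s1"),
                mk_profile(3950, 4000, "g2", "s1"),
                mk_profile(3800, 4000, "g1", "s2"),
                mk_profile(3850, 4000, "g2", "s2"))
  m <- build_occupancy(profs, th)
  expect_true(all(m == 1L))
  expect_equal(dim(m), c(2, 2))
  # a missing (genome, sample) pair defaults to 0
  m2 <- build_occupancy(profs[1:3], th)
  expect_equal(m2["g2", "s2"], 0L)
  # genomes never seen anywhere can be forced into the grid
  m3 <- build_occupancy(profs, th, genome_ids = c("g1", "g2", "g3"))
  expect_equal(sum(m3["g3", ]), 0L)
  # duplicate profiles are an error
  expect_error(build_occupancy(c(profs, profs[1]), th), "duplicate")
})

test_that("SAM import reproduces interval-union coverage", {
  g <- random_circle(300, seed = 206)
  sam <- tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:unsorted", "@SQ\tSN:g1\tLN:300")
  rec <- function(id, pos, len) {
    sprintf("%s\t0\tg1\t%d\t60\t%dM\t*\t0\t0\t%s\t*", id, pos, len,
            substr(g, pos, pos + len - 1))
  }
  writeLines(c(hdr, rec("r1", 1, 100)), sam)
  p <- read_sam_coverage(sam, c(g1 = 300))[[1]]
  expect_equal(p$covered_positions, 100)
  # two overlapping reads 1-100 and 51-150 cover 150 positions
  writeLines(c(hdr, rec("r1", 1, 100), rec("r2", 51, 100)), sam)
  p2 <- read_sam_coverage(sam, c(g1 = 300))[[1]]
  expect_equal(p2$covered_positions, 150)
  # empty alignment file: breadth 0
  writeLines(hdr, sam)
  p3 <- read_sam_coverage(sam, c(g1 = 300))[[1]]
  expect_equal(p3$breadth, 0)
  # unknown reference names are an error
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:mystery\tLN:300"), sam)
  expect_error(read_sam_coverage(sam, c(g1 = 300)), "mystery")
})

test_that("SAM-imported breadth equals the exact mapper on synthetic reads", {
  g <- random_circle(2000, seed = 207)
  sim <- simulate_coverage(g, 0.7, read_length = 100, seed = 208)
  doubled <- paste0(g, g)
  sam <- tempfile(fileext = ".sam")
  lines <- c("@HD\tVN:1.6\tSO:unsorted", "@SQ\tSN:g1\tLN:2000")
  keep <- logical(length(sim$reads))
  for (i in seq_along(sim$reads)) {
    rd <- sim$reads[[i]]
    pos <- regexpr(rd, doubled, fixed = TRUE)[1]
    if (pos > 2000) pos <- pos - 2000
    if (pos + nchar(rd) - 1 > 2000) next  # linear SAM cannot express wraps
    keep[i] <- TRUE
    lines <- c(lines, sprintf("read%d\t0\tg1\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
                              i, pos, nchar(rd), rd))
  }
  writeLines(lines, sam)
  p_sam <- read_sam_coverage(sam, c(g1 = 2000))[[1]]
  p_map <- recruit_reads(sim$reads[keep], g, genome_id = "g1")
  expect_equal(p_sam$breadth, p_map$breadth)
})
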