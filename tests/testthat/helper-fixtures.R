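# Shared fixtures and independent oracles, all built in code.

random_circle <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

toy_genome <- function(seed, length_nt = 2000L, mcp_aa = 300L,
                       extra = NULL) {
  plan <- data.frame(family = "MCP", length_aa = mcp_aa, strand = "+",
                     stringsAsFactors = FALSE)
  if (!is.null(extra)) plan <- rbind(plan, extra)
  tpl <- genome_template(sprintf("toy%d", seed), length_nt, plan,
                         seed = seed, length_range = NULL)
  generate_genome(tpl)
}

# Do two member->cluster assignments describe the same partition?
same_partition <- function(a, b) {
  if (!setequal(names(a), names(b))) return(FALSE)
  all(vapply(names(a), function(m) {
    setequal(names(a)[a == a[[m]]], names(b)[b == b[[m]]])
  }, logical(1)))
}

truth_assignments <- function(community) {
  unlist(lapply(names(community$truth_clusters), function(r) {
    setNames(rep(r, length(community$truth_clusters[[r]])),
             community$truth_clusters[[r]])
  }))
}

# Independent set-formula oracle for binary dissimilarities.
set_formula_dissim <- function(x, y, index) {
  a <- sum(x & y)
  b <- sum(x & !y)
  c <- sum(!x & y)
  switch(index,
         bray_curtis = if (2 * a + b + c == 0) 0 else (b + c) / (2 * a + b + c),
         jaccard = if (a + b + c == 0) 0 else (b + c) / (a + b + c),
         euclidean = sqrt(b + c))
}

random_occupancy <- function(n_genomes, n_samples, seed, p = 0.5) {
  set.seed(seed)
  m <- matrix(rbinom(n_genomes * n_samples, 1L, p), n_genomes,
              dimnames = list(sprintf("g%02d", seq_len(n_genomes)),
                              sprintf("s%02d", seq_len(n_samples))))
  m
}

# Brute-force maximum ungapped identity over all rotations and both
# strands of equal-length circular sequences.
bruteforce_rotation_identity <- function(a, b) {
  n <- nchar(a)
  ac <- strsplit(a, "")[[1]]
  best <- 0
  for (s in c(b, microvir::revcomp(b))) {
    dbl <- strsplit(paste0(s, s), "")[[1]]
    for (k in 0:(n - 1)) {
      idt <- sum(ac == dbl[(k + 1):(k + n)]) / n * 100
      if (idt > best) best <- idt
    }
  }
  best
}

# Tiny UPGMA oracle: naive agglomeration over a dissimilarity matrix,
# returning the cophenetic matrix.
upgma_cophenetic_oracle <- function(d) {
  m <- as.matrix(d)
  n <- nrow(m)
  groups <- as.list(rownames(m))
  coph <- matrix(0, n, n, dimnames = dimnames(m))
  active <- m
  while (length(groups) > 1L) {
    am <- active
    diag(am) <- Inf
    ij <- which(am == min(am), arr.ind = TRUE)[1, ]
    i <- min(ij); j <- max(ij)
    h <- active[i, j]
    for (x in groups[[i]]) for (y in groups[[j]]) {
      coph[x, y] <- h; coph[y, x] <- h
    }
    merged <- c(groups[[i]], groups[[j]])
    # average linkage: size-weighted mean of distances
    ni <- length(groups[[i]]); nj <- length(groups[[j]])
    newd <- (ni * active[i, -c(i, j)] + nj * active[j, -c(i, j)]) / (ni + nj)
    keep <- setdiff(seq_along(groups), c(i, j))
    groups <- c(groups[keep], list(merged))
    if (length(keep)) {
      active <- rbind(cbind(active[keep, keep, drop = FALSE], newd),
                      c(newd, 0))
    } else {
      active <- matrix(0, 1, 1)
    }
  }
  coph
}
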