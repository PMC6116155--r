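# Community comparison from the binary occupancy matrix: dissimilarity
# indices, Venn partitions, average-linkage dendrograms and richness.

#' Binary dissimilarity between samples
#'
#' Computes pairwise sample dissimilarities from a binary occupancy
#' matrix. With `a` shared presences and `b`, `c` presences exclusive to
#' each sample: Bray-Curtis = (b+c)/(2a+b+c), Jaccard = (b+c)/(a+b+c),
#' Euclidean = sqrt(b+c). Computed with [vegan::vegdist()] on
#' presence/absence data. Two empty samples have dissimilarity 0 by
#' convention (an empty vs a non-empty sample gives 1 for Bray-Curtis and
#' Jaccard); the convention is applied with a message.
#'
#' @param matrix an `occupancy_matrix` (genomes x samples) or any binary
#'   matrix with sample columns.
#' @param index_name one of `"bray_curtis"`, `"jaccard"`, `"euclidean"`.
#' @return an object of class `dissimilarity_matrix`: list with
#'   `sample_ids`, `values` (symmetric matrix), `index_name`, and `d`
#'   (the underlying `dist`).
#' @export
binary_dissimilarity <- function(matrix,
                                 index_name = c("bray_curtis", "jaccard",
                                                "euclidean")) {
  index_name <- match.arg(index_name)
  x <- t(unclass(matrix) > 0) * 1   # samples as rows, strictly binary
  method <- c(bray_curtis = "bray", jaccard = "jaccard",
              euclidean = "euclidean")[[index_name]]
  d <- suppressWarnings(vegan::vegdist(x, method = method, binary = TRUE))
  v <- as.matrix(d)
  if (any(!is.finite(v))) {
    empty <- rowSums(x) == 0
    for (i in which(empty)) for (j in which(empty)) v[i, j] <- 0
    diag(v) <- 0
    if (any(!is.finite(v))) v[!is.finite(v)] <- 1
    message("empty sample(s) present: empty-empty dissimilarity set to 0, ",
            "empty-nonempty to 1")
  }
  out <- list(sample_ids = rownames(v), values = v,
              index_name = index_name, d = stats::as.dist(v))
  class(out) <- "dissimilarity_matrix"
  out
}

#' @export
print.dissimilarity_matrix <- function(x, ...) {
  cat(sprintf("%s dissimilarity over %d samples\n", x$index_name,
              length(x$sample_ids)))
  print(round(x$values, 4))
  invisible(x)
}

#' Venn partition of presence sets
#'
#' Exact region counts from set algebra on the presence sets of two or
#' three samples.
#'
#' @param matrix an `occupancy_matrix`.
#' @param set_ids two or three sample (column) names.
#' @return an object of class `venn_partition`: list with `set_ids`,
#'   `regions` (named counts: for 2 sets `unique_A`, `unique_B`,
#'   `shared`; for 3 sets the seven regions), `union_size`, `set_sizes`.
#' @export
venn_partition <- function(matrix, set_ids) {
  if (!all(set_ids %in% colnames(matrix))) {
    stop("unknown sample id(s): ",
         paste(setdiff(set_ids, colnames(matrix)), collapse = ", "),
         call. = FALSE)
  }
  k <- length(set_ids)
  if (k < 2L || k > 3L) {
    stop("venn_partition supports 2 or 3 sets", call. = FALSE)
  }
  sets <- lapply(set_ids, function(s) rownames(matrix)[matrix[, s] > 0])
  names(sets) <- set_ids
  if (k == 2L) {
    A <- sets[[1]]; B <- sets[[2]]
    regions <- c(length(setdiff(A, B)), length(setdiff(B, A)),
                 length(intersect(A, B)))
    names(regions) <- c(paste0("unique_", set_ids[1]),
                        paste0("unique_", set_ids[2]), "shared")
  } else {
    A <- sets[[1]]; B <- sets[[2]]; C <- sets[[3]]
    abc <- intersect(intersect(A, B), C)
    ab <- setdiff(intersect(A, B), C)
    ac <- setdiff(intersect(A, C), B)
    bc <- setdiff(intersect(B, C), A)
    ua <- setdiff(A, union(B, C))
    ub <- setdiff(B, union(A, C))
    uc <- setdiff(C, union(A, B))
    regions <- c(length(ua), length(ub), length(uc), length(ab),
                 length(ac), length(bc), length(abc))
    names(regions) <- c(paste0("unique_", set_ids),
                        paste(set_ids[1], set_ids[2], sep = "_"),
                        paste(set_ids[1], set_ids[3], sep = "_"),
                        paste(set_ids[2], set_ids[3], sep = "_"),
                        "all_shared")
  }
  out <- list(set_ids = set_ids, regions = regions,
              union_size = length(Reduce(union, sets)),
              set_sizes = lengths(sets))
  class(out) <- "venn_partition"
  out
}

#' @export
print.venn_partition <- function(x, ...) {
  cat(sprintf("Venn partition of %s (union %d)\n",
              paste(x$set_ids, collapse = ", "), x$union_size))
  print(x$regions)
  invisible(x)
}

#' Agglomerative dendrogram of samples
#'
#' Hierarchical clustering of the sample dissimilarity matrix (default:
#' average linkage / UPGMA). Samples are ordered lexicographically before
#' clustering so merge tie-breaks are deterministic. Branch lengths in the
#' Newick string correspond to merge heights.
#'
#' @param dissim a [binary_dissimilarity()] result (or a `dist`).
#' @param linkage linkage method for [stats::hclust()].
#' @return an object of class `sample_dendrogram`: list with `hclust`,
#'   `phylo` (an [ape] tree) and `newick` (text).
#' @export
sample_dendrogram <- function(dissim, linkage = "average") {
  d <- if (inherits(dissim, "dissimilarity_matrix")) dissim$d else
    stats::as.dist(dissim)
  if (attr(d, "Size") < 3L) {
    stop("dendrogram requires at least 3 samples", call. = FALSE)
  }
  if (any(!is.finite(d))) {
    stop("non-finite dissimilarities", call. = FALSE)
  }
  m <- as.matrix(d)
  ord <- order(rownames(m))
  d <- stats::as.dist(m[ord, ord])
  hc <- stats::hclust(d, method = linkage)
  ph <- ape::as.phylo(hc)
  out <- list(hclust = hc, phylo = ph,
              newick = ape::write.tree(ph))
  class(out) <- "sample_dendrogram"
  out
}

#' @export
print.sample_dendrogram <- function(x, ...) {
  cat("sample dendrogram:\n  ", x$newick, "\n")
  invisible(x)
}

#' Per-sample richness and uniqueness
#'
#' @param matrix an `occupancy_matrix`.
#' @return data.frame with `sample_id`, `n_genomes` (present genomes) and
#'   `n_unique` (genomes present in that sample only).
#' @export
richness_report <- function(matrix) {
  m <- unclass(matrix) > 0
  rs <- rowSums(m)
  data.frame(sample_id = colnames(m),
             n_genomes = unname(colSums(m)),
             n_unique = vapply(seq_len(ncol(m)), function(j)
               sum(m[, j] & rs == 1L), integer(1)),
             stringsAsFactors = FALSE)
}
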