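# Rotation/strand-normalized pairwise identities and dereplication at the
# species-level 95% nucleotide-identity cutoff.

# Global alignment identity between two nucleotide strings (one strand).
# Affine gaps (open 10, extend 0.5); terminal gap columns excluded from
# the denominator, internal gap columns count as mismatches.
align_identity_nt <- function(a, b, gap_open = 10, gap_ext = 0.5,
                              match = 1, mismatch = -1) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch,
                                                 baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = sm, gapOpening = gap_open, gapExtension = gap_ext)
  alignment_identity(as.character(Biostrings::alignedPattern(aln)),
                     as.character(Biostrings::alignedSubject(aln)))
}

# Global alignment identity between two proteins (BLOSUM62, open 11 / ext 1).
align_identity_aa <- function(a, b, gap_open = 11, gap_ext = 1,
                              substitution_matrix = "BLOSUM62") {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_ext)
  alignment_identity(as.character(Biostrings::alignedPattern(aln)),
                     as.character(Biostrings::alignedSubject(aln)))
}

#' Genome-wide pairwise nucleotide identity
#'
#' Global alignment identity between two circular genomes, maximized over
#' the strand of `b`. Genomes anchored at the MCP start codon are already
#' rotation-normalized; when either genome lacks an anchor set
#' `anchored = FALSE` and the identity is additionally maximized over a
#' coarse grid of `n_rotations` rotations of `b`. Identity is
#' matches / alignment columns (terminal gaps excluded, internal gap
#' columns counted in the denominator) x 100.
#'
#' @param a,b genomes (objects or nucleotide strings).
#' @param anchored are both genomes MCP-anchored (rotation already
#'   normalized)?
#' @param n_rotations rotation grid size for the unanchored fallback.
#' @param ... alignment parameters passed to the engine
#'   (`gap_open`, `gap_ext`, `match`, `mismatch`).
#' @return percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(a, b, anchored = TRUE, n_rotations = 36L, ...) {
  sa <- genome_sequence(a)
  sb <- genome_sequence(b)
  if (!nzchar(sa) || !nzchar(sb)) stop("empty sequence", call. = FALSE)
  cands <- if (anchored) c(0L) else {
    unique(as.integer(seq(0L, nchar(sb) - 1L,
                          length.out = min(n_rotations, nchar(sb)))))
  }
  best <- 0
  for (k in cands) {
    rb <- rotate_seq(sb, k)
    best <- max(best,
                align_identity_nt(sa, rb, ...),
                align_identity_nt(sa, revcomp(rb), ...))
  }
  best
}

# Unique k-mer set of a sequence (exact substrings).
kmer_set <- function(s, k = 15L) {
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(substring(s, 1:(n - k + 1L), k:n))
}

# Containment of the smaller k-mer set in the other. At >=95% identity a
# genome keeps well over 25% of its 15-mers intact even under worst-case
# substitution placement, while unrelated genomes share ~0%; the default
# 0.05 cutoff is therefore a conservative prescreen for the 95% decision.
kmer_containment <- function(ka, kb) {
  if (!length(ka) || !length(kb)) return(0)
  length(intersect(ka, kb)) / min(length(ka), length(kb))
}

#' Dereplicate genomes at a species-level identity cutoff
#'
#' Greedy centroid clustering: genomes are processed longest-first (ties
#' broken lexicographically by id); each genome joins the first existing
#' cluster whose representative it matches at or above
#' `cluster_identity_pct`, otherwise it founds a new cluster. Candidate
#' pairs are prescreened by exact 15-mer containment (both strands) and by
#' an ungapped equal-length comparison before paying for a full
#' affine-gap alignment, which does not change the decision at the 95%
#' cutoff (see the methods vignette).
#'
#' @param genomes a named list of genome objects or a named character
#'   vector of sequences (assumed rotation-normalized, e.g. MCP-anchored
#'   or sharing a common rotation).
#' @param thresholds a [microvir_thresholds()] object.
#' @param identities optional precomputed identity matrix (ids x ids);
#'   when supplied, alignment is skipped entirely.
#' @param kmer_prescreen containment below which a pair is skipped without
#'   alignment.
#' @param ... passed to [pairwise_identity()].
#' @return a list of clusters, each a list with `representative`,
#'   `members` (character vector, representative first) and
#'   `identity_to_rep` (named numeric vector).
#' @export
dereplicate <- function(genomes, thresholds = microvir_thresholds(),
                        identities = NULL, kmer_prescreen = 0.05, ...) {
  if (length(genomes) == 0L) stop("no genomes to dereplicate", call. = FALSE)
  seqs <- vapply(genomes, genome_sequence, character(1))
  ids <- names(genomes) %||% vapply(genomes, genome_id_of, character(1))
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) names(seqs) <- ids
  ids <- names(seqs)
  if (anyDuplicated(ids)) stop("duplicate genome ids", call. = FALSE)
  thr <- thresholds$cluster_identity_pct
  ord <- order(-nchar(seqs), ids)
  seqs <- seqs[ord]
  ids <- ids[ord]
  use_matrix <- !is.null(identities)
  if (!use_matrix) {
    kms <- lapply(seqs, kmer_set)
    kms_rc <- lapply(seqs, function(s) kmer_set(revcomp(s)))
  }
  clusters <- list()
  rep_ids <- character(0)
  pair_identity <- function(i_rep, i) {
    if (use_matrix) return(identities[ids[i_rep], ids[i]])
    cont <- max(kmer_containment(kms[[i_rep]], kms[[i]]),
                kmer_containment(kms[[i_rep]], kms_rc[[i]]))
    if (cont < kmer_prescreen) return(0)
    if (nchar(seqs[i_rep]) == nchar(seqs[i])) {
      ung <- 100 * (1 - hamming(seqs[i_rep], seqs[i]) / nchar(seqs[i]))
      if (ung >= thr) return(ung)   # gapped identity can only be >= this
    }
    pairwise_identity(seqs[i_rep], seqs[i], ...)
  }
  for (i in seq_along(seqs)) {
    joined <- FALSE
    for (ci in seq_along(clusters)) {
      idt <- pair_identity(clusters[[ci]]$rep_index, i)
      if (idt >= thr) {
        clusters[[ci]]$members <- c(clusters[[ci]]$members, ids[i])
        clusters[[ci]]$identity_to_rep <- c(clusters[[ci]]$identity_to_rep,
                                            setNames(idt, ids[i]))
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      clusters[[length(clusters) + 1L]] <- list(
        representative = ids[i], rep_index = i, members = ids[i],
        identity_to_rep = setNames(100, ids[i]))
    }
  }
  lapply(clusters, function(cl) {
    cl$rep_index <- NULL
    class(cl) <- "genome_cluster"
    cl
  })
}

#' @export
print.genome_cluster <- function(x, ...) {
  cat(sprintf("cluster %s: %d member(s)\n", x$representative,
              length(x$members)))
  invisible(x)
}

#' Cluster membership as a named vector
#'
#' @param clusters output of [dereplicate()].
#' @return named character vector: member id -> representative id.
#' @export
cluster_assignments <- function(clusters) {
  unlist(unname(lapply(clusters, function(cl)
    setNames(rep(cl$representative, length(cl$members)), cl$members))))
}

#' Pairwise amino-acid identity matrix for MCP proteins
#'
#' Global-alignment percent identity between every pair of proteins;
#' symmetric with a diagonal of 100. Feeds the novel-clade screen (MCPs
#' under 70% identity to every known reference).
#'
#' @param proteins named character vector (or data.frame with
#'   `protein_id`, `sequence`) of at least two amino-acid sequences.
#' @param ... passed to the protein alignment engine.
#' @return an object of class `identity_matrix`: list with `ids` and
#'   `values` (symmetric percent-identity matrix).
#' @export
mcp_identity_matrix <- function(proteins, ...) {
  if (is.data.frame(proteins)) {
    proteins <- setNames(proteins$sequence, proteins$protein_id)
  }
  if (length(proteins) < 2L) stop("need at least two proteins", call. = FALSE)
  ids <- names(proteins) %||% sprintf("protein%d", seq_along(proteins))
  n <- length(proteins)
  vals <- matrix(100, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      idt <- align_identity_aa(proteins[[i]], proteins[[j]], ...)
      vals[i, j] <- idt
      vals[j, i] <- idt
    }
  }
  out <- list(ids = ids, values = vals)
  class(out) <- "identity_matrix"
  out
}

#' @export
print.identity_matrix <- function(x, ...) {
  cat(sprintf("identity matrix over %d sequences\n", length(x$ids)))
  print(round(x$values, 1))
  invisible(x)
}
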