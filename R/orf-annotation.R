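# ORF calling on circular genomes, MCP identification against a reference
# panel, and reorientation of genomes to the MCP start codon.
#
# Internal coordinates are 0-based: `begin` is the forward-strand offset of
# the first base of the start codon as read on the ORF's own strand (for a
# minus-strand ORF this is the highest forward coordinate of its span).
# GFF3 output converts to 1-based inclusive.

# Scan one strand of a circular genome for maximal ORFs.
# `s` is the strand's 5'->3' sequence; coordinates are returned relative to
# that string and mapped back by the caller.
#
# The circle is unrolled three times and candidate start codons are taken
# from the middle copy: every such start has at least one full circle of
# upstream context (so its previous in-frame stop is visible, which the
# maximal-ORF rule needs) and one full circle downstream (so its stop is
# visible even when the ORF wraps the origin).
scan_orfs_one_strand <- function(s, min_aa, start_codons) {
  g <- nchar(s)
  if (g < 6L) {
    return(data.frame(a0 = integer(0), len_nt = integer(0),
                      protein = character(0)))
  }
  gc11 <- genetic_code_11()
  tripled <- paste0(s, s, s)
  out <- vector("list", 3L)
  for (f in 0:2) {
    idx <- seq.int(f + 1L, 3L * g - 2L, by = 3L)     # 1-based codon starts
    codons <- substring(tripled, idx, idx + 2L)
    aa <- unname(gc11[codons])                        # NA for fuzzy codons
    is_stop <- !is.na(aa) & aa == "*"
    is_start <- codons %in% start_codons
    stops_i <- which(is_stop)
    starts_i <- which(is_start)
    if (!length(stops_i) || !length(starts_i)) next
    # previous and next in-frame stop around each start codon
    prev <- findInterval(starts_i, stops_i)           # 0 = no previous stop
    nxt <- stops_i[prev + 1L]
    keep <- prev > 0L & !is.na(nxt)
    starts_i <- starts_i[keep]; nxt <- nxt[keep]
    if (!length(starts_i)) next
    # maximal ORF: first start codon after each previous stop
    first <- !duplicated(nxt)
    starts_i <- starts_i[first]; nxt <- nxt[first]
    a0 <- idx[starts_i] - 1L                          # 0-based on tripled
    b0 <- idx[nxt] - 1L
    len_nt <- b0 - a0 + 3L                            # includes stop codon
    n_aa <- (b0 - a0) %/% 3L
    keep <- a0 >= g & a0 < 2L * g & len_nt <= g & n_aa > min_aa
    if (!any(keep)) next
    a0 <- a0[keep]; b0 <- b0[keep]; len_nt <- len_nt[keep]
    starts_k <- starts_i[keep]; nxt_k <- nxt[keep]
    prot <- mapply(function(si, ei) {
      paste(aa[seq.int(si, ei - 1L)], collapse = "")
    }, starts_k, nxt_k, USE.NAMES = FALSE)
    if (!length(prot)) prot <- character(0)
    out[[f + 1L]] <- data.frame(a0 = a0 - g, len_nt = len_nt,
                                protein = as.character(prot),
                                stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(a0 = integer(0), len_nt = integer(0),
                      protein = character(0)))
  }
  do.call(rbind, out)
}

#' Call open reading frames on a circular genome
#'
#' Finds maximal ORFs on both strands of a circular nucleotide sequence:
#' for every in-frame stop codon, the ORF starting at the first start codon
#' after the previous stop. Origin-spanning ORFs are found by scanning the
#' doubled sequence and deduplicating. Only ORFs encoding strictly more
#' than `thresholds$orf_min_aa` amino acids (stop codon excluded) are
#' reported. Translation uses the standard bacterial genetic code
#' (table 11); start codons default to ATG only.
#'
#' @param genome a `unit_genome`/`microvir_genome` object or a nucleotide
#'   string.
#' @param thresholds a [microvir_thresholds()] object.
#' @param start_codons character vector of permitted start codons.
#' @return a data.frame with one row per ORF, sorted by `begin`:
#'   `orf_id`, `begin` (0-based forward offset of the start codon's first
#'   base on the ORF's strand), `strand` (`+`/`-`), `length_aa`,
#'   `length_nt` (including the stop codon), `wraps_origin`, `protein`.
#'   The genome id and length are attached as attributes.
#' @examples
#' th <- microvir_thresholds(orf_min_aa = 5)
#' g <- paste0("TAAATG", strrep("GCT", 9), "TAA", strrep("ACGT", 10))
#' call_orfs(g, th)
#' @export
call_orfs <- function(genome, thresholds = microvir_thresholds(),
                      start_codons = c("ATG")) {
  s <- genome_sequence(genome)
  gid <- genome_id_of(genome)
  g <- nchar(s)
  min_aa <- thresholds$orf_min_aa
  fwd <- scan_orfs_one_strand(s, min_aa, start_codons)
  rev <- scan_orfs_one_strand(revcomp(s), min_aa, start_codons)
  res <- data.frame(
    begin = c(fwd$a0, if (nrow(rev)) (g - 1L - rev$a0) else integer(0)),
    strand = c(rep("+", nrow(fwd)), rep("-", nrow(rev))),
    length_aa = c((fwd$len_nt - 3L) %/% 3L, (rev$len_nt - 3L) %/% 3L),
    length_nt = c(fwd$len_nt, rev$len_nt),
    protein = c(fwd$protein, rev$protein),
    stringsAsFactors = FALSE
  )
  res$wraps_origin <- ifelse(res$strand == "+",
                             res$begin + res$length_nt > g,
                             res$begin - res$length_nt + 1L < 0L)
  res <- res[order(res$begin, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  if (nrow(res)) res$orf_id <- sprintf("%s_orf%02d", gid, seq_len(nrow(res)))
  else res$orf_id <- character(0)
  res <- res[, c("orf_id", "begin", "strand", "length_aa", "length_nt",
                 "wraps_origin", "protein")]
  attr(res, "genome_id") <- gid
  attr(res, "genome_length") <- g
  res
}

#' Search a protein against a reference panel by local alignment
#'
#' Smith-Waterman local alignment of an ORF protein against every panel
#' member (BLOSUM62, affine gaps: open 11, extend 1). The best hit is the
#' maximum-score alignment, with ties broken by panel order. Percent
#' identity is matches / aligned columns x 100.
#'
#' @param orf_protein amino-acid string (nonempty).
#' @param panel a data.frame with columns `protein_id`, `sequence` and
#'   optionally `group_label` (see [synthetic_mcp_panel()] or
#'   [read_mcp_panel()]).
#' @param substitution_matrix name of the substitution matrix.
#' @param gap_open,gap_ext affine gap penalties (positive costs).
#' @param score_floor alignments scoring below this are reported as no-hit.
#' @return a list: `hit` (logical), and when `hit` is `TRUE`:
#'   `protein_id`, `group_label`, `score`, `identity_pct`.
#' @export
translated_search <- function(orf_protein, panel,
                              substitution_matrix = "BLOSUM62",
                              gap_open = 11, gap_ext = 1,
                              score_floor = 50) {
  if (!is.character(orf_protein) || length(orf_protein) != 1L ||
      !nzchar(orf_protein)) {
    stop("empty query protein", call. = FALSE)
  }
  if (is.null(panel) || nrow(panel) == 0L) stop("empty panel", call. = FALSE)
  q <- Biostrings::AAString(orf_protein)
  best <- NULL
  for (i in seq_len(nrow(panel))) {
    aln <- Biostrings::pairwiseAlignment(
      q, Biostrings::AAString(panel$sequence[i]), type = "local",
      substitutionMatrix = substitution_matrix,
      gapOpening = gap_open, gapExtension = gap_ext, scoreOnly = FALSE)
    sc <- Biostrings::score(aln)
    if (is.null(best) || sc > best$score) {
      best <- list(i = i, score = sc, aln = aln)
    }
  }
  if (best$score < score_floor) return(list(hit = FALSE, score = best$score))
  idt <- alignment_identity(
    as.character(Biostrings::alignedPattern(best$aln)),
    as.character(Biostrings::alignedSubject(best$aln)))
  list(hit = TRUE,
       protein_id = panel$protein_id[best$i],
       group_label = if ("group_label" %in% names(panel))
         panel$group_label[best$i] else NA_character_,
       score = best$score,
       identity_pct = idt)
}

#' Is an MCP a novel-clade candidate?
#'
#' Strict-threshold predicate: a candidate when best reference identity is
#' strictly below `thresholds$mcp_novelty_pct` (default 70%).
#'
#' @param identity_pct best panel identity (percent).
#' @param thresholds a [microvir_thresholds()] object.
#' @return logical.
#' @export
is_novel_mcp <- function(identity_pct, thresholds = microvir_thresholds()) {
  identity_pct < thresholds$mcp_novelty_pct
}

#' Identify the major capsid protein of a genome
#'
#' Scores every called ORF against the MCP reference panel; the MCP is the
#' ORF with the highest local-alignment score. If a decoy panel (e.g.
#' cellular proteins) is supplied and outscores the MCP panel, the genome
#' is excluded as a likely false positive. If no ORF hits either panel the
#' genome is routed to an "unclassified" bin.
#'
#' @param genome a unit genome object or nucleotide string.
#' @param orfs output of [call_orfs()] for `genome`.
#' @param panel MCP reference panel data.frame.
#' @param thresholds a [microvir_thresholds()] object.
#' @param decoy_panel optional decoy/cellular panel for the false-positive
#'   screen.
#' @param ... passed to [translated_search()].
#' @return an object of class `mcp_call`: a list with `genome_id`,
#'   `status` (`"ok"`, `"excluded"` or `"unclassified"`), `orf_index`,
#'   `orf_id`, `best_reference`, `best_identity_pct`, `score`,
#'   `group_label`, `novel_candidate`.
#' @export
identify_mcp <- function(genome, orfs, panel,
                         thresholds = microvir_thresholds(),
                         decoy_panel = NULL, ...) {
  gid <- genome_id_of(genome)
  if (is.null(orfs) || nrow(orfs) == 0L) {
    stop("identify_mcp requires at least one ORF", call. = FALSE)
  }
  hits <- lapply(orfs$protein, function(p)
    tryCatch(translated_search(p, panel, ...), error = function(e) list(hit = FALSE, score = -Inf)))
  scores <- vapply(hits, function(h) h$score %||% -Inf, numeric(1))
  hit_ok <- vapply(hits, function(h) isTRUE(h$hit), logical(1))
  res <- list(genome_id = gid)
  if (!any(hit_ok)) {
    res$status <- "unclassified"
    class(res) <- "mcp_call"
    return(res)
  }
  best_i <- which(hit_ok)[which.max(scores[hit_ok])]
  best <- hits[[best_i]]
  if (!is.null(decoy_panel) && nrow(decoy_panel)) {
    decoy_scores <- vapply(orfs$protein, function(p) {
      h <- tryCatch(translated_search(p, decoy_panel, ...),
                    error = function(e) list(score = -Inf))
      h$score %||% -Inf
    }, numeric(1))
    if (max(decoy_scores) > best$score) {
      res$status <- "excluded"
      res$decoy_score <- max(decoy_scores)
      res$mcp_score <- best$score
      class(res) <- "mcp_call"
      return(res)
    }
  }
  res$status <- "ok"
  res$orf_index <- best_i
  res$orf_id <- orfs$orf_id[best_i]
  res$best_reference <- best$protein_id
  res$best_identity_pct <- best$identity_pct
  res$score <- best$score
  res$group_label <- best$group_label
  res$novel_candidate <- is_novel_mcp(best$identity_pct, thresholds)
  class(res) <- "mcp_call"
  res
}

#' @export
print.mcp_call <- function(x, ...) {
  cat(sprintf("MCP call for %s: %s\n", x$genome_id, x$status))
  if (identical(x$status, "ok")) {
    cat(sprintf("  ORF %s -> %s (%s), identity %.1f%%, novel candidate: %s\n",
                x$orf_id, x$best_reference, x$group_label,
                x$best_identity_pct, x$novel_candidate))
  }
  invisible(x)
}

# Remap an ORF table through a rotation of the genome (new origin at
# 0-based offset k).
rotate_orfs <- function(orfs, k, g) {
  orfs$begin <- ((orfs$begin - k) %% g + g) %% g
  orfs$wraps_origin <- ifelse(orfs$strand == "+",
                              orfs$begin + orfs$length_nt > g,
                              orfs$begin - orfs$length_nt + 1L < 0L)
  orfs
}

# Remap an ORF table through reverse complementation of the genome.
revcomp_orfs <- function(orfs, g) {
  orfs$begin <- g - 1L - orfs$begin
  orfs$strand <- ifelse(orfs$strand == "+", "-", "+")
  orfs$wraps_origin <- ifelse(orfs$strand == "+",
                              orfs$begin + orfs$length_nt > g,
                              orfs$begin - orfs$length_nt + 1L < 0L)
  orfs
}

#' Anchor a genome to its MCP start codon
#'
#' Rotates (and, when the MCP lies on the minus strand, reverse
#' complements) a circular genome so that its sequence begins at the first
#' base of the MCP start codon on the plus strand. All ORF coordinates are
#' remapped consistently. Genome length is unchanged and the operation is
#' idempotent.
#'
#' @param genome a unit genome object or nucleotide string.
#' @param orfs ORF table from [call_orfs()].
#' @param mcp_orf row index (or `orf_id`) of the MCP in `orfs`.
#' @return a list with `genome` (same type as the input, re-oriented) and
#'   `orfs` (remapped table, re-sorted by `begin`).
#' @export
anchor_to_mcp <- function(genome, orfs, mcp_orf) {
  s <- genome_sequence(genome)
  g <- nchar(s)
  if (is.character(mcp_orf)) mcp_orf <- match(mcp_orf, orfs$orf_id)
  if (is.na(mcp_orf) || mcp_orf < 1L || mcp_orf > nrow(orfs)) {
    stop("mcp_orf must index a row of `orfs`", call. = FALSE)
  }
  mcp <- orfs[mcp_orf, ]
  if (mcp$strand == "-") {
    s <- revcomp(s)
    orfs <- revcomp_orfs(orfs, g)
    mcp_begin <- g - 1L - mcp$begin
  } else {
    mcp_begin <- mcp$begin
  }
  s <- rotate_seq(s, mcp_begin)
  orfs <- rotate_orfs(orfs, mcp_begin, g)
  ord <- order(orfs$begin, orfs$strand)
  orfs <- orfs[ord, , drop = FALSE]
  rownames(orfs) <- NULL
  attr(orfs, "genome_id") <- genome_id_of(genome)
  attr(orfs, "genome_length") <- g
  attr(orfs, "anchored") <- TRUE
  list(genome = replace_sequence(genome, s), orfs = orfs)
}
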