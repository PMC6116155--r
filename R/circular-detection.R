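# Circular contig identification via terminal direct repeats, trimming to
# unit-length genomes, and the size filter.

#' Detect a terminal direct repeat on a contig
#'
#' A contig assembled across a circular template carries a direct repeat:
#' its first `L` bases reappear as its last `L` bases. The detector uses
#' an exact-seed-and-extend strategy: the contig's first `min_repeat_nt`
#' bases are matched (allowing one mismatch) across the contig; every
#' match that runs to the contig end defines a candidate repeat, the
#' candidate is verified over its full length, and the longest repeat
#' whose mismatch fraction is at most `max_mismatch_rate` wins. Candidate
#' length is capped at half the contig so the two copies cannot overlap.
#' Degenerate bases (N) count as mismatches.
#'
#' @param contig nucleotide string (optionally named with the contig id).
#' @param thresholds a [microvir_thresholds()] object
#'   (`min_repeat_nt`, `max_mismatch_rate`).
#' @param contig_id identifier; defaults to the name of `contig` if any.
#' @return an object of class `circular_contig` when a repeat is found:
#'   list with `contig_id`, `sequence`, `repeat_length`,
#'   `repeat_mismatches`, `circular = TRUE`. Otherwise a list with
#'   `circular = FALSE` and a `reason`.
#' @examples
#' g <- strrep("ACGTT", 500)
#' # not a good example sequence for repeats (it is periodic); use random:
#' set.seed(1)
#' circle <- paste(sample(c("A","C","G","T"), 2000, TRUE), collapse = "")
#' contig <- make_assembly_contig(circle, overrun_nt = 60)
#' detect_terminal_repeat(contig)$repeat_length
#' @export
detect_terminal_repeat <- function(contig,
                                   thresholds = microvir_thresholds(),
                                   contig_id = NULL) {
  s <- genome_sequence(contig)
  contig_id <- contig_id %||%
    (if (!is.null(names(contig)) && nzchar(names(contig)[1])) names(contig)[1]
     else "contig")
  n <- nchar(s)
  min_rep <- thresholds$min_repeat_nt
  rate <- thresholds$max_mismatch_rate
  if (n < 2L * min_rep) {
    return(list(circular = FALSE, contig_id = contig_id,
                reason = sprintf("contig shorter than 2 x min_repeat_nt (%d nt)",
                                 2L * min_rep)))
  }
  seed <- substr(s, 1L, min_rep)
  subject <- Biostrings::DNAString(s)
  m <- Biostrings::matchPattern(seed, subject, max.mismatch = 1L,
                                fixed = TRUE)
  starts <- BiocGenerics::start(m)
  # a repeat of length L starts at position p = n - L + 1
  starts <- starts[starts >= 2L]
  L <- n - starts + 1L
  keep <- L >= min_rep & L <= n %/% 2L
  starts <- starts[keep]
  L <- L[keep]
  if (length(L)) {
    ord <- order(L, decreasing = TRUE)   # longest qualifying repeat wins
    chars <- seq_chars(s)
    for (i in ord) {
      p <- starts[i]
      len <- L[i]
      pre <- chars[seq_len(len)]
      suf <- chars[p:n]
      mism <- sum(pre != suf | pre == "N" | suf == "N")
      if (mism / len <= rate) {
        out <- list(contig_id = contig_id, sequence = s,
                    repeat_length = len, repeat_mismatches = mism,
                    circular = TRUE)
        class(out) <- "circular_contig"
        return(out)
      }
    }
  }
  list(circular = FALSE, contig_id = contig_id,
       reason = sprintf("no terminal direct repeat >= %d nt within mismatch rate %.3f",
                        min_rep, rate))
}

#' @export
print.circular_contig <- function(x, ...) {
  cat(sprintf("circular contig %s: %d nt, terminal repeat %d nt (%d mismatches)\n",
              x$contig_id, nchar(x$sequence), x$repeat_length,
              x$repeat_mismatches))
  invisible(x)
}

#' Trim a circular contig to a unit-length genome
#'
#' Removes the trailing copy of the terminal direct repeat, leaving one
#' full traversal of the circle. The unit genome keeps the contig's
#' starting rotation; canonical orientation happens later at MCP
#' anchoring.
#'
#' @param circ a `circular_contig` from [detect_terminal_repeat()].
#' @param genome_id identifier for the unit genome (default: derived from
#'   the contig id).
#' @return an object of class `unit_genome`: list with `genome_id`,
#'   `sequence`, `length_nt`, `source_contig`.
#' @export
trim_to_unit <- function(circ, genome_id = NULL) {
  if (!inherits(circ, "circular_contig") || !isTRUE(circ$circular)) {
    stop("trim_to_unit requires a circular contig; ",
         "non-circular contigs are rejected", call. = FALSE)
  }
  n <- nchar(circ$sequence)
  unit <- substr(circ$sequence, 1L, n - circ$repeat_length)
  out <- list(genome_id = genome_id %||% sub("_contig$", "", circ$contig_id),
              sequence = unit, length_nt = nchar(unit),
              source_contig = circ$contig_id)
  class(out) <- "unit_genome"
  out
}

#' @export
print.unit_genome <- function(x, ...) {
  cat(sprintf("unit genome %s: %d nt (from %s)\n",
              x$genome_id, x$length_nt, x$source_contig))
  invisible(x)
}

#' Apply the genome size filter
#'
#' Admits unit genomes whose length lies within
#' `[size_min_nt, size_max_nt]`, both bounds inclusive; rejections are
#' logged with their lengths.
#'
#' @param units a list of `unit_genome` objects.
#' @param thresholds a [microvir_thresholds()] object.
#' @return a list with `admitted` (list of unit genomes) and `rejected`
#'   (data.frame with `genome_id`, `length_nt`, `reason`).
#' @export
size_filter <- function(units, thresholds = microvir_thresholds()) {
  lens <- vapply(units, function(u) as.integer(u$length_nt), integer(1))
  ids <- vapply(units, function(u) u$genome_id, character(1))
  ok <- lens >= thresholds$size_min_nt & lens <= thresholds$size_max_nt
  rejected <- data.frame(
    genome_id = ids[!ok], length_nt = lens[!ok],
    reason = ifelse(lens[!ok] < thresholds$size_min_nt,
                    sprintf("below %d nt", thresholds$size_min_nt),
                    sprintf("above %d nt", thresholds$size_max_nt)),
    stringsAsFactors = FALSE)
  list(admitted = units[ok], rejected = rejected)
}
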