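# Read recruitment -> breadth of coverage -> binary presence calls.
# Depth is recorded but never used for presence (read counts from
# RCA-amplified ssDNA viromes are not quantitative).

#' Recruit reads against a genome by exact matching
#'
#' Maps each read as an exact substring of the circular genome (both
#' strands, origin wrap allowed); a read covers every position of every
#' exact match. Breadth is the fraction of genome positions covered by at
#' least one read. This mapper is the in-package stand-in for an external
#' aligner on error-free synthetic reads; use [read_sam_coverage()] to
#' import real alignments.
#'
#' @param reads character vector of reads (may be empty).
#' @param genome genome object or nucleotide string.
#' @param sample_id sample the reads came from.
#' @param genome_id genome identifier (default: from `genome`).
#' @return an object of class `coverage_profile`: list with `genome_id`,
#'   `sample_id`, `covered_positions`, `genome_length`, `breadth`,
#'   `mean_depth`, `depth` (integer vector).
#' @export
recruit_reads <- function(reads, genome, sample_id = "sample",
                          genome_id = NULL) {
  s <- genome_sequence(genome)
  g <- nchar(s)
  genome_id <- genome_id %||% genome_id_of(genome)
  depth <- integer(g)
  if (length(reads)) {
    doubled <- Biostrings::DNAString(paste0(s, s))
    for (rd in reads) {
      r <- nchar(rd)
      if (r > g) {
        warning("read longer than genome skipped (", r, " > ", g, " nt)",
                call. = FALSE)
        next
      }
      for (q in unique(c(rd, revcomp(rd)))) {
        m <- Biostrings::matchPattern(q, doubled)
        starts <- BiocGenerics::start(m)
        starts <- starts[starts <= g]   # dedupe wrap copies
        for (s0 in starts) {
          idx <- (s0 - 1L + 0:(r - 1L)) %% g + 1L
          depth[idx] <- depth[idx] + 1L
        }
      }
    }
  }
  covered <- sum(depth > 0L)
  out <- list(genome_id = genome_id, sample_id = sample_id,
              covered_positions = covered, genome_length = g,
              breadth = covered / g, mean_depth = sum(depth) / g,
              depth = depth)
  class(out) <- "coverage_profile"
  out
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("%s in %s: breadth %.3f (%d/%d positions), mean depth %.1fx\n",
              x$genome_id, x$sample_id, x$breadth, x$covered_positions,
              x$genome_length, x$mean_depth))
  invisible(x)
}

#' Call presence from breadth of coverage
#'
#' A genome is present in a sample when reads cover strictly more than
#' `breadth_present` (default 75%) of its positions. Depth plays no role.
#'
#' @param profile a `coverage_profile`.
#' @param thresholds a [microvir_thresholds()] object.
#' @return `1L` (present) or `0L` (absent).
#' @export
call_presence <- function(profile, thresholds = microvir_thresholds()) {
  stopifnot(inherits(profile, "coverage_profile"))
  if (profile$breadth > thresholds$breadth_present) 1L else 0L
}

#' Build the binary occupancy matrix
#'
#' Assembles presence calls into a genomes x samples binary matrix over
#' the full grid; (genome, sample) pairs without a profile are 0.
#'
#' @param profiles list of `coverage_profile` objects (at most one per
#'   genome/sample pair; duplicates are an error).
#' @param thresholds a [microvir_thresholds()] object.
#' @param genome_ids,sample_ids optional full row/column label sets (e.g.
#'   to include genomes never seen in any sample).
#' @return an object of class `occupancy_matrix` (a binary integer matrix
#'   with genome rows and sample columns).
#' @export
build_occupancy <- function(profiles, thresholds = microvir_thresholds(),
                            genome_ids = NULL, sample_ids = NULL) {
  gids <- vapply(profiles, function(p) p$genome_id, character(1))
  sids <- vapply(profiles, function(p) p$sample_id, character(1))
  if (anyDuplicated(paste(gids, sids, sep = "\r"))) {
    dup <- paste(gids, sids)[duplicated(paste(gids, sids, sep = "\r"))]
    stop("duplicate (genome, sample) profiles: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  genome_ids <- genome_ids %||% sort(unique(gids))
  sample_ids <- sample_ids %||% sort(unique(sids))
  if (!all(gids %in% genome_ids) || !all(sids %in% sample_ids)) {
    stop("profiles reference genomes/samples outside the provided grid",
         call. = FALSE)
  }
  m <- matrix(0L, length(genome_ids), length(sample_ids),
              dimnames = list(genome_ids, sample_ids))
  for (p in profiles) {
    m[p$genome_id, p$sample_id] <- call_presence(p, thresholds)
  }
  class(m) <- c("occupancy_matrix", class(m))
  m
}

#' @export
print.occupancy_matrix <- function(x, ...) {
  cat(sprintf("occupancy matrix: %d genomes x %d samples, %d presences\n",
              nrow(x), ncol(x), sum(x)))
  print(unclass(x))
  invisible(x)
}
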