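#' Pipeline thresholds
#'
#' Bundles every cutoff the pipeline uses into one validated object.
#' Defaults follow the conventions of microvirus virome studies:
#' circular contigs between 1 and 8 kb are considered, ORFs must encode
#' proteins of more than 80 amino acids, genomes are dereplicated at the
#' 95% nucleotide-identity phage species demarcation, a genome is called
#' present in a sample when reads cover strictly more than 75% of its
#' positions, and an MCP sharing less than 70% amino-acid identity with
#' its best reference is flagged as a novel-clade candidate.
#'
#' @param size_min_nt,size_max_nt inclusive admission bounds (nt) for unit
#'   genomes.
#' @param min_repeat_nt minimum terminal direct repeat length (nt) for a
#'   contig to be called circular.
#' @param max_mismatch_rate maximum mismatch fraction tolerated inside a
#'   terminal repeat.
#' @param orf_min_aa ORFs must encode strictly more than this many amino
#'   acids (stop codon excluded).
#' @param cluster_identity_pct genomes join a cluster at or above this
#'   genome-wide percent identity.
#' @param breadth_present a genome is present when breadth of coverage is
#'   strictly greater than this fraction.
#' @param mcp_novelty_pct an MCP is a novel-clade candidate when its best
#'   reference identity is strictly below this percentage.
#' @param mcp_screen_evalue,nr_screen_evalue e-value cutoffs applied when
#'   importing external BLAST tabular hits (the in-package protein search
#'   uses a raw score floor instead).
#' @return an object of class `microvir_thresholds` (a named list).
#' @examples
#' th <- microvir_thresholds()
#' th$cluster_identity_pct
#' @export
microvir_thresholds <- function(size_min_nt = 1000L,
                                size_max_nt = 8000L,
                                min_repeat_nt = 10L,
                                max_mismatch_rate = 0.02,
                                orf_min_aa = 80L,
                                cluster_identity_pct = 95.0,
                                breadth_present = 0.75,
                                mcp_novelty_pct = 70.0,
                                mcp_screen_evalue = 1e-4,
                                nr_screen_evalue = 1e-3) {
  th <- list(
    size_min_nt = as.integer(size_min_nt),
    size_max_nt = as.integer(size_max_nt),
    min_repeat_nt = as.integer(min_repeat_nt),
    max_mismatch_rate = max_mismatch_rate,
    orf_min_aa = as.integer(orf_min_aa),
    cluster_identity_pct = cluster_identity_pct,
    breadth_present = breadth_present,
    mcp_novelty_pct = mcp_novelty_pct,
    mcp_screen_evalue = mcp_screen_evalue,
    nr_screen_evalue = nr_screen_evalue
  )
  class(th) <- "microvir_thresholds"
  validate_thresholds(th)
  th
}

#' Validate a thresholds object
#'
#' @param th a `microvir_thresholds` object (or plain named list).
#' @return `th`, invisibly, if valid; otherwise an error describing the
#'   offending field.
#' @export
validate_thresholds <- function(th) {
  chk <- function(cond, msg) if (!cond) stop("invalid thresholds: ", msg, call. = FALSE)
  chk(is_scalar_number(th$size_min_nt) && is_scalar_number(th$size_max_nt) &&
        th$size_min_nt < th$size_max_nt,
      "size_min_nt must be < size_max_nt")
  chk(th$size_min_nt > 0, "size_min_nt must be positive")
  chk(is_scalar_number(th$min_repeat_nt) && th$min_repeat_nt >= 1,
      "min_repeat_nt must be >= 1")
  chk(is_scalar_number(th$max_mismatch_rate) &&
        th$max_mismatch_rate >= 0 && th$max_mismatch_rate < 1,
      "max_mismatch_rate must be in [0, 1)")
  chk(is_scalar_number(th$orf_min_aa) && th$orf_min_aa >= 1,
      "orf_min_aa must be >= 1")
  for (f in c("cluster_identity_pct", "mcp_novelty_pct")) {
    chk(is_scalar_number(th[[f]]) && th[[f]] > 0 && th[[f]] < 100,
        paste(f, "must be in (0, 100)"))
  }
  chk(is_scalar_number(th$breadth_present) &&
        th$breadth_present > 0 && th$breadth_present < 1,
      "breadth_present must be in (0, 1)")
  for (f in c("mcp_screen_evalue", "nr_screen_evalue")) {
    chk(is_scalar_number(th[[f]]) && th[[f]] > 0, paste(f, "must be > 0"))
  }
  invisible(th)
}

#' @export
print.microvir_thresholds <- function(x, ...) {
  cat("microvir thresholds:\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
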