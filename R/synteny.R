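# Gene-order fingerprints of MCP-anchored genomes and counts of distinct
# genome organizations per phylogenetic group.

#' Reduce an anchored genome to a synteny fingerprint
#'
#' Orders the family labels of every ORF by start-codon position from the
#' MCP (overlapping genes are ordered by their start codons), so two
#' genomes with the same gene plan but different intergenic spacing yield
#' identical fingerprints. ORFs without a family assignment are rendered
#' `"HYP"`. By default strand is recorded (a trailing `-` marks
#' minus-strand genes) but ignored when fingerprints are compared; set
#' `include_strand = TRUE` to make strand part of the fingerprint.
#'
#' @param genome an anchored genome (object or string); used for error
#'   checking only.
#' @param orfs ORF table from [call_orfs()] after [anchor_to_mcp()], with
#'   a `family_label` column (add one from MCP calls / panel hits; missing
#'   or NA labels become `"HYP"`).
#' @param group_label phylogenetic group of the genome (optional).
#' @param include_strand include strand in the comparable label sequence.
#' @return an object of class `synteny_fingerprint`: list with
#'   `genome_id`, `labels`, `strands`, `group_label` and `key` (the
#'   comparable label string).
#' @export
synteny_fingerprint <- function(genome, orfs, group_label = NA_character_,
                                include_strand = FALSE) {
  if (is.null(orfs) || nrow(orfs) == 0L) {
    stop("fingerprint requires at least one labeled ORF", call. = FALSE)
  }
  labels <- if ("family_label" %in% names(orfs)) orfs$family_label
            else rep(NA_character_, nrow(orfs))
  labels[is.na(labels) | !nzchar(labels)] <- "HYP"
  ord <- order(orfs$begin, orfs$strand)
  labels <- labels[ord]
  strands <- orfs$strand[ord]
  if (labels[1] != "MCP" || orfs$begin[ord][1] != 0L) {
    stop("genome is not MCP-anchored: first ORF must be the MCP at ",
         "position 0", call. = FALSE)
  }
  key_labels <- if (include_strand) {
    paste0(labels, ifelse(strands == "-", "-", ""))
  } else labels
  out <- list(genome_id = genome_id_of(genome), labels = labels,
              strands = strands, group_label = group_label,
              key = paste(key_labels, collapse = "|"))
  class(out) <- "synteny_fingerprint"
  out
}

#' @export
print.synteny_fingerprint <- function(x, ...) {
  cat(sprintf("%s [%s]: %s\n", x$genome_id,
              x$group_label %||% NA, x$key))
  invisible(x)
}

#' Count distinct genome organizations per group
#'
#' @param fingerprints a list of [synteny_fingerprint()] objects.
#' @param group_assignments optional named character vector
#'   (genome id -> group) overriding the fingerprints' own `group_label`.
#' @return a data.frame with `group` and `n_organizations` (number of
#'   distinct label sequences), one row per group, ordered by group;
#'   groups present in `group_assignments` but without fingerprints get a
#'   count of 0.
#' @export
count_organizations <- function(fingerprints, group_assignments = NULL) {
  ids <- vapply(fingerprints, function(f) f$genome_id, character(1))
  keys <- vapply(fingerprints, function(f) f$key, character(1))
  groups <- vapply(fingerprints, function(f)
    as.character(f$group_label %||% NA), character(1))
  if (!is.null(group_assignments)) {
    groups <- unname(group_assignments[ids])
  }
  if (anyNA(groups)) {
    stop("every fingerprint needs a group label", call. = FALSE)
  }
  all_groups <- sort(unique(c(groups,
                              if (!is.null(group_assignments))
                                unique(unname(group_assignments)))))
  counts <- vapply(all_groups, function(g)
    length(unique(keys[groups == g])), integer(1))
  data.frame(group = all_groups, n_organizations = unname(counts),
             stringsAsFactors = FALSE)
}
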