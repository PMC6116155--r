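# Internal sequence helpers shared across modules.

#' @importFrom Biostrings DNAString DNAStringSet AAString AAStringSet
#'   reverseComplement getGeneticCode matchPattern pairwiseAlignment
#'   alignedPattern alignedSubject readBStringSet writeXStringSet translate
#' @importFrom stats setNames runif hclust as.dist cophenetic
#' @importFrom utils read.delim write.table head tail
NULL

# Genetic code: standard bacterial/archaeal/plant-plastid code (table 11).
genetic_code_11 <- function() Biostrings::getGeneticCode("11")

stop_codons <- function() {
  gc11 <- genetic_code_11()
  names(gc11)[gc11 == "*"]
}

# Synonymous codons per amino acid, stop codons excluded.
codon_table <- function() {
  gc11 <- genetic_code_11()
  split(names(gc11)[gc11 != "*"], gc11[gc11 != "*"])
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

rand_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Reverse complement of a nucleotide string
#'
#' @param x a single nucleotide string (IUPAC letters).
#' @return the reverse complement as a character scalar.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Rotate a circular sequence so that 0-based position `k` becomes position 0.
rotate_seq <- function(x, k) {
  n <- nchar(x)
  k <- ((k %% n) + n) %% n
  if (k == 0) return(x)
  paste0(substr(x, k + 1L, n), substr(x, 1L, k))
}

# Are two circular sequences the same circle (any rotation, either strand)?
# Uses the classic doubled-string containment test.
rotation_equivalent <- function(a, b) {
  if (nchar(a) != nchar(b)) return(FALSE)
  doubled <- paste0(a, a)
  grepl(b, doubled, fixed = TRUE) || grepl(revcomp(b), doubled, fixed = TRUE)
}

# Count mismatching positions between two equal-length strings.
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(seq_chars(a) != seq_chars(b))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Accessors that let most operations take either a classed genome object
# or a bare nucleotide string.
genome_sequence <- function(x) {
  if (is.character(x)) return(unname(x[[1L]]))
  if (is.list(x) && !is.null(x$sequence)) return(x$sequence)
  stop("cannot extract a sequence from this object", call. = FALSE)
}

genome_id_of <- function(x) {
  if (is.list(x)) {
    return(x$genome_id %||% x$id %||% "genome")
  }
  if (!is.null(names(x)) && nzchar(names(x)[1L])) return(names(x)[1L])
  "genome"
}

replace_sequence <- function(x, s) {
  if (is.character(x)) {
    out <- s
    names(out) <- names(x)
    return(out)
  }
  x$sequence <- s
  if (!is.null(x$length_nt)) x$length_nt <- nchar(s)
  x
}

# Percent identity from two aligned (gapped) strings of equal length:
# terminal gap columns are excluded from the denominator; internal gap
# columns count as mismatches.
alignment_identity <- function(p, s) {
  pc <- seq_chars(p)
  sc <- seq_chars(s)
  stopifnot(length(pc) == length(sc))
  gap <- pc == "-" | sc == "-"
  keep <- which(!gap)
  if (!length(keep)) return(0)
  cols <- seq.int(min(keep), max(keep))  # trim terminal gap columns
  100 * sum(pc[cols] == sc[cols] & !gap[cols]) / length(cols)
}
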