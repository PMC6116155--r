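# Synthetic microvirus-like data: circular genomes with planted genes,
# assembly-style contigs with terminal direct repeats, point-mutation
# variants, and per-sample read coverage with controllable breadth.

aa_alphabet <- function() {
  setdiff(sort(unique(unname(genetic_code_11()))), "*")
}

#' Describe a genome to be generated
#'
#' A template fixes the genome length, the ordered gene plan and the seed,
#' so that [generate_genome()] is reproducible byte-for-byte.
#'
#' @param id genome identifier.
#' @param length_nt genome length in nucleotides.
#' @param gene_plan data.frame with columns `family` (exactly one row must
#'   be `"MCP"`), `length_aa` and `strand` (`+`/`-`).
#' @param seed integer RNG seed.
#' @param length_range permitted genome size envelope (nt); the default
#'   3,900-5,800 matches complete microvirus genomes. Use `NULL` to skip
#'   the range check (e.g. for small toys in unit tests).
#' @return an object of class `genome_template`.
#' @examples
#' plan <- data.frame(family = c("MCP", "REP"), length_aa = c(500, 300),
#'                    strand = c("+", "+"))
#' genome_template("CGM001", 4300, plan, seed = 7)
#' @export
genome_template <- function(id, length_nt, gene_plan, seed,
                            length_range = c(3900L, 5800L)) {
  stopifnot(is.character(id), length(id) == 1L)
  length_nt <- as.integer(length_nt)
  if (!is.null(length_range) &&
      (length_nt < length_range[1] || length_nt > length_range[2])) {
    stop(sprintf("length_nt %d outside permitted range [%d, %d]",
                 length_nt, length_range[1], length_range[2]), call. = FALSE)
  }
  gene_plan <- as.data.frame(gene_plan, stringsAsFactors = FALSE)
  stopifnot(all(c("family", "length_aa", "strand") %in% names(gene_plan)))
  if (sum(gene_plan$family == "MCP") != 1L) {
    stop("gene_plan must contain exactly one MCP gene", call. = FALSE)
  }
  if (!all(gene_plan$strand %in% c("+", "-"))) {
    stop("gene strands must be '+' or '-'", call. = FALSE)
  }
  structure(list(id = id, length_nt = length_nt,
                 gene_plan = gene_plan, seed = as.integer(seed)),
            class = "genome_template")
}

# Back-translate a protein with uniformly random synonymous codons.
codons_for_protein <- function(protein) {
  tab <- codon_table()
  aa <- seq_chars(protein)
  vapply(aa, function(a) {
    opts <- tab[[a]]
    if (is.null(opts)) stop("unknown amino acid: ", a, call. = FALSE)
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1), USE.NAMES = FALSE)
}

random_protein <- function(length_aa) {
  alpha <- aa_alphabet()
  paste(c("M", sample(alpha, length_aa - 1L, replace = TRUE)), collapse = "")
}

# Substitute exactly round(fraction * length) residues of a protein to a
# different amino acid; the initiator methionine is kept.
mutate_protein <- function(protein, fraction) {
  aa <- seq_chars(protein)
  n <- length(aa)
  k <- round(fraction * n)
  if (k == 0L) return(protein)
  pos <- sample(2:n, k)   # keep the initiator Met
  alpha <- aa_alphabet()
  for (p in pos) aa[p] <- sample(setdiff(alpha, aa[p]), 1L)
  paste(aa, collapse = "")
}

# One realization attempt for generate_genome (runs inside the seed scope).
realize_genome <- function(template, proteins) {
  plan <- template$gene_plan
  n <- nrow(plan)
  prots <- character(n)
  for (i in seq_len(n)) {
    fam <- plan$family[i]
    if (!is.null(proteins[[fam]])) {
      prots[i] <- proteins[[fam]]
      if (substr(prots[i], 1, 1) != "M") {
        stop("supplied protein for ", fam, " must start with M", call. = FALSE)
      }
      if (nchar(prots[i]) != plan$length_aa[i]) {
        plan$length_aa[i] <- nchar(prots[i])
      }
    } else {
      prots[i] <- random_protein(plan$length_aa[i])
    }
  }
  # cassette = in-frame guard stop + coding codons + stop codon
  cass_len <- 3L * plan$length_aa + 6L
  total_gap <- template$length_nt - sum(cass_len)
  if (total_gap < 0L) {
    stop(sprintf(
      "sizing error: gene plan needs %d nt but genome length is %d nt",
      sum(cass_len), template$length_nt), call. = FALSE)
  }
  gaps <- if (n > 0L) drop(stats::rmultinom(1L, total_gap, rep(1, n))) else total_gap
  stops <- stop_codons()
  pieces <- character(0)
  begins <- integer(n)
  cursor <- 0L
  for (i in seq_len(n)) {
    cassette <- paste0(sample(stops, 1L),
                       paste(codons_for_protein(prots[i]), collapse = ""),
                       sample(stops, 1L))
    if (plan$strand[i] == "+") {
      begins[i] <- cursor + 3L
      pieces <- c(pieces, cassette)
    } else {
      begins[i] <- cursor + nchar(cassette) - 4L
      pieces <- c(pieces, revcomp(cassette))
    }
    cursor <- cursor + nchar(cassette)
    filler <- rand_dna(gaps[i])
    pieces <- c(pieces, filler)
    cursor <- cursor + gaps[i]
  }
  seqn <- paste(pieces, collapse = "")
  truth <- data.frame(
    family = plan$family, strand = plan$strand, begin = begins,
    length_aa = plan$length_aa, length_nt = 3L * (plan$length_aa + 1L),
    protein = prots, stringsAsFactors = FALSE)
  list(sequence = seqn, truth = truth, plan = plan)
}

orf_key <- function(df) {
  if (!nrow(df)) return(character(0))
  sprintf("%d:%s:%d", df$begin, df$strand, df$length_aa)
}

#' Generate a circular microvirus-like genome
#'
#' Realizes a [genome_template()]: each planted gene becomes an intact ORF
#' (ATG start, in-frame stop, no internal stops), preceded by an in-frame
#' "guard" stop codon so that the maximal-ORF convention of [call_orfs()]
#' recovers the planted start exactly. Intergenic filler is uniform random
#' A/C/G/T. The realization is resampled (drawing fresh randomness from
#' the same seeded stream) until the set of called ORFs above the length
#' threshold equals the planted set, so truth annotations are exactly
#' recoverable.
#'
#' @param template a [genome_template()].
#' @param proteins optional named list mapping a family label to a fixed
#'   amino-acid sequence (e.g. an MCP drawn from a reference panel);
#'   families not listed get a random protein.
#' @param thresholds thresholds used for the recoverability check.
#' @param start_codons permitted start codons (ATG only by default).
#' @param max_tries maximum number of realization attempts.
#' @return an object of class `microvir_genome`: a list with `id`,
#'   `sequence`, `length_nt`, `truth` (data.frame of planted ORFs in the
#'   same coordinate convention as [call_orfs()]), `plan`, `seed`.
#' @export
generate_genome <- function(template, proteins = NULL,
                            thresholds = microvir_thresholds(),
                            start_codons = c("ATG"),
                            max_tries = 300L) {
  stopifnot(inherits(template, "genome_template"))
  with_seed(template$seed, {
    for (try in seq_len(max_tries)) {
      r <- realize_genome(template, proteins)
      called <- call_orfs(r$sequence, thresholds, start_codons)
      visible <- r$truth[r$truth$length_aa > thresholds$orf_min_aa, ,
                         drop = FALSE]
      if (setequal(orf_key(called), orf_key(visible))) {
        out <- list(id = template$id, sequence = r$sequence,
                    length_nt = nchar(r$sequence), truth = r$truth,
                    plan = r$plan, seed = template$seed)
        class(out) <- "microvir_genome"
        return(out)
      }
    }
    stop("could not realize a cleanly recoverable genome in ",
         max_tries, " attempts", call. = FALSE)
  })
}

#' @export
print.microvir_genome <- function(x, ...) {
  cat(sprintf("microvirus-like genome %s: %d nt, %d planted genes (%s)\n",
              x$id, x$length_nt, nrow(x$truth),
              paste(x$truth$family, collapse = ", ")))
  invisible(x)
}

#' Turn a circular genome into an assembly-style linear contig
#'
#' Emulates an assembler overrunning a circular template: the contig is a
#' rotation of the genome starting at `start_offset`, extended by its own
#' first `overrun_nt` bases, which creates the terminal direct repeat that
#' [detect_terminal_repeat()] must find and [trim_to_unit()] must undo.
#'
#' @param genome a `microvir_genome` or nucleotide string.
#' @param overrun_nt repeat length in nt; must satisfy
#'   `0 <= overrun_nt < genome length`.
#' @param start_offset 0-based rotation offset.
#' @return the contig as a character scalar of length
#'   `genome length + overrun_nt`.
#' @export
make_assembly_contig <- function(genome, overrun_nt, start_offset = 0L) {
  s <- genome_sequence(genome)
  g <- nchar(s)
  overrun_nt <- as.integer(overrun_nt)
  if (overrun_nt < 0L || overrun_nt >= g) {
    stop("overrun_nt must be in [0, genome length)", call. = FALSE)
  }
  rotated <- rotate_seq(s, start_offset)
  paste0(rotated, substr(rotated, 1L, overrun_nt))
}

#' Introduce point mutations into a genome
#'
#' Substitutes exactly `round(substitution_fraction * length)` positions,
#' chosen without replacement under `seed`, each to a different base. By
#' default (when the input carries truth annotations) substitutions avoid
#' planted start/stop/guard codons and never create a premature in-frame
#' stop inside a planted gene, so truth annotations remain recoverable on
#' the variant; set `protect_planted = FALSE` for unconstrained mutation.
#'
#' @param genome a `microvir_genome` or nucleotide string.
#' @param substitution_fraction fraction of positions to substitute, in
#'   `[0, 0.5]`.
#' @param seed RNG seed (`NULL` draws from the current RNG stream).
#' @param protect_planted protect planted-gene codon structure (ignored
#'   when the input has no truth annotation).
#' @param id identifier for the variant (object input only).
#' @return same type as the input, with the mutated sequence.
#' @export
mutate_genome <- function(genome, substitution_fraction, seed = NULL,
                          protect_planted = TRUE, id = NULL) {
  if (substitution_fraction < 0 || substitution_fraction > 0.5) {
    stop("substitution_fraction must be in [0, 0.5]", call. = FALSE)
  }
  s <- genome_sequence(genome)
  g <- nchar(s)
  n_sub <- round(substitution_fraction * g)
  if (n_sub == 0L) {
    out <- replace_sequence(genome, s)
    if (is.list(out) && !is.null(id)) out$id <- id
    return(out)
  }
  truth <- if (is.list(genome)) genome$truth else NULL
  use_protect <- protect_planted && !is.null(truth) && nrow(truth) > 0L
  protected <- logical(g)        # 1-based flags
  gene_of <- rep(NA_integer_, g)
  codon_of <- rep(NA_integer_, g)
  if (use_protect) {
    for (i in seq_len(nrow(truth))) {
      L <- truth$length_nt[i]
      b <- truth$begin[i]
      if (truth$strand[i] == "+") {
        body <- (b + 0:(L - 1L)) %% g
        guard <- (b - 3:1) %% g
      } else {
        body <- (b - 0:(L - 1L)) %% g
        guard <- (b + 1:3) %% g
      }
      gene_of[body + 1L] <- i
      codon_of[body + 1L] <- rep(seq_len(L / 3L), each = 3L)
      # start codon, stop codon and guard stop are untouchable
      protected[body[1:3] + 1L] <- TRUE
      protected[body[(L - 2L):L] + 1L] <- TRUE
      protected[guard + 1L] <- TRUE
    }
  }
  stops <- stop_codons()
  chars <- seq_chars(s)
  bases <- c("A", "C", "G", "T")
  mutate_body <- function() {
    pool <- sample.int(g)            # permutation of 1-based positions
    done <- 0L
    for (p in pool) {
      if (done == n_sub) break
      if (protected[p]) next
      cur <- chars[p]
      cands <- sample(setdiff(bases, cur))
      gi <- gene_of[p]
      placed <- FALSE
      for (nb in cands) {
        if (!is.na(gi)) {
          ci <- codon_of[p]
          b <- truth$begin[gi]
          L <- truth$length_nt[gi]
          if (truth$strand[gi] == "+") {
            cpos <- (b + (ci - 1L) * 3L + 0:2) %% g + 1L
            codon <- chars[cpos]
            codon[cpos == p] <- nb
            codon <- paste(codon, collapse = "")
          } else {
            cpos <- (b - (ci - 1L) * 3L - 0:2) %% g + 1L
            codon <- chartr("ACGT", "TGCA", chars[cpos])
            codon[cpos == p] <- chartr("ACGT", "TGCA", nb)
            codon <- paste(codon, collapse = "")
          }
          if (codon %in% stops) next  # would truncate the planted gene
        }
        chars[p] <<- nb
        placed <- TRUE
        break
      }
      if (placed) done <- done + 1L
    }
    if (done < n_sub) {
      stop("could not place the requested number of substitutions",
           call. = FALSE)
    }
  }
  with_seed(seed, mutate_body())
  out <- replace_sequence(genome, paste(chars, collapse = ""))
  if (is.list(out)) out$id <- id %||% paste0(genome_id_of(genome), "_mut")
  out
}

#' Simulate per-sample read coverage with controllable breadth
#'
#' Draws error-free reads as exact substrings of the circular genome
#' (wrapping the origin) until the realized breadth of coverage reaches
#' the target; a read that would overshoot the `target + 0.02` band is
#' truncated so the realized breadth lands within two percentage points
#' of the target. `target_breadth = 1` produces a deterministic tiling
#' with breadth exactly 1; `target_breadth = 0` produces no reads.
#'
#' @param genome a `microvir_genome` or nucleotide string.
#' @param target_breadth target fraction of genome positions covered, in
#'   `[0, 1]`.
#' @param read_length read length in nt (must be `< genome length`).
#' @param seed RNG seed (`NULL` draws from the current stream).
#' @param max_reads cap on the number of reads; if the target band cannot
#'   be reached within the cap an error reports the realized breadth.
#' @return an object of class `coverage_sim`: list with `reads` (named
#'   character vector), `realized_breadth`, `covered` (logical per
#'   position), `n_reads`.
#' @export
simulate_coverage <- function(genome, target_breadth, read_length = 150L,
                              seed = NULL, max_reads = NULL) {
  if (target_breadth < 0 || target_breadth > 1) {
    stop("target_breadth must be in [0, 1]", call. = FALSE)
  }
  s <- genome_sequence(genome)
  g <- nchar(s)
  read_length <- as.integer(read_length)
  if (read_length >= g) stop("read_length must be < genome length", call. = FALSE)
  doubled <- paste0(s, s)
  mk <- function(start0, len) substr(doubled, start0 + 1L, start0 + len)
  if (target_breadth == 0) {
    out <- list(reads = character(0), realized_breadth = 0,
                covered = logical(g), n_reads = 0L)
    class(out) <- "coverage_sim"
    return(out)
  }
  if (target_breadth >= 1) {
    starts <- seq.int(0L, g - 1L, by = read_length)
    reads <- vapply(starts, mk, character(1), len = read_length)
    names(reads) <- sprintf("read%04d", seq_along(reads))
    out <- list(reads = reads, realized_breadth = 1,
                covered = rep(TRUE, g), n_reads = length(reads))
    class(out) <- "coverage_sim"
    return(out)
  }
  if (is.null(max_reads)) max_reads <- ceiling(20 * g / read_length) + 100L
  run <- function() {
    covered <- logical(g)
    reads <- character(0)
    starts <- integer(0)
    cap <- floor((target_breadth + 0.02) * g)
    while (sum(covered) < target_breadth * g) {
      if (length(reads) >= max_reads) {
        stop(sprintf(
          "unreachable breadth: target %.3f, realized %.4f after %d reads",
          target_breadth, mean(covered), length(reads)), call. = FALSE)
      }
      s0 <- sample.int(g, 1L) - 1L
      idx <- (s0 + 0:(read_length - 1L)) %% g + 1L
      newly <- !covered[idx]
      if (sum(covered) + sum(newly) <= cap) {
        len <- read_length
      } else {
        allowed <- cap - sum(covered)
        len <- suppressWarnings(max(which(cumsum(newly) <= allowed)))
        if (!is.finite(len) || len < 30L || sum(newly[seq_len(len)]) == 0L) next
      }
      covered[idx[seq_len(len)]] <- TRUE
      reads <- c(reads, mk(s0, len))
      starts <- c(starts, s0)
    }
    list(covered = covered, reads = reads, starts = starts)
  }
  r <- with_seed(seed, run())
  names(r$reads) <- sprintf("read%04d", seq_along(r$reads))
  out <- list(reads = r$reads, realized_breadth = mean(r$covered),
              covered = r$covered, n_reads = length(r$reads))
  class(out) <- "coverage_sim"
  out
}
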