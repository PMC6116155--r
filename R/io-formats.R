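# Standard formats the pipeline touches: FASTA, GFF3, SAM coverage import,
# TSV matrices and cluster tables, Newick trees, BLAST tabular hits, and
# the JSON run manifest.

#' Read sequences from a FASTA file
#'
#' Reads nucleotide (default) or amino-acid FASTA. Sequences are
#' uppercased on read (with a message when anything changed), duplicate
#' ids are an error, and non-IUPAC characters are an error reporting the
#' offending record and position.
#'
#' @param path file path.
#' @param type `"DNA"` or `"AA"`.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  xs <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(xs))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- as.character(xs)
  upper <- toupper(seqs)
  if (any(upper != seqs)) {
    message("lowercase letters uppercased on read: ", basename(path))
    seqs <- upper
  }
  valid <- if (type == "DNA") {
    paste0(paste(names(Biostrings::IUPAC_CODE_MAP), collapse = ""), "-")
  } else {
    "ACDEFGHIKLMNPQRSTVWYBXZJUO*-"
  }
  bad_re <- paste0("[^", valid, "]")
  hit <- regexpr(bad_re, seqs)
  if (any(hit > 0)) {
    i <- which(hit > 0)[1]
    stop(sprintf("non-IUPAC character '%s' in record '%s' at position %d",
                 substr(seqs[i], hit[i], hit[i]), ids[i], hit[i]),
         call. = FALSE)
  }
  setNames(seqs, ids)
}

#' Write sequences to a FASTA file
#'
#' Writes 70-column wrapped FASTA; round-trips through [read_fasta()]
#' preserve ids and sequences exactly.
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param type `"DNA"` or `"AA"`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  if (length(seqs) && (is.null(names(seqs)) || any(!nzchar(names(seqs))))) {
    stop("all sequences must be named", call. = FALSE)
  }
  if (anyDuplicated(names(seqs))) {
    stop("duplicate FASTA ids: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "),
         call. = FALSE)
  }
  xs <- if (type == "DNA") Biostrings::DNAStringSet(seqs)
        else Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(xs, path, width = 70L)
  invisible(path)
}

#' Read an MCP reference panel
#'
#' @param fasta_path amino-acid FASTA of reference MCPs.
#' @param labels_path TSV with columns `protein_id` and `group_label`;
#'   every FASTA record must be labeled.
#' @return data.frame with `protein_id`, `group_label`, `sequence`.
#' @export
read_mcp_panel <- function(fasta_path, labels_path) {
  seqs <- read_fasta(fasta_path, type = "AA")
  lab <- utils::read.delim(labels_path, stringsAsFactors = FALSE)
  if (!all(c("protein_id", "group_label") %in% names(lab))) {
    stop("label table needs columns protein_id and group_label",
         call. = FALSE)
  }
  missing <- setdiff(names(seqs), lab$protein_id)
  if (length(missing)) {
    stop("panel members without group label: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  data.frame(protein_id = names(seqs),
             group_label = lab$group_label[match(names(seqs),
                                                 lab$protein_id)],
             sequence = unname(seqs), stringsAsFactors = FALSE)
}

# 0-based circular ORF span -> list of 1-based inclusive (start, end)
# parts in forward coordinates (two parts when the ORF wraps the origin).
orf_gff_parts <- function(begin, length_nt, strand, g) {
  if (begin < 0L || begin >= g || length_nt > g) {
    stop("ORF coordinates outside genome", call. = FALSE)
  }
  if (strand == "+") {
    s0 <- begin
    e0 <- begin + length_nt - 1L
  } else {
    s0 <- begin - length_nt + 1L
    e0 <- begin
  }
  if (s0 >= 0L && e0 < g) {
    list(c(s0 + 1L, e0 + 1L))
  } else if (s0 < 0L) {             # wraps leftwards
    list(c(s0 + g + 1L, g), c(1L, e0 + 1L))
  } else {                          # e0 >= g, wraps rightwards
    list(c(s0 + 1L, g), c(1L, e0 - g + 1L))
  }
}

#' Write ORF annotations as GFF3
#'
#' 1-based inclusive coordinates; origin-spanning ORFs are emitted as two
#' CDS part-features sharing an `ID`, with circularity declared via
#' `Is_circular=true` on the region feature.
#'
#' @param orfs ORF table from [call_orfs()] (optionally with a
#'   `family_label` column, written as the `Name` attribute).
#' @param genome_id,genome_length sequence region metadata (defaults:
#'   taken from the `orfs` attributes).
#' @param path output path, or `NULL` to return the lines invisibly.
#' @param header include the `##gff-version 3` header and region pragma.
#' @return character vector of GFF3 lines, invisibly when written.
#' @export
write_gff3 <- function(orfs, genome_id = NULL, genome_length = NULL,
                       path = NULL, header = TRUE) {
  genome_id <- genome_id %||% attr(orfs, "genome_id") %||% "genome"
  genome_length <- genome_length %||% attr(orfs, "genome_length")
  if (is.null(genome_length)) stop("genome_length required", call. = FALSE)
  lines <- character(0)
  if (header) lines <- c(lines, "##gff-version 3")
  lines <- c(lines,
             sprintf("##sequence-region %s 1 %d", genome_id, genome_length),
             sprintf(paste0("%s\tmicrovir\tregion\t1\t%d\t.\t+\t.\t",
                            "ID=%s;Is_circular=true"),
                     genome_id, genome_length, genome_id))
  if (!is.null(orfs) && nrow(orfs)) {
    for (i in seq_len(nrow(orfs))) {
      parts <- orf_gff_parts(orfs$begin[i], orfs$length_nt[i],
                             orfs$strand[i], genome_length)
      if (any(vapply(parts, function(p) p[1] < 1L || p[2] > genome_length,
                     logical(1)))) {
        stop("ORF coordinates outside genome: ", orfs$orf_id[i],
             call. = FALSE)
      }
      name <- if ("family_label" %in% names(orfs) &&
                  !is.na(orfs$family_label[i]))
        sprintf(";Name=%s", orfs$family_label[i]) else ""
      for (p in parts) {
        lines <- c(lines, sprintf(
          "%s\tmicrovir\tCDS\t%d\t%d\t.\t%s\t0\tID=%s%s",
          genome_id, p[1], p[2], orfs$strand[i], orfs$orf_id[i], name))
      }
    }
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Import per-genome coverage from a SAM file
#'
#' Converts a SAM alignment file into coverage profiles: per genome, the
#' union of reference positions covered by aligned blocks (CIGAR-aware;
#' unmapped records are ignored). References in the SAM header must be a
#' subset of the supplied genome set.
#'
#' @param path SAM file path.
#' @param genome_lengths named integer vector (genome id -> length), or a
#'   named character vector of genome sequences.
#' @param sample_id sample the alignments came from.
#' @return list of `coverage_profile` objects, one per genome in
#'   `genome_lengths` (genomes without alignments get breadth 0).
#' @export
read_sam_coverage <- function(path, genome_lengths, sample_id = "sample") {
  if (is.character(genome_lengths)) {
    genome_lengths <- setNames(nchar(genome_lengths),
                               names(genome_lengths))
  }
  bam <- Rsamtools::asBam(path,
                          destination = tempfile(fileext = ""),
                          overwrite = TRUE, indexDestination = TRUE)
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  unknown <- setdiff(names(hdr), names(genome_lengths))
  if (length(unknown)) {
    stop("SAM references not in the genome set: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  aln <- GenomicAlignments::readGAlignments(bam)
  cov <- GenomicAlignments::coverage(aln)
  lapply(names(genome_lengths), function(gid) {
    g <- as.integer(genome_lengths[[gid]])
    depth <- integer(g)
    if (gid %in% names(cov)) {
      v <- as.integer(cov[[gid]])
      depth[seq_along(v)] <- v
    }
    out <- list(genome_id = gid, sample_id = sample_id,
                covered_positions = sum(depth > 0L), genome_length = g,
                breadth = sum(depth > 0L) / g,
                mean_depth = sum(depth) / g, depth = depth)
    class(out) <- "coverage_profile"
    out
  })
}

#' Write / read a matrix as TSV
#'
#' Single header row, first column `id` holding row names, stable column
#' order; numeric values at 6 significant digits. The round-trip preserves
#' the matrix (integer matrices stay integer).
#'
#' @param m matrix with row and column names.
#' @param path file path.
#' @return `path` invisibly (write); the matrix (read).
#' @export
write_matrix_tsv <- function(m, path) {
  m <- unclass(m)
  vals <- if (is.integer(m) || all(m == round(m))) m else signif(m, 6)
  df <- data.frame(id = rownames(m), vals, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE, fill = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  m
}

#' Write / read dereplication clusters as TSV
#'
#' @param clusters output of [dereplicate()].
#' @param path file path.
#' @return `path` invisibly (write); a cluster list (read).
#' @export
write_clusters_tsv <- function(clusters, path) {
  df <- do.call(rbind, lapply(clusters, function(cl) {
    data.frame(representative = cl$representative, member = cl$members,
               identity_to_rep = signif(unname(cl$identity_to_rep), 6),
               stringsAsFactors = FALSE)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_clusters_tsv
#' @export
read_clusters_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, fill = FALSE)
  lapply(split(df, df$representative), function(d) {
    out <- list(representative = d$representative[1], members = d$member,
                identity_to_rep = setNames(d$identity_to_rep, d$member))
    class(out) <- "genome_cluster"
    out
  })
}

#' Write / read a Newick tree
#'
#' Thin wrappers over [ape::write.tree()] / [ape::read.tree()]; the
#' round-trip preserves topology and branch lengths.
#'
#' @param tree a `sample_dendrogram` or `phylo` object.
#' @param path file path.
#' @return `path` invisibly (write); a `phylo` (read).
#' @export
write_newick <- function(tree, path) {
  ph <- if (inherits(tree, "sample_dendrogram")) tree$phylo else tree
  ape::write.tree(ph, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}

#' Import BLAST tabular (outfmt 6) hits
#'
#' Maps the standard 12 columns to named hit records and applies an
#' optional e-value cutoff (the classical BLAST screen thresholds live in
#' [microvir_thresholds()]).
#'
#' @param path tabular file path.
#' @param max_evalue optional e-value cutoff; hits above it are dropped.
#' @return data.frame with the standard columns `qseqid`, `sseqid`,
#'   `pident`, `length`, `mismatch`, `gapopen`, `qstart`, `qend`,
#'   `sstart`, `send`, `evalue`, `bitscore`.
#' @export
read_blast_tab <- function(path, max_evalue = NULL) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          fill = FALSE)
  if (ncol(df) != length(cols)) {
    stop("expected 12 tab-separated columns (BLAST outfmt 6), got ",
         ncol(df), call. = FALSE)
  }
  names(df) <- cols
  if (!is.null(max_evalue)) df <- df[df$evalue < max_evalue, , drop = FALSE]
  df
}

#' Expand a GenBank accession range
#'
#' Accepts ranges like `"MH572269-MH572526"` and returns the individual
#' accessions (shared alphabetic prefix, zero-padded numeric suffix).
#'
#' @param range_spec a single `"FROM-TO"` string or a vector of plain
#'   accessions (returned as is).
#' @return character vector of accessions.
#' @examples
#' length(expand_accession_range("MH572269-MH572526"))  # 258
#' @export
expand_accession_range <- function(range_spec) {
  if (length(range_spec) != 1L || !grepl("-", range_spec, fixed = TRUE)) {
    return(range_spec)
  }
  parts <- strsplit(range_spec, "-", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop("malformed accession range", call. = FALSE)
  pre1 <- sub("[0-9]+$", "", parts[1])
  pre2 <- sub("[0-9]+$", "", parts[2])
  if (pre1 != pre2) stop("accession prefixes differ", call. = FALSE)
  n1 <- sub("^[A-Za-z]+", "", parts[1])
  n2 <- sub("^[A-Za-z]+", "", parts[2])
  width <- nchar(n1)
  nums <- seq.int(as.integer(n1), as.integer(n2))
  sprintf("%s%0*d", pre1, width, nums)
}

#' Download deposited genomes from GenBank (optional, needs network)
#'
#' The single networking utility in the package: fetches nucleotide FASTA
#' for a set of accessions via NCBI efetch. Never called by the pipeline,
#' tests or the acceptance script; intended for optional validation
#' against deposited genome sets.
#'
#' @param accessions accession vector or range (see
#'   [expand_accession_range()]).
#' @param dest output FASTA path.
#' @return `dest`, invisibly.
#' @export
fetch_genbank_fasta <- function(accessions, dest) {
  accessions <- expand_accession_range(accessions)
  url <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
                "?db=nuccore&rettype=fasta&retmode=text&id=",
                paste(accessions, collapse = ","))
  utils::download.file(url, dest, quiet = TRUE)
  invisible(dest)
}

#' Build a run manifest
#'
#' Records pipeline version, the thresholds snapshot, input digests,
#' per-stage record counts and the seed registry; every stage's counts
#' must reconcile (admitted + rejected = input).
#'
#' @param thresholds a [microvir_thresholds()] object.
#' @param stage_counts named list: stage -> list(input, admitted, rejected).
#' @param inputs named character vector of input file paths (digested with
#'   md5).
#' @param seeds named list of seeds used.
#' @return a list of class `run_manifest`.
#' @export
build_manifest <- function(thresholds, stage_counts = list(),
                           inputs = character(0), seeds = list()) {
  for (nm in names(stage_counts)) {
    sc <- stage_counts[[nm]]
    if (!is.null(sc$input) && !is.null(sc$admitted) && !is.null(sc$rejected) &&
        sc$admitted + sc$rejected != sc$input) {
      stop("stage counts do not reconcile for ", nm, call. = FALSE)
    }
  }
  digests <- if (length(inputs)) {
    vapply(inputs, function(p)
      if (file.exists(p)) unname(tools::md5sum(p)) else NA_character_,
      character(1))
  } else character(0)
  out <- list(pipeline = "microvir",
              version = as.character(utils::packageVersion("microvir")),
              thresholds = unclass(thresholds),
              inputs = as.list(digests),
              stage_counts = stage_counts,
              seeds = seeds,
              created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  class(out) <- "run_manifest"
  out
}

#' @rdname build_manifest
#' @param manifest a `run_manifest`.
#' @param path output JSON path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}
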