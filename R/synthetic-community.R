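# Synthetic MCP reference panel and whole-community simulation: the truth
# scaffolding for end-to-end tests of detection, dereplication, annotation
# and occupancy.

#' Generate a synthetic MCP reference panel
#'
#' Builds a small stand-in for a curated panel of Microviridae major
#' capsid proteins: one random base protein per phylogenetic group plus
#' within-group members derived by amino-acid substitution. Purely
#' synthetic sequences - useful for testing classification logic, not for
#' classifying real data.
#'
#' @param n_groups number of groups (capped at the label vocabulary size).
#' @param members_per_group panel members per group.
#' @param length_range MCP length range (aa).
#' @param within_divergence amino-acid divergence between members of the
#'   same group.
#' @param seed RNG seed (`NULL` draws from the current stream).
#' @param group_labels controlled vocabulary of group labels.
#' @return a data.frame with columns `protein_id`, `group_label`,
#'   `sequence`.
#' @export
synthetic_mcp_panel <- function(n_groups = 6L, members_per_group = 2L,
                                length_range = c(380L, 520L),
                                within_divergence = 0.2,
                                seed = NULL,
                                group_labels = c("Gokushovirinae", "Group_D",
                                                 "Pichovirinae", "Alpavirinae",
                                                 "Parabacteroides_prophage",
                                                 "Pequenovirus")) {
  n_groups <- min(n_groups, length(group_labels))
  build <- function() {
    rows <- list()
    for (gi in seq_len(n_groups)) {
      len <- sample(length_range[1]:length_range[2], 1L)
      base <- random_protein(len)
      for (mi in seq_len(members_per_group)) {
        p <- if (mi == 1L) base else mutate_protein(base, within_divergence)
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = sprintf("%s_ref%d", group_labels[gi], mi),
          group_label = group_labels[gi],
          sequence = p, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  }
  with_seed(seed, build())
}

#' Simulate a microvirus community with known truth
#'
#' Generates `n_clusters` unrelated genome templates (each carrying an MCP
#' planted from the reference panel plus accessory genes), derives
#' within-cluster variants by point mutation, wraps every genome into an
#' assembly-style contig with a random terminal overrun and rotation, and
#' simulates per-sample reads from each cluster representative according
#' to a random binary truth occupancy (every sample contains at least one
#' cluster; absent clusters may still contribute sparse reads well below
#' the presence threshold).
#'
#' @param n_clusters number of planted species-level clusters.
#' @param variants_per_cluster genomes per cluster (representative plus
#'   `variants_per_cluster - 1` variants).
#' @param sample_ids sample names.
#' @param divergence_within nucleotide substitution fraction between a
#'   variant and its representative (default 2%, inside the 95% species
#'   cutoff).
#' @param seed RNG seed for the whole community.
#' @param length_range genome size envelope (nt).
#' @param panel MCP reference panel (default: a fresh synthetic panel).
#' @param plant_divergence amino-acid divergence between a planted MCP and
#'   its panel source.
#' @param read_length simulated read length (nt).
#' @param present_breadth,absent_breadth target-breadth ranges for present
#'   and absent genomes (kept clear of the 75% presence boundary).
#' @param p_present prior probability a cluster is present in a sample.
#' @param overrun_range contig terminal-overrun range (nt).
#' @return an object of class `microvir_community`: list with `genomes`
#'   (named list of `microvir_genome`), `representatives`, `truth_clusters`
#'   (named list: representative id -> member ids), `truth_occupancy`
#'   (clusters x samples binary matrix), `breadth_truth` (realized breadth
#'   per cluster x sample), `contigs` (named character vector),
#'   `reads` (named list of per-sample read vectors), `panel`, `params`.
#' @export
simulate_community <- function(n_clusters = 5L, variants_per_cluster = 3L,
                               sample_ids = c("SC", "MC", "HC", "MB"),
                               divergence_within = 0.02,
                               seed = 1L,
                               length_range = c(3900L, 5800L),
                               panel = NULL,
                               plant_divergence = 0.10,
                               read_length = 150L,
                               present_breadth = c(0.80, 0.95),
                               absent_breadth = c(0.05, 0.55),
                               p_present = 0.5,
                               overrun_range = c(15L, 500L)) {
  stopifnot(n_clusters >= 1L, variants_per_cluster >= 1L,
            length(sample_ids) >= 1L)
  with_seed(seed, {
    if (is.null(panel)) panel <- synthetic_mcp_panel(seed = NULL)
    genomes <- list()
    reps <- character(n_clusters)
    truth_clusters <- vector("list", n_clusters)
    for (k in seq_len(n_clusters)) {
      rid <- sprintf("CGM%03d", k)
      src <- panel[((k - 1L) %% nrow(panel)) + 1L, ]
      mcp <- mutate_protein(src$sequence, plant_divergence)
      plan <- data.frame(
        family = c("MCP", "REP", "HYP"),
        length_aa = c(nchar(mcp),
                      sample(250:350, 1L),
                      sample(90:150, 1L)),
        strand = c("+", sample(c("+", "-"), 1L), sample(c("+", "-"), 1L)),
        stringsAsFactors = FALSE)
      len <- sample(length_range[1]:length_range[2], 1L)
      len <- max(len, sum(3L * plan$length_aa + 6L) + 150L)
      tpl <- genome_template(rid, len, plan,
                             seed = sample.int(.Machine$integer.max, 1L),
                             length_range = NULL)
      rep_g <- generate_genome(tpl, proteins = list(MCP = mcp))
      members <- rid
      genomes[[rid]] <- rep_g
      if (variants_per_cluster > 1L) {
        for (v in seq_len(variants_per_cluster - 1L)) {
          vid <- sprintf("%s_v%d", rid, v + 1L)
          genomes[[vid]] <- mutate_genome(rep_g, divergence_within,
                                          seed = NULL, id = vid)
          members <- c(members, vid)
        }
      }
      reps[k] <- rid
      truth_clusters[[k]] <- members
    }
    names(truth_clusters) <- reps

    contigs <- character(0)
    for (gid in names(genomes)) {
      g <- genomes[[gid]]
      ov <- sample(overrun_range[1]:overrun_range[2], 1L)
      off <- sample.int(g$length_nt, 1L) - 1L
      contigs[[paste0(gid, "_contig")]] <- make_assembly_contig(g, ov, off)
    }

    occ <- matrix(stats::rbinom(n_clusters * length(sample_ids), 1L,
                                p_present),
                  nrow = n_clusters,
                  dimnames = list(reps, sample_ids))
    for (j in seq_along(sample_ids)) {
      if (sum(occ[, j]) == 0L) occ[sample.int(n_clusters, 1L), j] <- 1L
    }

    breadth_truth <- matrix(0, n_clusters, length(sample_ids),
                            dimnames = dimnames(occ))
    reads <- setNames(vector("list", length(sample_ids)), sample_ids)
    for (j in seq_along(sample_ids)) {
      pooled <- character(0)
      for (k in seq_len(n_clusters)) {
        if (occ[k, j] == 1L) {
          tb <- runif(1L, present_breadth[1], present_breadth[2])
        } else if (runif(1L) < 0.5) {
          tb <- runif(1L, absent_breadth[1], absent_breadth[2])
        } else {
          next
        }
        sim <- simulate_coverage(genomes[[reps[k]]], tb,
                                 read_length = read_length, seed = NULL)
        breadth_truth[k, j] <- sim$realized_breadth
        if (sim$n_reads > 0L) {
          nm <- sprintf("%s_%s_%s", sample_ids[j], reps[k],
                        names(sim$reads))
          pooled <- c(pooled, setNames(sim$reads, nm))
        }
      }
      reads[[j]] <- pooled
    }

    out <- list(genomes = genomes, representatives = reps,
                truth_clusters = truth_clusters, truth_occupancy = occ,
                breadth_truth = breadth_truth, contigs = contigs,
                reads = reads, panel = panel,
                params = list(n_clusters = n_clusters,
                              variants_per_cluster = variants_per_cluster,
                              sample_ids = sample_ids,
                              divergence_within = divergence_within,
                              plant_divergence = plant_divergence,
                              read_length = read_length,
                              seed = seed))
    class(out) <- "microvir_community"
    out
  })
}

#' @export
print.microvir_community <- function(x, ...) {
  cat(sprintf(
    "synthetic microvirus community: %d genomes in %d clusters, %d samples\n",
    length(x$genomes), length(x$representatives),
    length(x$params$sample_ids)))
  invisible(x)
}

#' Write a simulated community to disk
#'
#' Writes genomes and contigs as FASTA, reads as per-sample FASTA, truth
#' annotations as GFF3, truth occupancy and cluster tables as TSV, and a
#' JSON run manifest echoing the generator parameters.
#'
#' @param community a [simulate_community()] result.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_community <- function(community, dir) {
  stopifnot(inherits(community, "microvir_community"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gseqs <- vapply(community$genomes, function(g) g$sequence, character(1))
  write_fasta(gseqs, file.path(dir, "genomes.fasta"))
  write_fasta(community$contigs, file.path(dir, "contigs.fasta"))
  for (sid in names(community$reads)) {
    write_fasta(community$reads[[sid]],
                file.path(dir, sprintf("reads_%s.fasta", sid)))
  }
  gff <- unlist(lapply(community$genomes, function(g) {
    orfs <- truth_as_orfs(g)
    write_gff3(orfs, genome_id = g$id, genome_length = g$length_nt,
               header = FALSE)
  }))
  writeLines(c("##gff-version 3", gff), file.path(dir, "truth_orfs.gff3"))
  write_matrix_tsv(community$truth_occupancy,
                   file.path(dir, "truth_occupancy.tsv"))
  cl <- data.frame(
    representative = rep(names(community$truth_clusters),
                         lengths(community$truth_clusters)),
    member = unlist(community$truth_clusters, use.names = FALSE),
    stringsAsFactors = FALSE)
  write.table(cl, file.path(dir, "truth_clusters.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_fasta(setNames(community$panel$sequence,
                       community$panel$protein_id),
              file.path(dir, "panel.faa"), type = "AA")
  write.table(community$panel[, c("protein_id", "group_label")],
              file.path(dir, "panel_groups.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest <- list(generator = "simulate_community",
                   parameters = community$params,
                   n_genomes = length(community$genomes),
                   n_clusters = length(community$representatives),
                   n_samples = length(community$params$sample_ids))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

# Convert a genome's truth table to the call_orfs() column layout.
truth_as_orfs <- function(genome) {
  tr <- genome$truth
  g <- genome$length_nt
  data.frame(
    orf_id = sprintf("%s_%s", genome$id, tr$family),
    begin = tr$begin, strand = tr$strand,
    length_aa = tr$length_aa, length_nt = tr$length_nt,
    wraps_origin = ifelse(tr$strand == "+",
                          tr$begin + tr$length_nt > g,
                          tr$begin - tr$length_nt + 1L < 0L),
    protein = tr$protein, family_label = tr$family,
    stringsAsFactors = FALSE)
}
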