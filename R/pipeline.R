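# End-to-end workflow: contigs -> circular detection -> trimming -> size
# filter -> ORF/MCP annotation -> MCP anchoring -> dereplication ->
# synteny fingerprints -> occupancy -> community comparison.

#' Annotate one unit genome
#'
#' Calls ORFs, identifies the MCP against the reference panel (with an
#' optional decoy screen), anchors the genome at the MCP start codon and
#' assigns family labels to all ORFs (the MCP ORF gets `"MCP"`; other
#' ORFs are labeled by their best accessory-panel hit when an accessory
#' panel is supplied, otherwise `"HYP"`).
#'
#' @param genome a `unit_genome` (or nucleotide string).
#' @param panel MCP reference panel.
#' @param thresholds a [microvir_thresholds()] object.
#' @param decoy_panel optional decoy panel for the false-positive screen.
#' @param accessory_panel optional panel for labeling non-MCP ORFs.
#' @param ... passed to [translated_search()].
#' @return a list with `status` (`"ok"`, `"unclassified"`, `"excluded"`),
#'   and for `"ok"`: `genome` (anchored), `orfs` (labeled, remapped),
#'   `mcp_call`.
#' @export
annotate_genome <- function(genome, panel,
                            thresholds = microvir_thresholds(),
                            decoy_panel = NULL, accessory_panel = NULL,
                            ...) {
  orfs <- call_orfs(genome, thresholds)
  if (nrow(orfs) == 0L) {
    return(list(status = "unclassified", genome = genome,
                reason = "no ORFs above length threshold"))
  }
  mcp <- identify_mcp(genome, orfs, panel, thresholds,
                      decoy_panel = decoy_panel, ...)
  if (!identical(mcp$status, "ok")) {
    return(list(status = mcp$status, genome = genome, mcp_call = mcp))
  }
  anchored <- anchor_to_mcp(genome, orfs, mcp$orf_id)
  orfs <- anchored$orfs
  labels <- rep("HYP", nrow(orfs))
  mcp_row <- match(mcp$orf_id, orfs$orf_id)
  labels[mcp_row] <- "MCP"
  if (!is.null(accessory_panel) && nrow(accessory_panel)) {
    for (i in setdiff(seq_len(nrow(orfs)), mcp_row)) {
      h <- tryCatch(translated_search(orfs$protein[i], accessory_panel, ...),
                    error = function(e) list(hit = FALSE))
      if (isTRUE(h$hit)) {
        labels[i] <- h$group_label %||% h$protein_id
      }
    }
  }
  orfs$family_label <- labels
  list(status = "ok", genome = anchored$genome, orfs = orfs, mcp_call = mcp)
}

#' Run the full genome-recovery and community pipeline
#'
#' Chains every stage on in-memory inputs: terminal-repeat detection,
#' trimming, size filtering, ORF/MCP annotation with anchoring,
#' dereplication at the species cutoff, synteny fingerprinting,
#' read-recruitment occupancy, and community comparison. Stage counts are
#' reconciled into a run manifest.
#'
#' @param contigs named character vector of assembled contig sequences.
#' @param panel MCP reference panel data.frame.
#' @param reads_by_sample named list (sample id -> character vector of
#'   reads); `NULL` skips occupancy and community stages.
#' @param thresholds a [microvir_thresholds()] object.
#' @param decoy_panel,accessory_panel optional panels (see
#'   [annotate_genome()]).
#' @param outdir optional directory; when given, all stage outputs are
#'   written (FASTA/GFF3/TSV/Newick/JSON).
#' @param verbose print one bookkeeping line per stage.
#' @return an object of class `microvir_run`: list with `units`,
#'   `annotations`, `genomes` (anchored, named), `clusters`,
#'   `representatives`, `fingerprints`, `organization_counts`,
#'   `profiles`, `occupancy`, `dissimilarity` (list of three),
#'   `dendrogram`, `richness`, `manifest`.
#' @export
run_pipeline <- function(contigs, panel, reads_by_sample = NULL,
                         thresholds = microvir_thresholds(),
                         decoy_panel = NULL, accessory_panel = NULL,
                         outdir = NULL, verbose = TRUE) {
  validate_thresholds(thresholds)
  say <- function(...) if (verbose) message(sprintf(...))
  counts <- list()

  # 1. circular detection + trimming
  circs <- list()
  for (cid in names(contigs)) {
    v <- detect_terminal_repeat(contigs[[cid]], thresholds, contig_id = cid)
    if (isTRUE(v$circular)) circs[[cid]] <- v
  }
  counts$detect <- list(input = length(contigs), admitted = length(circs),
                        rejected = length(contigs) - length(circs))
  say("detect-circles: %d contigs -> %d circular", length(contigs),
      length(circs))
  units <- lapply(circs, trim_to_unit)

  # 2. size filter
  sf <- size_filter(units, thresholds)
  units <- sf$admitted
  counts$size_filter <- list(input = length(circs),
                             admitted = length(units),
                             rejected = nrow(sf$rejected))
  say("size-filter: %d circular -> %d within [%d, %d] nt", length(circs),
      length(units), thresholds$size_min_nt, thresholds$size_max_nt)

  # 3. annotation + anchoring
  annotations <- list()
  genomes <- list()
  dropped <- character(0)
  for (u in units) {
    ann <- annotate_genome(u, panel, thresholds, decoy_panel = decoy_panel,
                           accessory_panel = accessory_panel)
    if (identical(ann$status, "ok")) {
      annotations[[u$genome_id]] <- ann
      genomes[[u$genome_id]] <- ann$genome
    } else {
      dropped <- c(dropped, u$genome_id)
    }
  }
  counts$annotate <- list(input = length(units),
                          admitted = length(genomes),
                          rejected = length(dropped))
  say("annotate: %d genomes -> %d MCP-anchored (%d unclassified/excluded)",
      length(units), length(genomes), length(dropped))
  if (!length(genomes)) stop("no annotated genomes", call. = FALSE)

  # 4. dereplication
  clusters <- dereplicate(genomes, thresholds)
  reps <- vapply(clusters, function(cl) cl$representative, character(1))
  counts$dereplicate <- list(input = length(genomes),
                             admitted = length(clusters),
                             rejected = length(genomes) - length(clusters))
  say("dereplicate: %d genomes -> %d clusters at %.0f%% identity",
      length(genomes), length(clusters), thresholds$cluster_identity_pct)

  # 5. synteny fingerprints
  fingerprints <- lapply(names(genomes), function(gid) {
    ann <- annotations[[gid]]
    synteny_fingerprint(ann$genome, ann$orfs,
                        group_label = ann$mcp_call$group_label)
  })
  names(fingerprints) <- names(genomes)
  org_counts <- count_organizations(fingerprints)
  say("synteny: %d fingerprints, %d distinct organizations overall",
      length(fingerprints),
      length(unique(vapply(fingerprints, function(f) f$key, character(1)))))

  profiles <- NULL; occupancy <- NULL; dissim <- NULL
  dendro <- NULL; richness <- NULL
  if (!is.null(reads_by_sample)) {
    # 6. occupancy over cluster representatives
    profiles <- list()
    for (sid in names(reads_by_sample)) {
      for (rid in reps) {
        profiles[[paste(rid, sid, sep = ":")]] <-
          recruit_reads(reads_by_sample[[sid]], genomes[[rid]],
                        sample_id = sid, genome_id = rid)
      }
    }
    occupancy <- build_occupancy(profiles, thresholds,
                                 genome_ids = sort(reps),
                                 sample_ids = names(reads_by_sample))
    say("occupancy: %d genomes x %d samples, %d presences",
        nrow(occupancy), ncol(occupancy), sum(occupancy))

    # 7. community comparison
    dissim <- lapply(setNames(nm = c("bray_curtis", "jaccard", "euclidean")),
                     function(ix) binary_dissimilarity(occupancy, ix))
    if (ncol(occupancy) >= 3L) {
      dendro <- sample_dendrogram(dissim$bray_curtis)
    }
    richness <- richness_report(occupancy)
    say("community: richness %s",
        paste(sprintf("%s=%d", richness$sample_id, richness$n_genomes),
              collapse = ", "))
  }

  manifest <- build_manifest(thresholds, stage_counts = counts)
  run <- list(units = units, annotations = annotations, genomes = genomes,
              clusters = clusters, representatives = reps,
              fingerprints = fingerprints,
              organization_counts = org_counts,
              profiles = profiles, occupancy = occupancy,
              dissimilarity = dissim, dendrogram = dendro,
              richness = richness, manifest = manifest)
  class(run) <- "microvir_run"
  if (!is.null(outdir)) write_run(run, outdir)
  run
}

#' @export
print.microvir_run <- function(x, ...) {
  cat(sprintf("microvir run: %d unit genomes, %d clusters\n",
              length(x$genomes), length(x$clusters)))
  if (!is.null(x$occupancy)) {
    cat(sprintf("  occupancy: %d x %d, %d presences\n", nrow(x$occupancy),
                ncol(x$occupancy), sum(x$occupancy)))
  }
  invisible(x)
}

# Flat ORF table across all annotated genomes (for TSV output).
run_orf_table <- function(run) {
  do.call(rbind, lapply(names(run$annotations), function(gid) {
    o <- run$annotations[[gid]]$orfs
    cbind(data.frame(genome_id = gid, stringsAsFactors = FALSE),
          o[, c("orf_id", "begin", "strand", "length_aa", "length_nt",
                "wraps_origin", "family_label")])
  }))
}

#' Write all pipeline outputs to a directory
#'
#' @param run a `microvir_run`.
#' @param outdir output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_run <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  gseqs <- vapply(run$genomes, genome_sequence, character(1))
  write_fasta(gseqs, file.path(outdir, "genomes_anchored.fasta"))
  write_fasta(gseqs[run$representatives],
              file.path(outdir, "representatives.fasta"))
  gff <- unlist(lapply(names(run$annotations), function(gid) {
    ann <- run$annotations[[gid]]
    write_gff3(ann$orfs, genome_id = gid,
               genome_length = nchar(genome_sequence(ann$genome)),
               header = FALSE)
  }))
  writeLines(c("##gff-version 3", gff), file.path(outdir, "orfs.gff3"))
  write.table(run_orf_table(run), file.path(outdir, "orfs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_clusters_tsv(run$clusters, file.path(outdir, "clusters.tsv"))
  calls <- do.call(rbind, lapply(run$annotations, function(a) {
    m <- a$mcp_call
    data.frame(genome_id = m$genome_id, orf_id = m$orf_id,
               best_reference = m$best_reference,
               best_identity_pct = signif(m$best_identity_pct, 6),
               group_label = m$group_label,
               novel_candidate = m$novel_candidate,
               stringsAsFactors = FALSE)
  }))
  write.table(calls, file.path(outdir, "mcp_calls.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  fp <- data.frame(
    genome_id = names(run$fingerprints),
    group_label = vapply(run$fingerprints, function(f)
      as.character(f$group_label %||% NA), character(1)),
    fingerprint = vapply(run$fingerprints, function(f) f$key, character(1)),
    stringsAsFactors = FALSE)
  write.table(fp, file.path(outdir, "synteny.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(run$organization_counts,
              file.path(outdir, "organizations.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(run$occupancy)) {
    write_matrix_tsv(run$occupancy, file.path(outdir, "occupancy.tsv"))
    breadth <- matrix(0, nrow(run$occupancy), ncol(run$occupancy),
                      dimnames = dimnames(run$occupancy))
    for (p in run$profiles) breadth[p$genome_id, p$sample_id] <- p$breadth
    write_matrix_tsv(breadth, file.path(outdir, "breadth.tsv"))
    for (ix in names(run$dissimilarity)) {
      write_matrix_tsv(run$dissimilarity[[ix]]$values,
                       file.path(outdir, sprintf("dissimilarity_%s.tsv", ix)))
    }
    if (!is.null(run$dendrogram)) {
      write_newick(run$dendrogram, file.path(outdir, "dendrogram.nwk"))
    }
    write.table(run$richness, file.path(outdir, "richness.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_manifest(run$manifest, file.path(outdir, "manifest.json"))
  invisible(outdir)
}
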