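hit_sequence <- function(genome, hit) {
  g <- as_genome(genome, "genome")
  s <- substr(g$seq, hit$start + 1L, hit$end)
  if (hit$strand == "-") revcomp(s) else s
}

#' Run the full 6S RNA annotation pipeline
#'
#' Orchestrates all stages over a genome set: first-pass homology search
#' against 6S references (relaxed e-value tier, overlapping hits joined,
#' best hit per genome), redundancy reduction of the accepted sequences to
#' consensus representatives, synteny-constrained rescue of the remaining
#' genomes near rarA/uspA anchors (second-iteration tag), terminator
#' calling with the shuffled-genome adaptive threshold, cre motif scanning
#' of each located 6S locus, and pRNA start projection with motif-guided
#' correction plus the NJ tree of the pRNA set. Fully deterministic given
#' the config seed.
#'
#' @param genomes Genome data.frame (id, seq, description).
#' @param config [pipeline_config()] list.
#' @param outdir Optional output directory; when given, intermediate
#'   artifacts are written as plain files (FASTA/GFF3/TSV/newick).
#' @param references_6s data.frame(id, seq) of 6S reference sequences.
#' @param anchor_refs data.frame(id, seq) of anchor references.
#' @param cre_sites Character vector of cre training sites.
#' @param prna_refs data.frame(id, seq, ref_start) of pRNA start references.
#' @return List: `report` (per-genome status table), `features` (all
#'   annotations as a feature table), `prna` (projection results or NULL),
#'   `consensus` (representative table), `config`.
#' @export
run_pipeline <- function(genomes, config = pipeline_config(), outdir = NULL,
                         references_6s = data.frame(
                           id = "ref6S", seq = seed_6s_sequence(),
                           stringsAsFactors = FALSE),
                         anchor_refs = anchor_references(),
                         cre_sites = default_cre_sites(),
                         prna_refs = data.frame(
                           id = "ref6S", seq = seed_6s_sequence(),
                           ref_start = prna_reference_start(),
                           stringsAsFactors = FALSE)) {
  stopifnot(nrow(genomes) >= 1L)
  scheme <- scoring_scheme()
  log_msg("INFO", "pipeline on ", nrow(genomes), " genome(s), seed ",
          config$seed)

  # stage 1: first-pass search
  accepted <- list(); status <- stats::setNames(rep("not_located",
                                                    nrow(genomes)),
                                                genomes$id)
  for (i in seq_len(nrow(genomes))) {
    g <- genomes[i, , drop = FALSE]
    hits <- list()
    for (qi in seq_len(nrow(references_6s))) {
      h <- search(references_6s[qi, , drop = FALSE], g, scheme)
      if (nrow(h)) hits[[length(hits) + 1L]] <- h
    }
    hits <- if (length(hits)) join_overlapping(do.call(rbind, hits)) else empty_hits()
    hits <- filter_by_evalue(hits, config$evalue_cm_like)
    best <- best_hit_per_genome(hits)
    if (!is.null(best)) {
      accepted[[g$id]] <- best
      status[g$id] <- "primary"
    }
  }

  # stage 2: redundancy reduction of accepted 6S sequences
  consensus <- NULL
  if (length(accepted)) {
    seqs6s <- data.frame(
      id = names(accepted),
      seq = vapply(names(accepted), function(gid) {
        hit_sequence(genomes[genomes$id == gid, , drop = FALSE],
                     accepted[[gid]])
      }, character(1)),
      stringsAsFactors = FALSE)
    consensus <- reduce_redundancy(seqs6s, cutoff = config$merge_edit_distance)
    log_msg("INFO", nrow(seqs6s), " accepted 6S sequence(s) reduced to ",
            nrow(consensus), " representative(s)")
  }

  # stage 3: synteny rescue for the remaining genomes
  rescue_queries <- if (!is.null(consensus) && nrow(consensus)) {
    data.frame(id = paste0("cons_", consensus$representative_id),
               seq = consensus$seq, stringsAsFactors = FALSE)
  } else {
    references_6s
  }
  for (gid in names(status)[status == "not_located"]) {
    g <- genomes[genomes$id == gid, , drop = FALSE]
    anchors <- locate_anchors(g, anchor_refs, scheme,
                              evalue_anchor = config$evalue_anchor)
    wins <- build_windows(anchors, W = config$anchor_window_nt,
                          genome_length = nchar(g$seq))
    hits <- rescue_search(g, wins, rescue_queries, scheme,
                          evalue_rescue = config$evalue_rescue)
    best <- best_hit_per_genome(hits)
    if (!is.null(best)) {
      accepted[[gid]] <- best
      status[gid] <- "rescued"
    }
  }

  # assemble ssrS features
  feats <- empty_features()
  for (gid in names(accepted)) {
    b <- accepted[[gid]]
    feats <- rbind(feats, features(
      gid, b$start, b$end, b$strand, "ssrS", score = b$raw_score,
      id = if (status[gid] == "rescued") {
        paste0(gid, "_ssrS_2nd-iteration")
      } else paste0(gid, "_ssrS"),
      pvalue = b$evalue))
  }

  # stage 4: terminators
  for (i in seq_len(nrow(genomes))) {
    g <- genomes[i, , drop = FALSE]
    res <- call_terminators(g, n_shuffles = config$n_shuffles,
                            fraction = config$fdr_fraction,
                            seed = child_seed(config$seed, 40 + i))
    if (nrow(res$accepted)) {
      feats <- rbind(feats, features(
        g$id, res$accepted$hairpin_start, res$accepted$hairpin_end,
        res$accepted$strand, "terminator", score = res$accepted$score))
    }
  }

  # stage 5: cre scanning at located loci
  pwm <- build_pwm(cre_sites)
  for (gid in names(accepted)) {
    g <- genomes[genomes$id == gid, , drop = FALSE]
    ssrS <- feats[feats$genome_id == gid & feats$kind == "ssrS", ][1, ]
    bg <- fit_background(g)
    hits <- scan_locus(pwm, bg, g, ssrS,
                       upstream_nt = config$cre_upstream_nt,
                       p_threshold = config$cre_pvalue)
    if (nrow(hits)) {
      feats <- rbind(feats, features(
        gid, hits$genome_start, hits$genome_end,
        ifelse(hits$strand == "+", ssrS$strand,
               ifelse(ssrS$strand == "+", "-", "+")),
        "cre_site", score = hits$score,
        id = paste0(gid, "_cre_", hits$region_class,
                    "_", seq_len(nrow(hits))),
        pvalue = hits$pvalue))
    }
  }

  # stage 6: pRNA projection
  prna <- NULL
  if (length(accepted) >= 2L) {
    targets <- data.frame(
      id = names(accepted),
      seq = vapply(names(accepted), function(gid) {
        hit_sequence(genomes[genomes$id == gid, , drop = FALSE],
                     accepted[[gid]])
      }, character(1)),
      stringsAsFactors = FALSE)
    prna <- prna_pipeline(targets, prna_refs, length = config$prna_length,
                          max_shift = config$prna_max_shift)
  }

  counts <- function(gid, kind) {
    sum(feats$genome_id == gid & feats$kind == kind)
  }
  report <- data.frame(
    genome_id = genomes$id,
    status = unname(status[genomes$id]),
    n_terminators = vapply(genomes$id, counts, numeric(1), "terminator"),
    n_cre = vapply(genomes$id, counts, numeric(1), "cre_site"),
    seed = config$seed,
    stringsAsFactors = FALSE)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_gff3(feats, file.path(outdir, "annotations.gff3"), genomes)
    utils::write.table(report, file.path(outdir, "report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(consensus)) {
      write_fasta(data.frame(
        id = consensus$representative_id, seq = consensus$seq,
        description = vapply(consensus$member_ids, paste, character(1),
                             collapse = ","),
        stringsAsFactors = FALSE),
        file.path(outdir, "representatives.fasta"))
    }
    if (!is.null(prna)) {
      writeLines(prna$newick, file.path(outdir, "prna_tree.nwk"))
      utils::write.table(
        cbind(base = BASES, as.data.frame(prna$motif$freqs)),
        file.path(outdir, "prna_motif.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(prna$calls[, c("target_id", "start",
                                        "shift_applied", "seq")],
                         file.path(outdir, "prna_calls.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    writeLines(yaml::as.yaml(config), file.path(outdir, "config.yaml"))
  }
  list(report = report, features = feats, prna = prna,
       consensus = consensus, config = config)
}
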