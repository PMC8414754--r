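#' Locate rarA/uspA anchors on a genome
#'
#' Runs the homology search for each anchor reference, applies the anchor
#' e-value threshold and joins overlapping hits; anchors are labeled by the
#' reference id (kind).
#'
#' @param genome One-row genome data.frame.
#' @param anchor_refs data.frame(id, seq) of anchor reference sequences.
#' @param scheme A [scoring_scheme()].
#' @param evalue_anchor Anchor e-value threshold (default 1e-40).
#' @param seed_len Search seed length.
#' @return Feature table of anchors (possibly empty), kind = reference id.
#' @export
locate_anchors <- function(genome, anchor_refs, scheme = scoring_scheme(),
                           evalue_anchor = 1e-40, seed_len = 12L) {
  g <- as_genome(genome, "genome")
  out <- list()
  for (i in seq_len(nrow(anchor_refs))) {
    hits <- search(anchor_refs[i, ], genome, scheme, seed_len = seed_len)
    hits <- filter_by_evalue(hits, evalue_anchor)
    if (nrow(hits)) {
      hits <- join_overlapping(hits)
      out[[length(out) + 1L]] <-
        features(g$id, hits$start, hits$end, hits$strand,
                 kind = anchor_refs$id[i], score = hits$raw_score)
    }
  }
  if (!length(out)) return(empty_features())
  do.call(rbind, out)
}

#' Build rescue windows around anchors
#'
#' Each anchor interval is extended by `W` nucleotides on both sides,
#' clipped to the genome bounds; overlapping windows are merged.
#'
#' @param anchors Anchor feature table (from [locate_anchors()]).
#' @param W Window extension in nt (default 2000).
#' @param genome_length Genome length for clipping.
#' @return data.frame(genome_id, start, end) of merged windows.
#' @export
build_windows <- function(anchors, W = 2000L, genome_length = NULL) {
  stopifnot(W >= 0L)
  if (nrow(anchors) == 0L) {
    return(data.frame(genome_id = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  start <- pmax(0L, anchors$start - W)
  end <- anchors$end + W
  if (!is.null(genome_length)) end <- pmin(as.integer(genome_length), end)
  w <- data.frame(genome_id = anchors$genome_id, start = start, end = end,
                  stringsAsFactors = FALSE)
  w <- w[order(w$genome_id, w$start, w$end), , drop = FALSE]
  out <- list()
  for (gid in unique(w$genome_id)) {
    grp <- w[w$genome_id == gid, , drop = FALSE]
    cur <- grp[1, , drop = FALSE]
    for (i in seq_len(nrow(grp))[-1]) {
      if (grp$start[i] <= cur$end) {
        cur$end <- max(cur$end, grp$end[i])
      } else {
        out[[length(out) + 1L]] <- cur
        cur <- grp[i, , drop = FALSE]
      }
    }
    out[[length(out) + 1L]] <- cur
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Synteny-constrained rescue search
#'
#' Second-iteration search restricted to the window subsequences with
#' exhaustive settings (minimal seed length, no x-drop heuristic) and a
#' relaxed e-value threshold; hit coordinates are lifted back to the genome
#' frame, so hits outside every window are impossible by construction.
#' Optionally, rescue hits overlapping previously accepted hits are
#' dropped.
#'
#' @param genome One-row genome data.frame.
#' @param windows Window table from [build_windows()].
#' @param queries data.frame(id, seq) of query (consensus) sequences.
#' @param scheme A [scoring_scheme()].
#' @param evalue_rescue Relaxed e-value threshold (default 0.1).
#' @param exclude_hits Optional hit table whose intervals must not overlap
#'   reported rescue hits.
#' @return Hit table in genome coordinates, sorted by evalue.
#' @export
rescue_search <- function(genome, windows, queries,
                          scheme = scoring_scheme(), evalue_rescue = 0.1,
                          exclude_hits = NULL) {
  g <- as_genome(genome, "genome")
  windows <- windows[windows$genome_id == g$id, , drop = FALSE]
  if (nrow(windows) == 0L) return(empty_hits())
  out <- list()
  for (wi in seq_len(nrow(windows))) {
    ws <- windows$start[wi]; we <- windows$end[wi]
    sub <- substr(g$seq, ws + 1L, we)
    for (qi in seq_len(nrow(queries))) {
      hits <- search(queries[qi, , drop = FALSE],
                     list(id = g$id, seq = sub), scheme,
                     seed_len = 4L, x_drop = Inf)
      if (nrow(hits)) {
        hits$start <- hits$start + ws
        hits$end <- hits$end + ws
        out[[length(out) + 1L]] <- hits
      }
    }
  }
  if (!length(out)) return(empty_hits())
  hits <- do.call(rbind, out)
  hits <- join_overlapping(hits)
  hits <- filter_by_evalue(hits, evalue_rescue)
  if (!is.null(exclude_hits) && nrow(exclude_hits) && nrow(hits)) {
    keep <- vapply(seq_len(nrow(hits)), function(i) {
      !any(exclude_hits$genome_id == hits$genome_id[i] &
             exclude_hits$start < hits$end[i] &
             exclude_hits$end > hits$start[i])
    }, logical(1))
    hits <- hits[keep, , drop = FALSE]
  }
  rownames(hits) <- NULL
  hits
}
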