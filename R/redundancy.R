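#' Levenshtein edit distance
#'
#' Unit-cost substitution/insertion/deletion distance between two strings.
#'
#' @param a,b Character scalars.
#' @return Integer distance.
#' @export
edit_distance <- function(a, b) {
  as.integer(utils::adist(a, b)[1, 1])
}

#' Collapse exactly identical sequences
#'
#' Identical strings are merged to a single representative; the
#' representative id is the lexicographically smallest member id.
#'
#' @param seqs data.frame(id, seq) or named character vector.
#' @return data.frame with columns `representative_id`, `seq`, `member_ids`
#'   (list column), ordered by representative id.
#' @export
dedupe_exact <- function(seqs) {
  tab <- as_seq_table(seqs)
  groups <- split(tab$id, tab$seq)
  reps <- vapply(groups, function(ids) min(ids), character(1))
  out <- data.frame(representative_id = unname(reps),
                    seq = names(groups), stringsAsFactors = FALSE)
  out$member_ids <- lapply(groups, function(ids) sort(ids))
  out <- out[order(out$representative_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Single-linkage clustering by edit distance
#'
#' Builds the graph with an edge between every pair of sequences at edit
#' distance `<= cutoff` and returns its connected components, i.e. the
#' transitive closure of the pairwise merge rule. Clusters are ordered (and
#' members listed) by smallest member id.
#'
#' @param seqs data.frame(id, seq) or named character vector.
#' @param cutoff Maximum edit distance joining two sequences (default 10).
#' @return List of clusters, each a list with `member_ids`, `members` and
#'   `representative` (consensus, see [consensus_of_cluster()]).
#' @export
cluster_by_distance <- function(seqs, cutoff = 10L) {
  stopifnot(cutoff >= 0L)
  tab <- as_seq_table(seqs)
  n <- nrow(tab)
  if (n == 0L) return(list())
  D <- utils::adist(tab$seq)
  adj <- D <= cutoff
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  clusters <- lapply(split(seq_len(n), comp), function(idx) {
    idx <- idx[order(tab$id[idx])]
    cl <- list(member_ids = tab$id[idx], members = tab$seq[idx])
    cl$representative <- consensus_of_cluster(cl)
    cl
  })
  clusters <- clusters[order(vapply(clusters, function(cl) cl$member_ids[1],
                                    character(1)))]
  names(clusters) <- NULL
  clusters
}

#' Majority consensus of a sequence cluster
#'
#' Members are multiply aligned; per column the majority character wins,
#' columns whose strict majority is the gap are dropped, and ties between
#' bases are broken in the fixed order A < C < G < T (a base always beats a
#' tied gap).
#'
#' @param cluster List with a `members` character vector (>= 1).
#' @return Consensus sequence (character scalar).
#' @export
consensus_of_cluster <- function(cluster) {
  members <- cluster$members
  stopifnot(length(members) >= 1L)
  if (length(members) == 1L) return(members[1])
  aln <- progressive_align(stats::setNames(members,
                                           paste0("m", seq_along(members))))
  mat <- do.call(rbind, lapply(aln$rows, seq_chars))
  cons <- apply(mat, 2, function(col) {
    base_counts <- vapply(BASES, function(b) sum(col == b), integer(1))
    gap_count <- sum(col == "-")
    if (gap_count > max(base_counts)) return(NA_character_)
    BASES[which.max(base_counts)]       # first max = A < C < G < T order
  })
  chars_seq(cons[!is.na(cons)])
}

#' Reduce a sequence set to representative consensus sequences
#'
#' Exact duplicates are merged first; the unique sequences are then
#' clustered at the edit-distance cutoff and each cluster replaced by its
#' majority consensus.
#'
#' @param seqs data.frame(id, seq) or named character vector.
#' @param cutoff Edit-distance cutoff (default 10).
#' @return data.frame with `representative_id`, `seq` (consensus),
#'   `member_ids` (list column of all original member ids).
#' @export
reduce_redundancy <- function(seqs, cutoff = 10L) {
  uniq <- dedupe_exact(seqs)
  clusters <- cluster_by_distance(
    data.frame(id = uniq$representative_id, seq = uniq$seq,
               stringsAsFactors = FALSE), cutoff = cutoff)
  out <- data.frame(
    representative_id = vapply(clusters, function(cl) cl$member_ids[1],
                               character(1)),
    seq = vapply(clusters, function(cl) cl$representative, character(1)),
    stringsAsFactors = FALSE)
  out$member_ids <- lapply(clusters, function(cl) {
    sort(unlist(uniq$member_ids[match(cl$member_ids, uniq$representative_id)]))
  })
  out
}
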