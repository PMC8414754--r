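#' Project reference start sites through an alignment
#'
#' Maps each reference start to its alignment column, takes the modal
#' column across references (ties: smallest column), and maps that column
#' back to every row's ungapped coordinate. Gap columns are resolved to the
#' nearest residue to the left and flagged inexact.
#'
#' @param aln A `sixs_msa` containing the reference rows and the targets.
#' @param references data.frame(row_id, ref_start) (or named integer
#'   vector); `ref_start` is 0-based on the ungapped reference.
#' @return data.frame: `target_id`, `start` (0-based), `exact`.
#' @export
project_starts <- function(aln, references) {
  if (is.numeric(references)) {
    references <- data.frame(row_id = names(references),
                             ref_start = unname(references),
                             stringsAsFactors = FALSE)
  }
  if (is.null(references) || nrow(references) == 0L) {
    stop("at least one reference is required", call. = FALSE)
  }
  cols <- vapply(seq_len(nrow(references)), function(i) {
    map_to_column(aln, references$row_id[i], references$ref_start[i])
  }, integer(1))
  tab <- table(cols)
  modal <- as.integer(names(tab)[tab == max(tab)])
  col <- min(modal)
  targets <- setdiff(aln$row_ids, references$row_id)
  res <- lapply(targets, function(id) map_to_position(aln, id, col))
  data.frame(target_id = targets,
             start = vapply(res, `[[`, integer(1), "position"),
             exact = vapply(res, `[[`, logical(1), "exact"),
             stringsAsFactors = FALSE)
}

#' Extract a pRNA sequence from its 6S template
#'
#' The pRNA is the antisense product of RNA polymerase reading the 6S RNA
#' as template; the base at `start` pairs with the pRNA 5' nucleotide.
#' `toward_5prime` (default) reads the template towards its 5' end,
#' returning the reverse complement of
#' `seq6s[start - length + 1 .. start]`; `toward_3prime` reads the other
#' way.
#'
#' @param seq6s 6S sequence (template strand, 5'->3').
#' @param start 0-based template position of the pRNA 5' pairing base.
#' @param length pRNA length (default 16).
#' @param direction "toward_5prime" or "toward_3prime".
#' @return pRNA sequence (DNA alphabet) of the requested length.
#' @export
extract_prna <- function(seq6s, start, length = 16L,
                         direction = c("toward_5prime", "toward_3prime")) {
  direction <- match.arg(direction)
  n <- nchar(seq6s)
  if (direction == "toward_5prime") {
    from <- start - length + 1L; to <- start
  } else {
    from <- start; to <- start + length - 1L
  }
  if (from < 0L || to >= n) stop("pRNA window out of bounds", call. = FALSE)
  revcomp(substr(seq6s, from + 1L, to + 1L))
}

#' Build a base-frequency motif profile with per-column information content
#'
#' @param prna_seqs Character vector (>= 2) of equal-length sequences.
#' @return `sixs_motif` list: `width`, `freqs` (4 x width), `ic`
#'   (information content per column, `2 - H` bits, no small-sample
#'   correction), `n` (number of sequences), `consensus` (majority base per
#'   column, ties A < C < G < T).
#' @export
build_motif <- function(prna_seqs) {
  stopifnot(length(prna_seqs) >= 2L)
  if (length(unique(nchar(prna_seqs))) != 1L) {
    stop("sequences must have equal lengths", call. = FALSE)
  }
  w <- nchar(prna_seqs[1])
  mat <- do.call(rbind, lapply(prna_seqs, seq_chars))
  freqs <- vapply(seq_len(w), function(j) {
    vapply(BASES, function(b) mean(mat[, j] == b), numeric(1))
  }, numeric(4))
  dimnames(freqs) <- list(BASES, NULL)
  H <- apply(freqs, 2, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  structure(list(width = w, freqs = freqs, ic = 2 - H,
                 n = length(prna_seqs),
                 consensus = chars_seq(BASES[apply(freqs, 2, which.max)])),
            class = "sixs_motif")
}

motif_loglik <- function(motif, seq) {
  idx <- match(seq_chars(seq), BASES)
  stopifnot(length(idx) == motif$width, !anyNA(idx))
  # pseudocount 0.5 on the underlying counts avoids -Inf
  pc <- (motif$freqs * motif$n + 0.5) / (motif$n + 2)
  sum(log(pc[cbind(idx, seq_len(motif$width))]))
}

#' Motif-guided correction of pRNA start sites
#'
#' For each call, candidate shifts in `-max_shift..max_shift` are evaluated
#' by the motif log-likelihood of the re-extracted pRNA window; the
#' best-scoring shift is adopted (ties: smaller absolute shift, then the
#' negative one). A single adjustment pass is made.
#'
#' @param calls data.frame with `target_id`, `start`, and the template
#'   sequences via `seqs` (named character vector keyed by target_id).
#' @param motif A `sixs_motif` built from the current pRNA set.
#' @param seqs Named character vector of 6S template sequences.
#' @param max_shift Maximum absolute shift (default 3).
#' @param length pRNA length.
#' @param direction Extraction direction (see [extract_prna()]).
#' @return `calls` with updated `start`, plus `shift_applied`, `seq` and
#'   `motif_score` columns.
#' @export
adjust_starts <- function(calls, motif, seqs, max_shift = 3L, length = 16L,
                          direction = "toward_5prime") {
  stopifnot(max_shift >= 0L)
  shifts <- seq(-max_shift, max_shift)
  ord <- order(abs(shifts), shifts)        # |shift| asc, negative first
  shifts <- shifts[ord]
  out <- calls
  out$shift_applied <- 0L
  out$seq <- NA_character_
  out$motif_score <- NA_real_
  for (i in seq_len(nrow(calls))) {
    s6 <- seqs[[calls$target_id[i]]]
    best <- NULL
    for (sh in shifts) {
      st <- calls$start[i] + sh
      p <- tryCatch(extract_prna(s6, st, length, direction),
                    error = function(e) NULL)
      if (is.null(p)) next
      sc <- motif_loglik(motif, p)
      if (is.null(best) || sc > best$sc) best <- list(sh = sh, sc = sc, p = p)
    }
    if (is.null(best)) stop("no in-bounds shift for target ",
                            calls$target_id[i], call. = FALSE)
    out$start[i] <- calls$start[i] + best$sh
    out$shift_applied[i] <- best$sh
    out$seq[i] <- best$p
    out$motif_score[i] <- best$sc
  }
  out
}

#' Neighbor-joining tree of pRNA sequences
#'
#' Trims all sequences (and the consensus) to positions 1-15, computes
#' pairwise Hamming distances divided by 15, and reconstructs the
#' Saitou-Nei neighbor-joining tree, returned as an unrooted newick string
#' with branch lengths.
#'
#' @param seqs data.frame(id, seq) or named character vector.
#' @param consensus Optional named character vector (or list(id, seq)) for
#'   the consensus taxon added to the tree.
#' @param positions Range of 1-based positions retained (default 1:15).
#' @return Newick string.
#' @export
nj_tree <- function(seqs, consensus = NULL, positions = 1:15) {
  tab <- as_seq_table(seqs)
  if (!is.null(consensus)) {
    cs <- if (is.list(consensus)) {
      data.frame(id = consensus$id, seq = consensus$seq,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(id = names(consensus) %||% "consensus",
                 seq = unname(consensus), stringsAsFactors = FALSE)
    }
    tab <- rbind(tab, cs)
  }
  if (nrow(tab) < 3L) stop("need at least 3 taxa", call. = FALSE)
  trimmed <- substr(tab$seq, min(positions), max(positions))
  stopifnot(all(nchar(trimmed) == length(positions)))
  mat <- do.call(rbind, lapply(trimmed, seq_chars))
  n <- nrow(mat)
  D <- matrix(0, n, n, dimnames = list(tab$id, tab$id))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      D[i, j] <- D[j, i] <- sum(mat[i, ] != mat[j, ]) / length(positions)
    }
  }
  tr <- ape::nj(stats::as.dist(D))
  ape::write.tree(tr)
}

#' End-to-end pRNA projection for a set of 6S sequences
#'
#' Aligns targets together with the references, projects the reference
#' starts, extracts pRNAs, builds the motif, applies the motif-guided shift
#' correction and builds the NJ tree of the corrected pRNAs plus their
#' consensus.
#'
#' @param targets data.frame(id, seq) of 6S sequences.
#' @param references data.frame(id, seq, ref_start).
#' @param length pRNA length (default 16).
#' @param max_shift Maximum correction shift (default 3).
#' @param direction Extraction direction.
#' @return List: `calls` (corrected start table with pRNA sequences),
#'   `motif`, `newick`, `alignment`.
#' @export
prna_pipeline <- function(targets, references, length = 16L, max_shift = 3L,
                          direction = "toward_5prime") {
  allseq <- rbind(targets[, c("id", "seq")], references[, c("id", "seq")])
  aln <- progressive_align(allseq)
  proj <- project_starts(aln, data.frame(row_id = references$id,
                                         ref_start = references$ref_start,
                                         stringsAsFactors = FALSE))
  seqs <- stats::setNames(targets$seq, targets$id)
  proj$seq <- vapply(seq_len(nrow(proj)), function(i) {
    extract_prna(seqs[[proj$target_id[i]]], proj$start[i], length, direction)
  }, character(1))
  motif <- build_motif(proj$seq)
  calls <- adjust_starts(proj, motif, seqs, max_shift, length, direction)
  motif <- build_motif(calls$seq)
  nwk <- if (nrow(calls) >= 2L) {
    nj_tree(data.frame(id = calls$target_id, seq = calls$seq,
                       stringsAsFactors = FALSE),
            consensus = c(consensus = motif$consensus))
  } else NA_character_
  list(calls = calls, motif = motif, newick = nwk, alignment = aln)
}
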