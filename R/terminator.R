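#' Dinucleotide-preserving sequence shuffle
#'
#' Uniformly samples a sequence with exactly the same mononucleotide and
#' dinucleotide multisets as the input (hence identical first and last
#' characters), via the Eulerian-path construction: the input defines a
#' multigraph with one edge per adjacent base pair; a random "last edge" is
#' drawn for every vertex except the terminal one until those edges form an
#' arborescence towards the terminal vertex, remaining out-edges are
#' shuffled, and the Eulerian walk is read off.
#'
#' @param seq Input string (length >= 2).
#' @param seed Integer seed (deterministic given the seed).
#' @return Shuffled string with identical dinucleotide composition.
#' @export
dinucleotide_shuffle <- function(seq, seed) {
  chars <- seq_chars(seq)
  n <- length(chars)
  if (n < 2L) stop("sequence must have length >= 2", call. = FALSE)
  first <- chars[1]; last <- chars[n]
  verts <- unique(chars)
  out_edges <- split(chars[-1], chars[-n])        # per-vertex multiset of targets
  with_seed(seed, {
    nonterm <- setdiff(names(out_edges), last)
    repeat {
      last_edge <- vapply(out_edges[nonterm], function(tg) {
        tg[sample.int(length(tg), 1L)]
      }, character(1))
      # every vertex with out-edges must reach `last` following last edges
      ok <- TRUE
      for (v in nonterm) {
        cur <- v; steps <- 0L
        while (cur != last) {
          if (!(cur %in% nonterm) || steps > length(verts)) { ok <- FALSE; break }
          cur <- last_edge[[cur]]
          steps <- steps + 1L
        }
        if (!ok) break
      }
      if (ok) break
    }
    ordered <- lapply(names(out_edges), function(v) {
      tg <- out_edges[[v]]
      if (v %in% nonterm) {
        le <- last_edge[[v]]
        tg <- tg[-match(le, tg)]
        c(if (length(tg)) tg[sample.int(length(tg))], le)
      } else {
        if (length(tg) > 1L) tg[sample.int(length(tg))] else tg
      }
    })
    names(ordered) <- names(out_edges)
    ptr <- stats::setNames(rep(1L, length(ordered)), names(ordered))
    res <- character(n)
    res[1] <- first
    cur <- first
    for (i in 2:n) {
      nxt <- ordered[[cur]][ptr[[cur]]]
      ptr[[cur]] <- ptr[[cur]] + 1L
      res[i] <- nxt
      cur <- nxt
    }
    chars_seq(res)
  })
}

PAIR_SCORES <- {
  m <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  m["G", "C"] <- m["C", "G"] <- 3
  m["A", "T"] <- m["T", "A"] <- 2
  m["G", "T"] <- m["T", "G"] <- 1
  m
}

terminator_params <- function(min_stem = 4L, max_stem = 25L, loop_min = 3L,
                              loop_max = 10L, loop_penalty = 0.5,
                              utract_len = 8L) {
  list(min_stem = min_stem, max_stem = max_stem, loop_min = loop_min,
       loop_max = loop_max, loop_penalty = loop_penalty,
       utract_len = utract_len)
}

scan_hairpins_one_strand <- function(chars, params) {
  n <- length(chars)
  idx <- match(chars, BASES)
  t_cum <- c(0, cumsum(chars == "T"))
  out <- list()
  for (l in params$loop_min:params$loop_max) {
    j <- seq_len(n)                      # 1-based loop start candidates
    stem_len <- integer(n)
    stem_score <- numeric(n)
    alive <- rep(TRUE, n)
    for (k in seq_len(params$max_stem)) {
      left <- j - k
      right <- j + l + k - 1L
      inb <- left >= 1L & right <= n
      p <- numeric(n)
      sel <- alive & inb
      if (!any(sel)) break
      p[sel] <- PAIR_SCORES[cbind(idx[left[sel]], idx[right[sel]])]
      alive <- sel & p > 0
      stem_len[alive] <- k
      stem_score[alive] <- stem_score[alive] + p[alive]
    }
    hit <- which(stem_len >= params$min_stem)
    if (!length(hit)) next
    k_j <- stem_len[hit]
    hp_start <- hit - k_j - 1L                   # 0-based
    hp_end <- hit + l + k_j - 1L                 # 0-based exclusive
    ut_from <- hp_end + 1L                       # 1-based downstream start
    ut_to <- pmin(n, hp_end + params$utract_len)
    u_count <- ifelse(ut_from <= ut_to,
                      t_cum[ut_to + 1L] - t_cum[ut_from], 0)
    out[[length(out) + 1L]] <- data.frame(
      hairpin_start = hp_start, hairpin_end = hp_end,
      stem_len = k_j, loop_len = l,
      score = stem_score[hit] - params$loop_penalty * (l - params$loop_min) +
        u_count,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(hairpin_start = integer(0), hairpin_end = integer(0),
                      stem_len = integer(0), loop_len = integer(0),
                      score = numeric(0)))
  }
  do.call(rbind, out)
}

#' Score Rho-independent terminator candidates
#'
#' Enumerates, on both strands, every inverted repeat with a maximal stem of
#' at least `min_stem` base pairs (G-C, A-T and G-T wobble pairs allowed)
#' around a 3-10 nt loop, scored as the sum of pair scores (G-C = 3,
#' A-T = 2, G-T = 1) minus 0.5 per loop nucleotide beyond 3, plus the count
#' of T in the 8 nt 3' of the hairpin. For each loop placement the stem is
#' extended outward as far as pairing allows.
#'
#' @param genome One-row genome data.frame (or plain string).
#' @param params See `terminator_params()` internals; defaults match the
#'   description above.
#' @return Candidate table (genome_id, hairpin_start, hairpin_end, strand,
#'   stem_len, loop_len, score); coordinates are 0-based half-open on the
#'   forward strand.
#' @export
score_terminators <- function(genome, params = terminator_params()) {
  g <- as_genome(genome, "genome")
  n <- nchar(g$seq)
  fw <- scan_hairpins_one_strand(seq_chars(g$seq), params)
  fw$strand <- rep("+", nrow(fw))
  rv <- scan_hairpins_one_strand(seq_chars(revcomp(g$seq)), params)
  if (nrow(rv)) {
    tmp <- n - rv$hairpin_end
    rv$hairpin_end <- n - rv$hairpin_start
    rv$hairpin_start <- tmp
  }
  rv$strand <- rep("-", nrow(rv))
  cands <- rbind(fw, rv)
  if (!nrow(cands)) {
    cands$genome_id <- character(0)
  } else {
    cands$genome_id <- g$id
  }
  cands <- cands[, c("genome_id", "hairpin_start", "hairpin_end", "strand",
                     "stem_len", "loop_len", "score")]
  cands <- cands[order(cands$hairpin_start, cands$hairpin_end, cands$strand), ]
  rownames(cands) <- NULL
  cands
}

#' Shuffled-genome adaptive significance threshold
#'
#' Chooses the smallest candidate threshold t (among the distinct observed
#' original scores, ascending) such that the average number of shuffled-
#' genome hits with score >= t is no more than `fraction` times the number
#' of original hits with score >= t. With the default fraction 0.05 this
#' means: if the original genome yields 100 hits above a score of 90, the
#' shuffled genomes may average at most 5 hits above 90 for 90 to be
#' accepted, otherwise a higher threshold is chosen. If no threshold
#' qualifies the result is +Inf and nothing is accepted.
#'
#' @param original_scores Numeric scores of candidates on the original
#'   genome.
#' @param shuffled_score_lists List (one element per shuffle) of numeric
#'   score vectors from the shuffled genomes.
#' @param fraction Acceptance fraction in (0, 1] (default 0.05).
#' @return List with `threshold`, `n_original_above`, `mean_shuffled_above`
#'   and `accepted` (indices into `original_scores`).
#' @export
adaptive_threshold <- function(original_scores, shuffled_score_lists,
                               fraction = 0.05) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("fraction must be in (0, 1]", call. = FALSE)
  }
  stopifnot(length(shuffled_score_lists) >= 1L)
  if (!length(original_scores)) {
    return(list(threshold = Inf, n_original_above = 0L,
                mean_shuffled_above = 0, accepted = integer(0)))
  }
  for (t in sort(unique(original_scores))) {
    n_orig <- sum(original_scores >= t)
    mean_shuf <- mean(vapply(shuffled_score_lists,
                             function(s) sum(s >= t), numeric(1)))
    if (mean_shuf <= fraction * n_orig) {
      return(list(threshold = t, n_original_above = n_orig,
                  mean_shuffled_above = mean_shuf,
                  accepted = which(original_scores >= t)))
    }
  }
  list(threshold = Inf, n_original_above = 0L, mean_shuffled_above = 0,
       accepted = integer(0))
}

#' Merge overlapping terminator candidates
#'
#' Same-strand candidates whose hairpin intervals overlap are merged
#' transitively; the highest-scoring member (ties: leftmost) represents the
#' merged group with its own coordinates and score.
#'
#' @param cands Candidate table from [score_terminators()].
#' @return Reduced candidate table.
#' @export
merge_overlapping_terminators <- function(cands) {
  if (!nrow(cands)) return(cands)
  out <- list()
  for (key in unique(paste(cands$genome_id, cands$strand))) {
    grp <- cands[paste(cands$genome_id, cands$strand) == key, , drop = FALSE]
    grp <- grp[order(grp$hairpin_start, grp$hairpin_end), , drop = FALSE]
    cur <- grp[1, , drop = FALSE]
    cur_end <- cur$hairpin_end
    for (i in seq_len(nrow(grp))[-1]) {
      row <- grp[i, , drop = FALSE]
      if (row$hairpin_start < cur_end) {
        cur_end <- max(cur_end, row$hairpin_end)
        if (row$score > cur$score) cur <- row
      } else {
        out[[length(out) + 1L]] <- cur
        cur <- row
        cur_end <- row$hairpin_end
      }
    }
    out[[length(out) + 1L]] <- cur
  }
  merged <- do.call(rbind, out)
  merged <- merged[order(merged$hairpin_start, merged$strand), , drop = FALSE]
  rownames(merged) <- NULL
  merged
}

#' Call terminators on a genome with the adaptive threshold
#'
#' Scores hairpin/U-tract candidates on the genome, rescoring after each of
#' `n_shuffles` dinucleotide-preserving genome shuffles, chooses the
#' adaptive threshold and merges the accepted overlapping candidates.
#'
#' @param genome One-row genome data.frame.
#' @param n_shuffles Number of genome shuffles (default 10).
#' @param fraction Acceptance fraction (default 0.05).
#' @param seed Integer seed driving the shuffles.
#' @param params Scorer parameters.
#' @return List with `accepted` (merged candidate table), `threshold`,
#'   `candidates` and the threshold diagnostics.
#' @export
call_terminators <- function(genome, n_shuffles = 10L, fraction = 0.05,
                             seed = 1L, params = terminator_params()) {
  g <- as_genome(genome, "genome")
  cands <- score_terminators(genome, params)
  shuf_scores <- lapply(seq_len(n_shuffles), function(i) {
    sh <- dinucleotide_shuffle(g$seq, child_seed(seed, i))
    score_terminators(sh, params)$score
  })
  th <- adaptive_threshold(cands$score, shuf_scores, fraction)
  accepted <- merge_overlapping_terminators(cands[th$accepted, , drop = FALSE])
  log_msg("INFO", sprintf("terminators %s: threshold=%s accepted=%d of %d",
                          g$id, format(th$threshold), nrow(accepted),
                          nrow(cands)))
  list(accepted = accepted, threshold = th$threshold,
       n_original_above = th$n_original_above,
       mean_shuffled_above = th$mean_shuffled_above, candidates = cands)
}
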