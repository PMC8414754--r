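#' Ungapped local search scoring scheme with Karlin-Altschul statistics
#'
#' Builds a match/mismatch scoring scheme and solves for the Karlin-Altschul
#' scale parameter lambda, so that raw segment scores S convert to e-values
#' as `K * m * n * exp(-lambda * S)` for query/target lengths m, n. The
#' expected per-position score under the background must be negative.
#'
#' @param match Match score (> 0).
#' @param mismatch Mismatch score (< 0).
#' @param background Base composition (length 4, A/C/G/T, sums to 1).
#' @param K Karlin-Altschul K constant (configured, not estimated).
#' @return List with class `sixs_scheme`: match, mismatch, background,
#'   lambda, K.
#' @export
scoring_scheme <- function(match = 1L, mismatch = -1L,
                           background = rep(0.25, 4), K = 0.1) {
  stopifnot(length(background) == 4L, abs(sum(background) - 1) < 1e-9,
            all(background >= 0), K > 0)
  scheme <- list(match = match, mismatch = mismatch,
                 background = background, K = K)
  scheme$lambda <- solve_lambda(scheme)
  class(scheme) <- "sixs_scheme"
  scheme
}

#' Solve the Karlin-Altschul scale equation
#'
#' Finds the unique positive root lambda of
#' `sum_ij p_i p_j exp(lambda * s_ij) = 1` by bracketed root-finding, where
#' `s_ij` is `match` on the diagonal and `mismatch` off it.
#'
#' @param scheme List with `match`, `mismatch`, `background` (see
#'   [scoring_scheme()]).
#' @return The positive root lambda (relative tolerance about 1e-12).
#' @export
solve_lambda <- function(scheme) {
  p <- scheme$background
  smat <- matrix(scheme$mismatch, 4, 4)
  diag(smat) <- scheme$match
  pp <- outer(p, p)
  escore <- sum(pp * smat)
  if (escore >= 0) {
    stop("expected per-position score must be negative for significance",
         call. = FALSE)
  }
  if (scheme$match <= 0) stop("match score must be positive", call. = FALSE)
  f <- function(l) sum(pp * exp(l * smat)) - 1
  hi <- 1
  while (f(hi) <= 0) hi <- hi * 2
  lo <- 1e-12
  if (f(lo) >= 0) stop("no positive root bracket found", call. = FALSE)
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-14)$root
  # one Newton polish for full relative precision
  fp <- function(l) sum(pp * smat * exp(l * smat))
  root - f(root) / fp(root)
}

as_genome <- function(x, default_id = "seq") {
  if (is.character(x) && length(x) == 1L) {
    return(list(id = default_id, seq = x))
  }
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    return(list(id = x$id, seq = x$seq))
  }
  if (is.list(x) && !is.null(x$seq)) return(list(id = x$id %||% default_id, seq = x$seq))
  stop("cannot interpret input as a genome", call. = FALSE)
}

empty_hits <- function() {
  data.frame(genome_id = character(0), query_id = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             raw_score = numeric(0), evalue = numeric(0),
             stringsAsFactors = FALSE)
}

# All exact seed_len-mer match positions (1-based) between q and t chars.
seed_matches <- function(qseq, tseq, seed_len) {
  m <- nchar(qseq); n <- nchar(tseq)
  if (m < seed_len || n < seed_len) {
    return(data.frame(qi = integer(0), tj = integer(0)))
  }
  qs <- substring(qseq, seq_len(m - seed_len + 1L),
                  seq_len(m - seed_len + 1L) + seed_len - 1L)
  ts <- substring(tseq, seq_len(n - seed_len + 1L),
                  seq_len(n - seed_len + 1L) + seed_len - 1L)
  tpos <- split(seq_along(ts), ts)
  hitlists <- tpos[qs]
  nhit <- lengths(hitlists)
  if (sum(nhit) == 0L) return(data.frame(qi = integer(0), tj = integer(0)))
  data.frame(qi = rep(seq_along(qs), nhit), tj = unlist(hitlists, use.names = FALSE))
}

# X-drop extension of all seeds on one diagonal; returns unique segments
# (relative coordinates into the diagonal overlap) with their scores.
extend_on_diagonal <- function(s, seed_rel_start, seed_len, x_drop) {
  L <- length(s)
  cr <- cumsum(s)
  segs <- vector("list", length(seed_rel_start))
  for (i in seq_along(seed_rel_start)) {
    a0 <- seed_rel_start[i]
    b0 <- a0 + seed_len - 1L
    # right extension: running score relative to seed right end
    bstar <- b0
    if (b0 < L) {
      run <- cr[(b0 + 1L):L] - cr[b0]
      stop_at <- which(cummax(run) - run > x_drop)[1]
      lim <- if (is.na(stop_at)) length(run) else stop_at
      best <- which.max(run[seq_len(lim)])
      if (run[best] > 0) bstar <- b0 + best
    }
    # left extension: running score relative to seed left start
    astar <- a0
    if (a0 > 1L) {
      left_cum <- if (a0 >= 2L) c(0, cr[seq_len(a0 - 1L)]) else 0
      # extension by k: segment [a0-k, a0-1] adds cr[a0-1] - cr[a0-k-1]
      k <- seq_len(a0 - 1L)
      run <- cr[a0 - 1L] - left_cum[a0 - k]
      stop_at <- which(cummax(run) - run > x_drop)[1]
      lim <- if (is.na(stop_at)) length(run) else stop_at
      best <- which.max(run[seq_len(lim)])
      if (run[best] > 0) astar <- a0 - best
    }
    prev <- if (astar >= 2L) cr[astar - 1L] else 0
    segs[[i]] <- c(astar, bstar, cr[bstar] - prev)
  }
  out <- unique(do.call(rbind, segs))
  out
}

#' Seeded ungapped local similarity search
#'
#' Seed-and-extend search of a query against both strands of a target.
#' Exact `seed_len`-mer matches are extended ungapped in both directions
#' until the running score drops `x_drop` below its maximum; the reported
#' interval is the maximal-scoring extension. Significance follows
#' Karlin-Altschul: `evalue = K * m * n * exp(-lambda * S)`.
#'
#' @param query,target Genome rows (or plain strings).
#' @param scheme A [scoring_scheme()].
#' @param seed_len Exact-match seed length (>= 4).
#' @param x_drop Extension drop-off; `Inf` disables the heuristic and always
#'   takes the best segment through each seed.
#' @return Hit table (genome_id, query_id, start, end, strand, raw_score,
#'   evalue), sorted by evalue; coordinates are 0-based half-open on the
#'   target. The strand is the orientation of the query match.
#' @export
search <- function(query, target, scheme, seed_len = 12L, x_drop = 20) {
  stopifnot(seed_len >= 4L)
  q <- as_genome(query, "query")
  t <- as_genome(target, "target")
  m <- nchar(q$seq); n <- nchar(t$seq)
  tc <- seq_chars(t$seq)
  res <- list()
  for (strand in c("+", "-")) {
    qseq <- if (strand == "+") q$seq else revcomp(q$seq)
    qc <- seq_chars(qseq)
    sm <- seed_matches(qseq, t$seq, seed_len)
    if (nrow(sm) == 0L) next
    d <- sm$tj - sm$qi
    for (dg in unique(d)) {
      rows <- sm[d == dg, , drop = FALSE]
      lo <- max(1L, 1L - dg)
      hi <- min(m, n - dg)
      idx <- lo:hi
      s <- ifelse(qc[idx] == tc[idx + dg], scheme$match, scheme$mismatch)
      segs <- extend_on_diagonal(s, rows$qi - lo + 1L, seed_len, x_drop)
      if (is.null(segs) || nrow(segs) == 0L) next
      qa <- segs[, 1] + lo - 1L          # 1-based query start on this strand
      qb <- segs[, 2] + lo - 1L          # 1-based query end
      res[[length(res) + 1L]] <- data.frame(
        genome_id = t$id, query_id = q$id,
        start = as.integer(qa + dg - 1L), end = as.integer(qb + dg),
        strand = strand, raw_score = segs[, 3],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) return(empty_hits())
  hits <- unique(do.call(rbind, res))
  hits$evalue <- scheme$K * m * n * exp(-scheme$lambda * hits$raw_score)
  hits <- hits[order(hits$evalue, -hits$raw_score, hits$start, hits$strand), ]
  rownames(hits) <- NULL
  hits
}

#' Join overlapping same-strand hits
#'
#' Hits on the same genome and strand whose intervals overlap by at least
#' one nucleotide are merged transitively into a single hit spanning their
#' union; the merged score is the maximum member score and the merged
#' e-value the minimum member e-value.
#'
#' @param hits Hit table.
#' @return Hit table with overlapping hits joined, sorted by evalue.
#' @export
join_overlapping <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  out <- list()
  for (key in unique(paste(hits$genome_id, hits$strand))) {
    grp <- hits[paste(hits$genome_id, hits$strand) == key, , drop = FALSE]
    grp <- grp[order(grp$start, grp$end), , drop = FALSE]
    cur <- grp[1, , drop = FALSE]
    for (i in seq_len(nrow(grp))[-1]) {
      row <- grp[i, , drop = FALSE]
      if (row$start < cur$end) {        # >= 1 nt overlap
        cur$end <- max(cur$end, row$end)
        if (row$evalue < cur$evalue) cur$query_id <- row$query_id
        cur$raw_score <- max(cur$raw_score, row$raw_score)
        cur$evalue <- min(cur$evalue, row$evalue)
      } else {
        out[[length(out) + 1L]] <- cur
        cur <- row
      }
    }
    out[[length(out) + 1L]] <- cur
  }
  joined <- do.call(rbind, out)
  joined <- joined[order(joined$evalue, -joined$raw_score, joined$start), ]
  rownames(joined) <- NULL
  joined
}

#' Best hit of a genome
#'
#' The hit with the minimal e-value; ties are broken by higher raw score,
#' then leftmost start, then + strand. An empty input returns NULL (the
#' genome is reported as not located).
#'
#' @param hits Hit table for one genome.
#' @return One-row hit table or NULL.
#' @export
best_hit_per_genome <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0L) return(NULL)
  stopifnot(length(unique(hits$genome_id)) == 1L)
  ord <- order(hits$evalue, -hits$raw_score, hits$start, hits$strand)
  out <- hits[ord[1], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter hits by e-value threshold
#'
#' @param hits Hit table.
#' @param threshold Keep hits with `evalue <= threshold`.
#' @return Filtered hit table, order preserved.
#' @export
filter_by_evalue <- function(hits, threshold) {
  stopifnot(threshold > 0)
  out <- hits[hits$evalue <= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}
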