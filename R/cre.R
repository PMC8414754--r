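#' Build a position weight matrix from aligned sites
#'
#' @param sites Character vector (>= 2) of equal-length sites.
#' @param pseudocount Added to every base count per column (default 0.5).
#' @return `sixs_pwm` list: `width`, `probs` (4 x width, columns sum to 1),
#'   `pseudocount`.
#' @export
build_pwm <- function(sites, pseudocount = 0.5) {
  stopifnot(length(sites) >= 2L, pseudocount >= 0)
  if (length(unique(nchar(sites))) != 1L) {
    stop("sites must have equal lengths", call. = FALSE)
  }
  w <- nchar(sites[1])
  mat <- do.call(rbind, lapply(sites, seq_chars))
  counts <- vapply(seq_len(w), function(j) {
    vapply(BASES, function(b) sum(mat[, j] == b), numeric(1))
  }, numeric(4))
  if (!all(colSums(counts) == length(sites))) {
    stop("sites contain non-ACGT characters", call. = FALSE)
  }
  probs <- (counts + pseudocount) / (length(sites) + 4 * pseudocount)
  dimnames(probs) <- list(BASES, NULL)
  structure(list(width = w, probs = probs, pseudocount = pseudocount),
            class = "sixs_pwm")
}

#' Reverse-complement a PWM
#'
#' @param pwm A `sixs_pwm`.
#' @return The PWM describing the motif on the opposite strand.
#' @export
revcomp_pwm <- function(pwm) {
  probs <- pwm$probs[c("T", "G", "C", "A"), rev(seq_len(pwm$width)),
                     drop = FALSE]
  rownames(probs) <- BASES
  structure(list(width = pwm$width, probs = probs,
                 pseudocount = pwm$pseudocount), class = "sixs_pwm")
}

#' Fit a first-order Markov background from a genome
#'
#' The transition matrix holds smoothed conditional dinucleotide
#' frequencies; the initial distribution is the (smoothed) mononucleotide
#' composition.
#'
#' @param genome One-row genome data.frame or plain string (length >= 2).
#' @param smoothing Pseudo-count added to every dinucleotide count
#'   (default 0.5), keeping all entries strictly positive.
#' @return `sixs_markov_bg` list: `initial` (length 4), `transition`
#'   (4 x 4, rows sum to 1).
#' @export
fit_background <- function(genome, smoothing = 0.5) {
  g <- as_genome(genome, "genome")
  chars <- seq_chars(g$seq)
  stopifnot(length(chars) >= 2L)
  idx <- match(chars, BASES)
  counts <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  tab <- table(factor(idx[-length(idx)], levels = 1:4),
               factor(idx[-1], levels = 1:4))
  counts[] <- as.numeric(tab)
  counts <- counts + smoothing
  transition <- counts / rowSums(counts)
  mono <- tabulate(idx, 4) + smoothing
  initial <- mono / sum(mono)
  names(initial) <- BASES
  structure(list(initial = initial, transition = transition),
            class = "sixs_markov_bg")
}

#' Log-odds score of a window under PWM vs Markov background (bits)
#'
#' `sum_i log2(pwm[b_i, i] / P_bg(b_i | b_{i-1}))`; the first position is
#' conditioned on `preceding_base` when given, otherwise on the background's
#' initial distribution.
#'
#' @param pwm A `sixs_pwm`.
#' @param window String of length `pwm$width`.
#' @param bg A `sixs_markov_bg`.
#' @param preceding_base Base immediately 5' of the window, or NULL.
#' @return Score in bits.
#' @export
logodds_score <- function(pwm, window, bg, preceding_base = NULL) {
  chars <- seq_chars(window)
  if (length(chars) != pwm$width) {
    stop("window length must equal pwm width", call. = FALSE)
  }
  idx <- match(chars, BASES)
  stopifnot(!anyNA(idx))
  p_bg <- numeric(pwm$width)
  p_bg[1] <- if (is.null(preceding_base)) {
    bg$initial[idx[1]]
  } else {
    bg$transition[match(preceding_base, BASES), idx[1]]
  }
  if (pwm$width > 1L) {
    p_bg[-1] <- bg$transition[cbind(idx[-pwm$width], idx[-1])]
  }
  sum(log2(pwm$probs[cbind(idx, seq_len(pwm$width))]) - log2(p_bg))
}

#' Exact score-to-p-value table under the Markov background
#'
#' Computes the exact distribution of the log-odds score over all
#' width-length windows drawn from the background chain (preceding base from
#' the initial distribution), by dynamic programming over (position, last
#' base, discretized score). Per-position score increments are rounded down
#' to multiples of `resolution`; the p-value lookup compensates by the
#' maximal total rounding loss, so reported p-values are conservative (never
#' smaller than exact) and within `width * resolution` of the exact tail in
#' score units.
#'
#' @param pwm A `sixs_pwm`.
#' @param bg A `sixs_markov_bg`.
#' @param resolution Score bin width in bits (default 1e-3).
#' @return `sixs_pvalue_table` with element `pvalue`, a function mapping a
#'   score (bits) to P(score >= s) under the background.
#' @export
score_pvalue_table <- function(pwm, bg, resolution = 1e-3) {
  stopifnot(resolution > 0)
  w <- pwm$width
  lp <- log2(pwm$probs)
  lt <- log2(bg$transition)
  # increment bins for position i given previous base a and current base b
  inc <- function(i) floor((matrix(lp[, i], 4, 4, byrow = TRUE) - lt) /
                             resolution)
  incs <- lapply(seq_len(w), inc)          # 4x4 integer matrices [a, b]
  # a zero motif probability gives a -Inf increment; clamp it far below the
  # lowest all-finite path so such windows sort beneath every finite score
  fin <- unlist(lapply(incs, function(d) d[is.finite(d)]))
  span <- max(fin) * w - min(fin) * w + 10
  incs <- lapply(incs, function(d) {
    d[!is.finite(d)] <- min(fin) - span
    d
  })
  # dist[b, k]: P(first i window chars, last base b, accumulated bin =
  # lo + k - 1); the state before position 1 is the preceding base drawn
  # from the initial distribution with accumulated bin 0.
  lo <- 0; hi <- 0
  dist <- matrix(bg$initial, 4, 1)
  for (i in seq_len(w)) {
    d <- incs[[i]]
    width_bins <- (hi - lo) + (max(d) - min(d)) + 1L
    ndist <- matrix(0, 4, width_bins)
    for (a in 1:4) {
      row <- dist[a, ]
      if (all(row == 0)) next
      for (b in 1:4) {
        shift <- d[a, b] - min(d)
        tgt <- seq_along(row) + shift
        ndist[b, tgt] <- ndist[b, tgt] + row * bg$transition[a, b]
      }
    }
    dist <- ndist
    hi <- hi + max(d); lo <- lo + min(d)
  }
  total <- colSums(dist)
  tailp <- rev(cumsum(rev(total)))         # P(bin >= lo + k - 1)
  pv <- function(score) {
    t_star <- floor(score / resolution) - w + 1
    k <- t_star - lo + 1
    if (k <= 1) return(1)
    if (k > length(tailp)) return(0)
    unname(tailp[k])
  }
  structure(list(pvalue = function(score) vapply(score, pv, numeric(1)),
                 resolution = resolution, width = w,
                 bin_lo = lo, tail = tailp),
            class = "sixs_pvalue_table")
}

scan_frame <- function(pwm, bg, ptab, frame_chars, strand_label) {
  w <- pwm$width
  L <- length(frame_chars)
  if (L < w) {
    return(data.frame(start = integer(0), strand = character(0),
                      score = numeric(0), pvalue = numeric(0)))
  }
  idx <- match(frame_chars, BASES)
  lp <- log2(pwm$probs)
  lt <- log2(bg$transition)
  starts <- seq_len(L - w + 1L)            # 1-based window starts
  score <- numeric(length(starts))
  for (i in seq_len(w)) {
    score <- score + lp[cbind(idx[starts + i - 1L], i)]
  }
  # background: positions 2..w conditioned within the window
  for (i in 2:w) {
    score <- score - lt[cbind(idx[starts + i - 2L], idx[starts + i - 1L])]
  }
  # first position: conditioned on preceding frame base when available
  prev <- c(NA_integer_, idx[seq_len(L - w)])[seq_along(starts)]
  first_bg <- ifelse(is.na(prev), log2(bg$initial[idx[starts]]),
                     lt[cbind(prev, idx[starts])])
  score <- score - first_bg
  data.frame(start = starts - 1L, strand = strand_label, score = score,
             pvalue = ptab$pvalue(score), stringsAsFactors = FALSE)
}

#' Scan a 6S locus for cre motif matches
#'
#' Scans both strands of the gene plus its upstream region (default 100 nt)
#' in the gene's frame. Hits with p-value at most `p_threshold` are
#' reported with their 0-based offset relative to the gene start (negative
#' = upstream of the gene) and classified as `upstream` or `internal` by
#' the sign of the offset. Overlapping same-strand hits are reduced to the
#' best p-value, and at most `max_hits` hits per locus are returned.
#'
#' @param pwm Motif PWM (gene-strand orientation).
#' @param bg Genome background from [fit_background()].
#' @param genome One-row genome data.frame.
#' @param ssrS One-row feature table locating the 6S gene.
#' @param upstream_nt Upstream context length (default 100).
#' @param p_threshold Report hits with p-value <= this (default 1e-5).
#' @param max_hits Best-N gate per locus (default 5).
#' @param resolution P-value table resolution.
#' @return data.frame: `position` (offset to gene start), `strand`, `score`
#'   (bits), `pvalue`, `region_class`, `genome_start`, `genome_end`.
#' @export
scan_locus <- function(pwm, bg, genome, ssrS, upstream_nt = 100L,
                       p_threshold = 1e-5, max_hits = 5L,
                       resolution = 1e-3) {
  g <- as_genome(genome, "genome")
  n <- nchar(g$seq)
  stopifnot(ssrS$start >= 0L, ssrS$end <= n)
  if (ssrS$strand == "+") {
    reg_start <- max(0L, ssrS$start - upstream_nt)
    frame_seq <- substr(g$seq, reg_start + 1L, ssrS$end)
    up_len <- ssrS$start - reg_start
  } else {
    reg_end <- min(n, ssrS$end + upstream_nt)
    frame_seq <- revcomp(substr(g$seq, ssrS$start + 1L, reg_end))
    up_len <- reg_end - ssrS$end
  }
  frame_chars <- seq_chars(frame_seq)
  rc <- revcomp_pwm(pwm)
  ptab_f <- score_pvalue_table(pwm, bg, resolution)
  ptab_r <- score_pvalue_table(rc, bg, resolution)
  hits <- rbind(scan_frame(pwm, bg, ptab_f, frame_chars, "+"),
                scan_frame(rc, bg, ptab_r, frame_chars, "-"))
  hits <- hits[hits$pvalue <= p_threshold, , drop = FALSE]
  if (nrow(hits)) {
    # reduce overlapping same-strand hits to the best p-value
    keep <- list()
    for (strand in c("+", "-")) {
      grp <- hits[hits$strand == strand, , drop = FALSE]
      if (!nrow(grp)) next
      grp <- grp[order(grp$start), , drop = FALSE]
      cur <- grp[1, , drop = FALSE]; cur_end <- cur$start + pwm$width
      for (i in seq_len(nrow(grp))[-1]) {
        row <- grp[i, , drop = FALSE]
        if (row$start < cur_end) {
          cur_end <- max(cur_end, row$start + pwm$width)
          if (row$pvalue < cur$pvalue) cur <- row
        } else {
          keep[[length(keep) + 1L]] <- cur
          cur <- row; cur_end <- row$start + pwm$width
        }
      }
      keep[[length(keep) + 1L]] <- cur
    }
    hits <- do.call(rbind, keep)
    hits <- hits[order(hits$pvalue), , drop = FALSE]
    if (nrow(hits) > max_hits) hits <- hits[seq_len(max_hits), , drop = FALSE]
  }
  offset <- hits$start - up_len
  out <- data.frame(position = offset, strand = hits$strand,
                    score = hits$score, pvalue = hits$pvalue,
                    region_class = ifelse(offset < 0, "upstream", "internal"),
                    stringsAsFactors = FALSE)
  if (nrow(out)) {
    if (ssrS$strand == "+") {
      out$genome_start <- ssrS$start + out$position
    } else {
      out$genome_start <- ssrS$end - out$position - pwm$width
    }
    out$genome_end <- out$genome_start + pwm$width
  } else {
    out$genome_start <- integer(0)
    out$genome_end <- integer(0)
  }
  rownames(out) <- NULL
  out
}
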