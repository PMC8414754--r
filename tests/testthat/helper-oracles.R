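# Independent oracles used by the unit and acceptance tests. These are
# deliberately written as direct (often brute-force) computations that share
# no code with the package implementation.

ORACLE_BASES <- c("A", "C", "G", "T")

rand_seq <- function(n, prob = NULL) {
  paste(sample(ORACLE_BASES, n, replace = TRUE, prob = prob), collapse = "")
}

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# Quadratic brute-force maximal ungapped segment scanner: for every exact
# seed match, enumerate all (a, b) extensions on its diagonal and keep the
# maximal-scoring segment (ties: shortest extension on each side).
oracle_search <- function(qseq, tseq, match, mismatch, seed_len, K, lambda) {
  res <- list()
  m0 <- nchar(qseq); n0 <- nchar(tseq)
  for (strand in c("+", "-")) {
    qs <- if (strand == "+") qseq else oracle_revcomp(qseq)
    qc <- strsplit(qs, "")[[1]]; tc <- strsplit(tseq, "")[[1]]
    m <- length(qc); n <- length(tc)
    for (qi in seq_len(max(0, m - seed_len + 1))) {
      for (tj in seq_len(max(0, n - seed_len + 1))) {
        if (substr(qs, qi, qi + seed_len - 1) !=
            substr(tseq, tj, tj + seed_len - 1)) next
        d <- tj - qi
        lo <- max(1, 1 - d); hi <- min(m, n - d)
        sc <- ifelse(qc[lo:hi] == tc[(lo:hi) + d], match, mismatch)
        a0 <- qi - lo + 1; b0 <- a0 + seed_len - 1
        best <- NULL
        for (a in seq(a0, 1)) {             # decreasing: shortest-left wins ties
          for (b in seq(b0, length(sc))) {  # increasing: shortest-right wins
            s <- sum(sc[a:b])
            if (is.null(best) || s > best$s) best <- list(a = a, b = b, s = s)
          }
        }
        qa <- best$a + lo - 1
        qb <- best$b + lo - 1
        res[[length(res) + 1]] <- data.frame(
          start = qa + d - 1, end = qb + d, strand = strand,
          raw_score = best$s, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), raw_score = numeric(0)))
  }
  out <- unique(do.call(rbind, res))
  out$evalue <- K * m0 * n0 * exp(-lambda * out$raw_score)
  out[order(out$start, out$end, out$strand), c("start", "end", "strand",
                                               "raw_score", "evalue")]
}

# Full DP Levenshtein oracle.
oracle_edit_distance <- function(a, b) {
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  na <- length(ac); nb <- length(bc)
  D <- matrix(0, na + 1, nb + 1)
  D[, 1] <- 0:na; D[1, ] <- 0:nb
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      D[i + 1, j + 1] <- min(D[i, j] + (ac[i] != bc[j]),
                             D[i, j + 1] + 1, D[i + 1, j] + 1)
    }
  }
  D[na + 1, nb + 1]
}

# Exponential-time recursive global-alignment score oracle (tiny strings).
oracle_nw_score <- function(a, b, match, mismatch, gap) {
  if (nchar(a) == 0) return(gap * nchar(b))
  if (nchar(b) == 0) return(gap * nchar(a))
  ha <- substr(a, 1, 1); hb <- substr(b, 1, 1)
  ta <- substr(a, 2, nchar(a)); tb <- substr(b, 2, nchar(b))
  max(oracle_nw_score(ta, tb, match, mismatch, gap) +
        (if (ha == hb) match else mismatch),
      oracle_nw_score(ta, b, match, mismatch, gap) + gap,
      oracle_nw_score(a, tb, match, mismatch, gap) + gap)
}

# Transitive-closure single-linkage clustering oracle on a distance matrix.
oracle_components <- function(D, cutoff) {
  n <- nrow(D)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, j] <= cutoff && comp[j] != comp[i]) {
          old <- comp[j]
          comp[comp == old] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# Cubic brute-force hairpin enumerator mirroring the documented candidate
# definition: for every loop placement the maximal outward stem extension.
oracle_hairpins <- function(seq, min_stem = 4, max_stem = 25) {
  pair_score <- function(x, y) {
    if ((x == "G" && y == "C") || (x == "C" && y == "G")) return(3)
    if ((x == "A" && y == "T") || (x == "T" && y == "A")) return(2)
    if ((x == "G" && y == "T") || (x == "T" && y == "G")) return(1)
    0
  }
  chars <- strsplit(seq, "")[[1]]; n <- length(chars)
  out <- list()
  for (l in 3:10) {
    for (j in seq_len(n)) {                 # 1-based loop start
      k <- 0; score <- 0
      while (k < max_stem) {
        left <- j - k - 1; right <- j + l + k
        if (left < 1 || right > n) break
        ps <- pair_score(chars[left], chars[right])
        if (ps == 0) break
        k <- k + 1; score <- score + ps
      }
      if (k >= min_stem) {
        hp_end <- j + l + k - 1             # 0-based exclusive
        u <- 0
        for (p in (hp_end + 1):(hp_end + 8)) {
          if (p <= n && chars[p] == "T") u <- u + 1
        }
        out[[length(out) + 1]] <- data.frame(
          hairpin_start = j - k - 1, hairpin_end = hp_end,
          stem_len = k, loop_len = l,
          score = score - 0.5 * (l - 3) + u)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(hairpin_start = integer(0), hairpin_end = integer(0),
                      stem_len = integer(0), loop_len = integer(0),
                      score = numeric(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$hairpin_start, res$hairpin_end), ]
}

# Exhaustive PWM score distribution under a first-order chain: enumerates
# every (preceding base, window) pair with its probability and exact score.
oracle_pwm_distribution <- function(probs, initial, transition) {
  w <- ncol(probs)
  grid <- expand.grid(rep(list(1:4), w + 1))  # col 1 = preceding base
  prob <- initial[grid[, 1]]
  score <- 0
  for (i in seq_len(w)) {
    tr <- transition[cbind(grid[, i], grid[, i + 1])]
    prob <- prob * tr
    score <- score + log2(probs[cbind(grid[, i + 1], i)]) - log2(tr)
  }
  data.frame(score = score, prob = prob)
}

oracle_pwm_pvalue <- function(dist, s) sum(dist$prob[dist$score >= s])

# Closed-form three-taxon neighbor-joining branch lengths.
oracle_three_taxon <- function(dAB, dAC, dBC) {
  c(a = (dAB + dAC - dBC) / 2,
    b = (dAB + dBC - dAC) / 2,
    c = (dAC + dBC - dAB) / 2)
}

# Random additive distance matrix from a random tree, with its tree.
oracle_additive_matrix <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE, br = function(k) runif(k, 0.1, 1))
  list(tree = tr, D = cophenetic(tr))
}

count_dinucs <- function(s) {
  ch <- strsplit(s, "")[[1]]
  if (length(ch) < 2) return(table(character(0)))
  table(factor(paste0(head(ch, -1), tail(ch, -1)),
               levels = as.vector(outer(ORACLE_BASES, ORACLE_BASES, paste0))))
}
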