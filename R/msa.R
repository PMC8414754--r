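SUBM4 <- function(match, mismatch) {
  m <- matrix(mismatch, 4, 4, dimnames = list(BASES, BASES))
  diag(m) <- match
  m
}

# Global alignment over a precomputed column-pair score matrix S (LA x LB)
# with linear gap penalty; vectorized anti-diagonal fill. Traceback prefers
# diagonal, then up (consume a), then left (consume b). Returns the aligned
# index path (NA marks a gap) and the optimal score.
nw_core <- function(S, gap) {
  LA <- nrow(S); LB <- ncol(S)
  M <- matrix(0, LA + 1L, LB + 1L)
  M[, 1] <- gap * (0:LA)
  M[1, ] <- gap * (0:LB)
  if (LA > 0L && LB > 0L) {
    for (d in 2:(LA + LB)) {
      ii <- max(1L, d - LB):min(LA, d - 1L)
      if (ii[1] > ii[length(ii)]) next
      jj <- d - ii
      M[cbind(ii + 1L, jj + 1L)] <- pmax(
        M[cbind(ii, jj)] + S[cbind(ii, jj)],
        M[cbind(ii, jj + 1L)] + gap,
        M[cbind(ii + 1L, jj)] + gap)
    }
  }
  ai <- integer(0); bi <- integer(0)
  i <- LA; j <- LB
  tol <- 1e-9
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        abs(M[i + 1L, j + 1L] - (M[i, j] + S[i, j])) < tol) {
      ai <- c(i, ai); bi <- c(j, bi); i <- i - 1L; j <- j - 1L
    } else if (i > 0L &&
               abs(M[i + 1L, j + 1L] - (M[i, j + 1L] + gap)) < tol) {
      ai <- c(i, ai); bi <- c(NA_integer_, bi); i <- i - 1L
    } else {
      ai <- c(NA_integer_, ai); bi <- c(j, bi); j <- j - 1L
    }
  }
  list(ai = ai, bi = bi, score = M[LA + 1L, LB + 1L])
}

#' Optimal pairwise global alignment
#'
#' Needleman-Wunsch alignment with linear gap penalty and deterministic
#' tie-breaking (prefer diagonal, then gap in the second sequence, then gap
#' in the first).
#'
#' @param a,b Sequences (character scalars).
#' @param match,mismatch,gap Scoring parameters.
#' @return List with gapped `a`, gapped `b` and the optimal `score`.
#' @export
pairwise_global_align <- function(a, b, match = 2, mismatch = -1, gap = -2) {
  ac <- seq_chars(a); bc <- seq_chars(b)
  S <- matrix(0, length(ac), length(bc))
  if (length(ac) && length(bc)) {
    S <- ifelse(outer(ac, bc, "=="), match, mismatch)
  }
  path <- nw_core(S, gap)
  ga <- ifelse(is.na(path$ai), "-", ac[path$ai])
  gb <- ifelse(is.na(path$bi), "-", bc[path$bi])
  list(a = chars_seq(ga), b = chars_seq(gb), score = path$score)
}

new_msa <- function(row_ids, rows) {
  stopifnot(length(row_ids) == length(rows),
            length(unique(nchar(rows))) <= 1L)
  structure(list(row_ids = row_ids, rows = rows), class = "sixs_msa")
}

#' @export
print.sixs_msa <- function(x, ...) {
  cat(sprintf("Multiple alignment: %d rows x %d columns\n",
              length(x$rows), if (length(x$rows)) nchar(x$rows[1]) else 0L))
  invisible(x)
}

msa_row <- function(aln, row_id) {
  i <- match(row_id, aln$row_ids)
  if (is.na(i)) stop(sprintf("row '%s' not in alignment", row_id), call. = FALSE)
  aln$rows[i]
}

as_seq_table <- function(seqs) {
  if (is.data.frame(seqs)) {
    return(data.frame(id = seqs$id, seq = seqs$seq, stringsAsFactors = FALSE))
  }
  if (is.character(seqs)) {
    ids <- names(seqs) %||% paste0("seq", seq_along(seqs))
    return(data.frame(id = ids, seq = unname(seqs), stringsAsFactors = FALSE))
  }
  stop("sequences must be a data.frame(id, seq) or named character vector",
       call. = FALSE)
}

profile_of <- function(rows) {
  L <- nchar(rows[1])
  mat <- matrix(0, 4, L, dimnames = list(BASES, NULL))
  for (r in rows) {
    chars <- seq_chars(r)
    for (bidx in seq_along(BASES)) {
      mat[bidx, ] <- mat[bidx, ] + (chars == BASES[bidx])
    }
  }
  mat / length(rows)                      # gap mass simply drops out
}

merge_alignments <- function(alnA, alnB, match, mismatch, gap) {
  pA <- profile_of(alnA$rows)
  pB <- profile_of(alnB$rows)
  S <- t(pA) %*% SUBM4(match, mismatch) %*% pB
  path <- nw_core(S, gap)
  ca <- lapply(alnA$rows, seq_chars)
  cb <- lapply(alnB$rows, seq_chars)
  rowsA <- vapply(ca, function(ch) {
    chars_seq(ifelse(is.na(path$ai), "-", ch[path$ai]))
  }, character(1))
  rowsB <- vapply(cb, function(ch) {
    chars_seq(ifelse(is.na(path$bi), "-", ch[path$bi]))
  }, character(1))
  new_msa(c(alnA$row_ids, alnB$row_ids), c(rowsA, rowsB))
}

#' Progressive multiple alignment
#'
#' Builds a guide tree by neighbor-joining on pairwise distances
#' (1 - identity of optimal pairwise alignments) and merges profiles
#' leaf-to-root, aligning profile columns by average substitution score
#' ("once a gap, always a gap"). Rows are returned in input order.
#'
#' @param seqs data.frame(id, seq) or named character vector (>= 1
#'   sequences; a single sequence yields a trivial one-row alignment).
#' @param match,mismatch,gap Scoring parameters (linear gap penalty).
#' @return A `sixs_msa` object (fields `row_ids`, `rows`).
#' @export
progressive_align <- function(seqs, match = 2, mismatch = -1, gap = -2) {
  tab <- as_seq_table(seqs)
  stopifnot(!anyDuplicated(tab$id))
  n <- nrow(tab)
  if (n == 0L) stop("no sequences to align", call. = FALSE)
  if (n == 1L) return(new_msa(tab$id, tab$seq))
  if (n == 2L) {
    pw <- pairwise_global_align(tab$seq[1], tab$seq[2], match, mismatch, gap)
    return(new_msa(tab$id, c(pw$a, pw$b)))
  }
  D <- matrix(0, n, n, dimnames = list(tab$id, tab$id))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      pw <- pairwise_global_align(tab$seq[i], tab$seq[j], match, mismatch, gap)
      ga <- seq_chars(pw$a); gb <- seq_chars(pw$b)
      ident <- sum(ga == gb & ga != "-") / length(ga)
      D[i, j] <- D[j, i] <- 1 - ident
    }
  }
  tr <- ape::nj(stats::as.dist(D))
  children <- split(tr$edge[, 2], tr$edge[, 1])
  align_node <- function(node) {
    if (node <= n) {                      # leaf
      return(new_msa(tab$id[node], tab$seq[node]))
    }
    kids <- children[[as.character(node)]]
    acc <- align_node(kids[1])
    for (k in kids[-1]) {
      acc <- merge_alignments(acc, align_node(k), match, mismatch, gap)
    }
    acc
  }
  aln <- align_node(n + 1L)               # ape root of the unrooted tree
  ord <- match(tab$id, aln$row_ids)
  new_msa(aln$row_ids[ord], aln$rows[ord])
}

#' Map between ungapped positions and alignment columns
#'
#' `map_to_column` converts a 0-based ungapped residue position of a row to
#' its 0-based alignment column. `map_to_position` is the inverse; for a gap
#' column it returns the nearest residue to the left and flags the result as
#' inexact.
#'
#' @param aln A `sixs_msa`.
#' @param row_id Row identifier.
#' @param pos 0-based ungapped position.
#' @return `map_to_column`: integer column. `map_to_position`: list with
#'   `position` (0-based) and `exact` (logical).
#' @export
map_to_column <- function(aln, row_id, pos) {
  chars <- seq_chars(msa_row(aln, row_id))
  cols <- which(chars != "-")
  if (pos < 0L || pos >= length(cols)) {
    stop("ungapped position out of range", call. = FALSE)
  }
  cols[pos + 1L] - 1L
}

#' @rdname map_to_column
#' @param col 0-based alignment column.
#' @export
map_to_position <- function(aln, row_id, col) {
  chars <- seq_chars(msa_row(aln, row_id))
  if (col < 0L || col >= length(chars)) {
    stop("column out of range", call. = FALSE)
  }
  counts <- cumsum(chars != "-")
  if (counts[col + 1L] == 0L) {
    stop("column precedes the first residue of the row", call. = FALSE)
  }
  list(position = counts[col + 1L] - 1L, exact = chars[col + 1L] != "-")
}

#' Read / write alignments as aligned FASTA (and Stockholm)
#'
#' @param aln A `sixs_msa`.
#' @param path File path.
#' @export
write_alignment <- function(aln, path) {
  write_fasta(data.frame(id = aln$row_ids, seq = aln$rows,
                         stringsAsFactors = FALSE), path)
}

#' @rdname write_alignment
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  new_msa(ids, unname(toupper(as.character(set))))
}

#' @rdname write_alignment
#' @export
write_stockholm <- function(aln, path) {
  ids <- format(aln$row_ids)
  writeLines(c("# STOCKHOLM 1.0",
               paste(ids, aln$rows), "//"), path)
  invisible(path)
}
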