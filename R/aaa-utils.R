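#' @keywords internal
"_PACKAGE"

BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Reverse complement of a DNA string
#'
#' @param seq Character scalar over the alphabet A/C/G/T.
#' @return The reverse complement as a character scalar.
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) return("")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  paste(rev(unname(COMPLEMENT[chars])), collapse = "")
}

seq_chars <- function(seq) {
  if (nchar(seq) == 0L) character(0) else strsplit(seq, "", fixed = TRUE)[[1]]
}

chars_seq <- function(chars) paste(chars, collapse = "")

#' Normalize a nucleotide sequence
#'
#' Uppercases and converts U to T so RNA and DNA inputs are interchangeable.
#' Characters outside A/C/G/T are rejected in strict mode; in lenient mode
#' each is replaced by a uniformly random concrete base (seeded).
#'
#' @param seq Character scalar.
#' @param strict Reject non-ACGT characters (default) instead of masking them.
#' @param seed Integer seed used only for lenient-mode replacement.
#' @param context Label used in error messages (e.g. a record id).
#' @return Normalized character scalar.
#' @export
normalize_seq <- function(seq, strict = TRUE, seed = 1L, context = "sequence") {
  s <- chartr("u", "t", toupper(seq))
  s <- chartr("U", "T", s)
  chars <- seq_chars(s)
  bad <- !(chars %in% BASES)
  if (any(bad)) {
    if (strict) {
      stop(sprintf("non-ACGT character '%s' in %s (strict mode)",
                   chars[which(bad)[1]], context), call. = FALSE)
    }
    chars[bad] <- with_seed(seed, sample(BASES, sum(bad), replace = TRUE))
    s <- chars_seq(chars)
  }
  s
}

# Evaluate expr with a local RNG state seeded from `seed`; restores the
# caller's RNG so library code never disturbs user-level randomness.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a stream-specific child seed from a master seed; stays below 2^31.
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 7919 + as.numeric(stream) * 104729) %% 2147483647
}

log_msg <- function(level, ...) {
  message(sprintf("[%s] %s", level, paste0(...)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
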