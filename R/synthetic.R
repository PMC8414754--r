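# Packaged fixture sequences. The seed 6S RNA gene is a synthetic 188-nt
# sequence with the canonical 6S architecture: a 12-nt leader, 26-nt closing
# stem arms flanking a weakly paired A/T-rich central bubble, and a short
# tail. The anchor "genes" are synthetic 360-nt marker sequences with low
# similarity to random background; the rescue stage only needs locatable
# anchors, not real protein genes.
SEED_6S <- paste0(
  "TAGCAACAAGTCAACATGTCTTGTACGAACGGACAACGTCTGGGTTAGAACTTTACTCCTCTAATGAGTA",
  "ATTCGTGAAGTAAAATAGATTATATTGTAAAATAACCGATGTTAATCCGGTATGGTTTATTGTTTTGTCC",
  "AGCTTCCTCGTTGTCCGTTCGTACAAGACATGTTGCCTAGAAAGGTAC")

ANCHOR_RARA <- paste0(
  "CGGTGCGCCTTGTTCGTGCTGTTCGGCTCGATGCCGCTCTGTTAGCTAGAATAACTAGAGCTTATCGTCC",
  "CTGTCGATCGAATTCGTTTCCTACCATCTGAATCTCTTAGATGTGCAAATGTTCACATAGACTCGTTATC",
  "TTACGCAGCAGGGCGTCCTAAATATGCGTGAGCTCTACTACATCGGTAGTCGTCAGCCTCCACGATAGCC",
  "TGTTGACGTCAGGCAACCTTGTGCGTGGTCATAGCTAGGCAATCTAACTCTTGTGAAGATATGTCAACCA",
  "TCTAAAGGGGAAAAGGCAAGAGGGGCGCGGGTCCCAGAGGCAGGCGCACTGATCTCTTGATTGTGCCACT",
  "CGGTGCCTCT")

ANCHOR_USPA <- paste0(
  "TGCTCTTCTGTAAAGTCACCCACCTCTTACTCCTTCGCAGCAAGAAAGGGAGGCCGAGAACGCAAGGCCT",
  "CTGGCGCAAAGCGTACCTATATCCACTGACTTTCACGAATATTTCTTACTATGACAATTTTATCCGCGAG",
  "TCAGAAGCCTCACGCTGGTATCTCAGACACATAAAGCACCATAGGTGGAGAAATGGGTACGGACAAGGAC",
  "GATGTCACCCTATTTGCAAACAGCGCTGTAGACTCCGAATGACCTTTTTCAACTTTGTCCGCAATAATGT",
  "AACCCACCTATTTTGCCCTGGCACATCAAGACGAACCGGTATAAAACAACATAAACGTTGAACCACTATG",
  "CTCTGCTTCA")

# Intrinsic terminator cassette planted downstream of the 6S gene: a
# GC-rich 9-bp stem, 4-nt loop, and an 8-nt U(T)-tract.
TERMINATOR_STEM <- "GCCGGCCTC"
TERMINATOR_LOOP <- "TTCG"
TERMINATOR_SEQ <- paste0(TERMINATOR_STEM, TERMINATOR_LOOP,
                         "GAGGCCGGC",      # reverse complement of the stem
                         "TTTTTTTT")

# 0-based position on SEED_6S paired with the 5' nucleotide of the pRNA
# (inside the central bubble, as in characterized 6S RNAs).
PRNA_REF_START <- 92L

#' Packaged reference sequences for the synthetic cohort
#'
#' @return `seed_6s_sequence()`: the 188-nt synthetic 6S gene;
#'   `anchor_references()`: data.frame(id, seq) with the synthetic rarA and
#'   uspA marker sequences; `prna_reference_start()`: the 0-based template
#'   position of the pRNA 5' end on the seed 6S sequence.
#' @export
seed_6s_sequence <- function() SEED_6S

#' @rdname seed_6s_sequence
#' @export
anchor_references <- function() {
  data.frame(id = c("rarA", "uspA"), seq = c(ANCHOR_RARA, ANCHOR_USPA),
             description = c("synthetic rarA anchor marker",
                             "synthetic uspA anchor marker"),
             stringsAsFactors = FALSE)
}

#' @rdname seed_6s_sequence
#' @export
prna_reference_start <- function() PRNA_REF_START

#' Synthetic cre training sites
#'
#' Loads the packaged synthetic stand-in list of catabolite-responsive
#' element (cre) sites (14-nt, pseudo-palindromic) used to train the default
#' PWM. Experimentally derived site lists can be supplied instead anywhere a
#' site list is accepted.
#'
#' @param path Optional path to a plain-text site list (one site per line,
#'   '#' comments allowed).
#' @return Character vector of equal-length sites.
#' @export
default_cre_sites <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cre_sites_synthetic.txt",
                        package = "sixsanno")
  }
  lines <- trimws(readLines(path))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  toupper(lines)
}

#' Uniform dinucleotide frequency matrix
#'
#' @return 4x4 matrix (rows = first base, columns = second base) with all
#'   entries 1/16.
#' @export
uniform_dinucleotide_freqs <- function() {
  matrix(1 / 16, 4, 4, dimnames = list(BASES, BASES))
}

as_dinuc_matrix <- function(freqs) {
  if (is.matrix(freqs)) {
    stopifnot(all(dim(freqs) == c(4, 4)))
    m <- freqs
    dimnames(m) <- list(BASES, BASES)
  } else {
    stopifnot(length(freqs) == 16L)
    m <- matrix(freqs, 4, 4, byrow = TRUE, dimnames = list(BASES, BASES))
  }
  stopifnot(all(m >= 0), abs(sum(m) - 1) < 1e-9)
  m
}

#' Sample a background genome from a stationary first-order chain
#'
#' @param length Sequence length.
#' @param dinucleotide_freqs 4x4 matrix (or length-16 vector, row-major
#'   AA..TT) of dinucleotide frequencies summing to 1.
#' @param seed Integer seed (sampling is deterministic given the seed).
#' @param id Genome id.
#' @param allow_degenerate Permit bases with zero marginal frequency
#'   (unreachable states); otherwise they are an error.
#' @return One-row genome data.frame (id, seq, description).
#' @export
generate_background <- function(length, dinucleotide_freqs, seed,
                                id = "background", allow_degenerate = FALSE) {
  stopifnot(length >= 1L)
  Fm <- as_dinuc_matrix(dinucleotide_freqs)
  marg <- rowSums(Fm)
  if (any(marg == 0) && !allow_degenerate) {
    stop("degenerate dinucleotide frequencies: base(s) ",
         paste(BASES[marg == 0], collapse = ","),
         " unreachable (set allow_degenerate = TRUE to permit)",
         call. = FALSE)
  }
  trans <- Fm / ifelse(marg > 0, marg, 1)
  cum <- t(apply(trans, 1, cumsum))
  chars <- with_seed(seed, {
    u <- stats::runif(length)
    out <- integer(length)
    out[1] <- sample.int(4L, 1L, prob = marg)
    if (length > 1L) {
      for (i in 2:length) {
        out[i] <- findInterval(u[i], cum[out[i - 1L], ],
                               left.open = TRUE) + 1L
      }
    }
    out
  })
  data.frame(id = id, seq = chars_seq(BASES[chars]),
             description = "synthetic background", stringsAsFactors = FALSE)
}

#' Mutate a sequence with substitutions and short indels
#'
#' Each position is independently substituted (to a uniformly chosen
#' different base) with probability `substitution_rate`; independently, an
#' indel event occurs at each position with probability `indel_rate`, with
#' equal odds of an insertion or a deletion of length drawn uniformly from
#' 1-3.
#'
#' @param seq Input string.
#' @param substitution_rate,indel_rate Per-position event probabilities.
#' @param seed Integer seed.
#' @return Mutated string (deterministic given the seed).
#' @export
mutate_sequence <- function(seq, substitution_rate, indel_rate, seed) {
  stopifnot(substitution_rate >= 0, substitution_rate <= 1,
            indel_rate >= 0, indel_rate <= 1)
  chars <- seq_chars(seq)
  n <- length(chars)
  with_seed(seed, {
    sub_at <- which(stats::runif(n) < substitution_rate)
    for (i in sub_at) {
      chars[i] <- sample(setdiff(BASES, chars[i]), 1L)
    }
    if (indel_rate > 0) {
      ev <- which(stats::runif(n) < indel_rate)
      keep <- rep(TRUE, n)
      inserts <- vector("list", n)
      for (i in ev) {
        len <- sample.int(3L, 1L)
        if (stats::runif(1) < 0.5) {
          inserts[[i]] <- sample(BASES, len, replace = TRUE)
        } else {
          keep[i:min(n, i + len - 1L)] <- FALSE
        }
      }
      pieces <- lapply(seq_len(n), function(i) {
        c(inserts[[i]], if (keep[i]) chars[i])
      })
      chars <- unlist(pieces)
    }
    chars_seq(chars)
  })
}

#' Specification of a planted synthetic locus
#'
#' Defaults describe the emulated study conditions: one 6S gene copy
#' diverged by 10% substitutions from the packaged seed sequence, flanked by
#' a rarA marker upstream and a uspA marker downstream (both within the
#' 2000-nt anchor window), a hairpin/U-tract terminator directly downstream
#' of the gene, a cre site in the 100-nt upstream region, and one decoy copy
#' planted farther than the anchor window from any anchor.
#'
#' @param seed_6s_sequence Seed 6S gene (default packaged sequence).
#' @param substitution_rate,indel_rate Divergence of planted copies.
#' @param n_decoys_outside_window Number of decoy 6S copies planted outside
#'   the anchor window.
#' @param terminator_present,cre_upstream_present,cre_internal_present Flags.
#' @param anchor_layout One of "both", "rarA_upstream", "uspA_downstream",
#'   "none".
#' @param genome_length Background length (must host all elements).
#' @param dinucleotide_freqs Background composition (4x4 or length-16).
#' @param cre_sites Training sites for the planted cre PWM.
#' @param anchor_window_nt Window used to validate decoy placement.
#' @return A `plant_spec` list.
#' @export
plant_spec <- function(seed_6s_sequence = SEED_6S,
                       substitution_rate = 0.1,
                       indel_rate = 0,
                       n_decoys_outside_window = 1L,
                       terminator_present = TRUE,
                       cre_upstream_present = TRUE,
                       cre_internal_present = FALSE,
                       anchor_layout = c("both", "rarA_upstream",
                                         "uspA_downstream", "none"),
                       genome_length = 10000L,
                       dinucleotide_freqs = uniform_dinucleotide_freqs(),
                       cre_sites = default_cre_sites(),
                       anchor_window_nt = 2000L) {
  anchor_layout <- match.arg(anchor_layout)
  stopifnot(substitution_rate >= 0, substitution_rate <= 1,
            indel_rate >= 0, indel_rate <= 1,
            n_decoys_outside_window >= 0L, genome_length >= 1L)
  spec <- list(seed_6s_sequence = seed_6s_sequence,
               substitution_rate = substitution_rate,
               indel_rate = indel_rate,
               n_decoys_outside_window = as.integer(n_decoys_outside_window),
               terminator_present = terminator_present,
               cre_upstream_present = cre_upstream_present,
               cre_internal_present = cre_internal_present,
               anchor_layout = anchor_layout,
               genome_length = as.integer(genome_length),
               dinucleotide_freqs = as_dinuc_matrix(dinucleotide_freqs),
               cre_sites = cre_sites,
               anchor_window_nt = as.integer(anchor_window_nt))
  class(spec) <- "plant_spec"
  spec
}

overwrite_at <- function(seq, sub, start0) {
  # start0 is 0-based; overwrites (not inserts) the subsequence
  stopifnot(start0 >= 0L, start0 + nchar(sub) <= nchar(seq))
  paste0(substr(seq, 1L, start0), sub,
         substr(seq, start0 + nchar(sub) + 1L, nchar(seq)))
}

sample_site_from_pwm <- function(pwm, seed) {
  with_seed(seed, {
    chars_seq(vapply(seq_len(pwm$width), function(i) {
      sample(BASES, 1L, prob = pwm$probs[, i])
    }, character(1)))
  })
}

plant_one_genome <- function(gid, spec, seed) {
  W <- spec$anchor_window_nt
  gene <- mutate_sequence(spec$seed_6s_sequence, spec$substitution_rate,
                          spec$indel_rate, child_seed(seed, 1))
  pwm <- build_pwm(spec$cre_sites)
  gap1 <- with_seed(child_seed(seed, 2), sample(150:400, 1L))
  gap2 <- with_seed(child_seed(seed, 3), sample(150:400, 1L))
  use_rarA <- spec$anchor_layout %in% c("both", "rarA_upstream")
  use_uspA <- spec$anchor_layout %in% c("both", "uspA_downstream")
  parts <- list()
  if (use_rarA) parts$rarA <- ANCHOR_RARA
  parts$gap1 <- strrep(".", gap1)          # placeholder: keep background
  parts$ssrS <- gene
  if (spec$terminator_present) parts$terminator <- TERMINATOR_SEQ
  parts$gap2 <- strrep(".", gap2)
  if (use_uspA) parts$uspA <- ANCHOR_USPA
  cassette_len <- sum(nchar(unlist(parts)))

  n_dec <- spec$n_decoys_outside_window
  dec_space <- if (n_dec > 0L) n_dec * (nchar(gene) + 100L) + 100L else 0L
  need <- 200L + dec_space + W + cassette_len + 100L
  if (spec$genome_length < need) {
    stop(sprintf("genome_length %d too small to host planted elements (need >= %d)",
                 spec$genome_length, need), call. = FALSE)
  }
  bg <- generate_background(spec$genome_length, spec$dinucleotide_freqs,
                            child_seed(seed, 4), id = gid)
  seqs <- bg$seq
  cassette_start <- spec$genome_length - cassette_len - 100L
  feats <- list()
  pos <- cassette_start
  for (nm in names(parts)) {
    w <- nchar(parts[[nm]])
    if (!startsWith(nm, "gap")) {
      seqs <- overwrite_at(seqs, parts[[nm]], pos)
      feats[[length(feats) + 1L]] <-
        features(gid, pos, pos + w, "+", nm, id = paste0(gid, "_", nm))
    }
    pos <- pos + w
  }
  truth <- do.call(rbind, feats)
  ssrS_start <- truth$start[truth$kind == "ssrS"]
  ssrS_end <- truth$end[truth$kind == "ssrS"]

  if (spec$cre_upstream_present) {
    site <- sample_site_from_pwm(pwm, child_seed(seed, 5))
    off <- with_seed(child_seed(seed, 6),
                     sample(seq(-90L, -(pwm$width + 5L)), 1L))
    st <- ssrS_start + off
    seqs <- overwrite_at(seqs, site, st)
    truth <- rbind(truth, features(gid, st, st + pwm$width, "+", "cre_site",
                                   id = paste0(gid, "_cre_up")))
  }
  if (spec$cre_internal_present) {
    site <- sample_site_from_pwm(pwm, child_seed(seed, 7))
    off <- with_seed(child_seed(seed, 8),
                     sample(seq(30L, nchar(gene) - pwm$width - 30L), 1L))
    st <- ssrS_start + off
    seqs <- overwrite_at(seqs, site, st)
    truth <- rbind(truth, features(gid, st, st + pwm$width, "+", "cre_site",
                                   id = paste0(gid, "_cre_int")))
  }
  if (n_dec > 0L) {
    anchor_min <- min(truth$start[truth$kind %in% c("rarA", "uspA", "ssrS")])
    slot_w <- nchar(gene) + 100L
    for (k in seq_len(n_dec)) {
      decoy <- mutate_sequence(spec$seed_6s_sequence, spec$substitution_rate,
                               spec$indel_rate, child_seed(seed, 100 + k))
      lo <- 100L + (k - 1L) * slot_w
      hi <- min(lo + 50L, anchor_min - W - nchar(decoy) - 1L)
      if (hi < lo) stop("cannot place decoy outside anchor window", call. = FALSE)
      st <- with_seed(child_seed(seed, 200 + k), sample(lo:hi, 1L))
      seqs <- overwrite_at(seqs, decoy, st)
      truth <- rbind(truth, features(gid, st, st + nchar(decoy), "+", "decoy",
                                     id = paste0(gid, "_decoy", k)))
    }
  }
  genome <- data.frame(id = gid, seq = seqs,
                       description = "synthetic cohort genome",
                       stringsAsFactors = FALSE)
  list(genome = genome, truth = truth)
}

#' Generate a synthetic genome cohort with planted ground truth
#'
#' For each genome a background sequence is sampled, a mutated 6S gene copy
#' is planted with anchors per the layout inside the anchor window, decoy
#' copies are planted farther than the window from any anchor, a
#' hairpin/U-tract terminator is appended downstream of the gene when
#' flagged, and cre sites sampled from the training PWM are placed upstream
#' and/or inside the gene. The returned truth set records every planted
#' feature; extraction of any truth interval reproduces the planted
#' sequence. Generation is bit-reproducible given (spec, seed).
#'
#' @param n_genomes Number of genomes.
#' @param spec A [plant_spec()].
#' @param seed Integer seed.
#' @return List of per-genome lists with elements `genome` (one-row genome
#'   data.frame) and `truth` (feature table).
#' @export
plant_cohort <- function(n_genomes, spec = plant_spec(), seed = 1L) {
  stopifnot(inherits(spec, "plant_spec"), n_genomes >= 0L)
  lapply(seq_len(n_genomes), function(i) {
    plant_one_genome(sprintf("g%03d", i), spec, child_seed(seed, i * 1000))
  })
}

#' Accessors for cohorts from [plant_cohort()]
#'
#' @param cohort List returned by [plant_cohort()].
#' @return `cohort_genomes`: genome data.frame (one row per genome);
#'   `cohort_truth`: combined feature table.
#' @export
cohort_genomes <- function(cohort) {
  do.call(rbind, lapply(cohort, `[[`, "genome"))
}

#' @rdname cohort_genomes
#' @export
cohort_truth <- function(cohort) {
  do.call(rbind, lapply(cohort, `[[`, "truth"))
}
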