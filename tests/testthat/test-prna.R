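test_that("start projection through the alignment follows the column map", {
  # identical target: projected start equals the reference start
  aln <- progressive_align(c(ref = "ACGTACGTAC", t1 = "ACGTACGTAC"))
  p <- project_starts(aln, c(ref = 4L))
  expect_equal(p$start[p$target_id == "t1"], 4L)
  expect_true(p$exact)
  # gapped reference: counting through the map
  aln2 <- structure(list(row_ids = c("ref", "t1"),
                         rows = c("AC-GT", "ACAGT")), class = "sixs_msa")
  p2 <- project_starts(aln2, c(ref = 2L))   # G at column 3
  expect_equal(p2$start, 3L)
  # modal column rule with ties -> smallest column
  aln3 <- structure(list(row_ids = c("r1", "r2", "r3", "t"),
                         rows = c("AAAAA", "AAAAA", "AAAAA", "AAAAA")),
                    class = "sixs_msa")
  p3 <- project_starts(aln3, c(r1 = 1L, r2 = 1L, r3 = 3L))
  expect_equal(p3$start, 1L)
  expect_error(project_starts(aln3, stats::setNames(integer(0),
                                                    character(0))),
               "reference")
})

test_that("pRNA extraction is the reverse complement of the template window", {
  expect_equal(extract_prna("AAAAAAAAAAAAAAAC", 15, 16), "GTTTTTTTTTTTTTTT")
  expect_equal(extract_prna("ACGT", 0, 1), "T")
  expect_equal(extract_prna("ACGTACGT", 2, 3, "toward_3prime"),
               revcomp("GTA"))
  expect_error(extract_prna("ACGT", 1, 16), "out of bounds")
  # involution: re-embedding the reverse complement restores the window
  s <- rand_seq(40)
  p <- extract_prna(s, 30, 16)
  expect_equal(revcomp(p), substr(s, 16, 31))
})

test_that("motif profile frequencies and information content", {
  m <- build_motif(c("AAAA", "AAAA", "AAAA", "AAAA"))
  expect_equal(unname(m$ic), rep(2, 4))
  u <- build_motif(c("AAAA", "CCCC", "GGGG", "TTTT"))
  expect_equal(unname(u$ic), rep(0, 4))
  mix <- build_motif(c("A", "A", "A", "C"))
  expect_equal(unname(mix$ic), 2 - (-(0.75 * log2(0.75) + 0.25 * log2(0.25))),
               tolerance = 1e-9)
  expect_error(build_motif(c("AA", "AAA")), "equal length")
  # invariance under row permutation
  set.seed(4)
  seqs <- vapply(1:10, function(i) rand_seq(12), character(1))
  expect_equal(build_motif(seqs)$ic, build_motif(rev(seqs))$ic)
})

test_that("motif-guided shift correction restores displaced starts", {
  set.seed(31)
  seed6s <- seed_6s_sequence()
  true_start <- prna_reference_start()
  targets <- stats::setNames(
    vapply(1:30, function(i) mutate_sequence(seed6s, 0.05, 0, seed = i),
           character(1)), paste0("t", 1:30))
  prnas <- vapply(names(targets), function(id) {
    extract_prna(targets[[id]], true_start, 16)
  }, character(1))
  motif <- build_motif(prnas)
  # displace starts by known offsets within +/-3 and ask for correction
  offsets <- sample(-3:3, length(targets), replace = TRUE)
  calls <- data.frame(target_id = names(targets),
                      start = true_start + offsets,
                      stringsAsFactors = FALSE)
  fixed <- adjust_starts(calls, motif, targets, max_shift = 3L)
  frac <- mean(fixed$start == true_start)
  expect_gte(frac, 0.9)
  # already-optimal calls keep shift 0; max_shift 0 is the identity
  opt <- data.frame(target_id = names(targets)[1], start = true_start,
                    stringsAsFactors = FALSE)
  expect_equal(adjust_starts(opt, motif, targets, max_shift = 3L)$shift_applied,
               0L)
  noshift <- adjust_starts(calls, motif, targets, max_shift = 0L)
  expect_equal(noshift$start, calls$start)
})

test_that("three-taxon NJ matches the closed-form branch lengths", {
  # pairwise differences 2, 4, 4 over 15 positions
  t1 <- "AAAAAAAAAAAAAAA"
  t2 <- "CCAAAAAAAAAAAAA"
  t3 <- "AAAGGGGAAAAAAAA"
  m <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]) / 15
  expect_equal(c(m(t1, t2), m(t1, t3), m(t2, t3)) * 15, c(2, 4, 6))
  nwk <- nj_tree(c(A = t1, B = t2, C = t3))
  tr <- ape::read.tree(text = nwk)
  want <- oracle_three_taxon(m(t1, t2), m(t1, t3), m(t2, t3))
  got <- stats::setNames(tr$edge.length[match(1:3, tr$edge[, 2])],
                         tr$tip.label)
  expect_equal(unname(got[c("A", "B", "C")]), unname(want), tolerance = 1e-9)
})

test_that("NJ recovers random additive trees exactly", {
  for (seed in 1:8) {
    n <- sample(4:8, 1)
    gen <- oracle_additive_matrix(n, seed = 100 + seed)
    nwk <- ape::write.tree(ape::nj(as.dist(gen$D)))
    tr <- ape::read.tree(text = nwk)
    # path-length identity: cophenetic distances reproduce the input matrix
    got <- cophenetic(tr)[rownames(gen$D), colnames(gen$D)]
    expect_equal(got, gen$D, tolerance = 1e-8)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr),
                                           ape::unroot(gen$tree))), 0)
  }
})

test_that("identical sequences give a zero-length star and few taxa error", {
  nwk <- nj_tree(c(a = strrep("A", 15), b = strrep("A", 15),
                   c = strrep("A", 15)))
  tr <- ape::read.tree(text = nwk)
  expect_true(all(abs(tr$edge.length) < 1e-12))
  expect_error(nj_tree(c(a = strrep("A", 15), b = strrep("A", 15))),
               "at least 3")
})

test_that("end-to-end projection recovers planted starts on a mutated cohort", {
  set.seed(91)
  seed6s <- seed_6s_sequence()
  true_start <- prna_reference_start()
  targets <- data.frame(
    id = paste0("t", 1:25),
    seq = vapply(1:25, function(i) mutate_sequence(seed6s, 0.1, 0,
                                                   seed = 700 + i),
                 character(1)),
    stringsAsFactors = FALSE)
  refs <- data.frame(id = "ref6S", seq = seed6s, ref_start = true_start,
                     stringsAsFactors = FALSE)
  res <- prna_pipeline(targets, refs)
  frac <- mean(res$calls$start == true_start)
  expect_gte(frac, 0.95)
  expect_equal(unique(nchar(res$calls$seq)), 16L)
  expect_equal(res$motif$width, 16L)
  expect_true(grepl("consensus", res$newick))
})
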