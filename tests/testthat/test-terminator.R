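test_that("dinucleotide shuffle preserves composition exactly", {
  expect_equal(dinucleotide_shuffle("AAAA", seed = 1), "AAAA")
  # "ACGT" admits exactly one arrangement of its edges starting at A
  expect_equal(dinucleotide_shuffle("ACGT", seed = 99), "ACGT")
  expect_error(dinucleotide_shuffle("A", seed = 1), "length >= 2")
  set.seed(6)
  for (i in 1:40) {
    s <- rand_seq(sample(2:400, 1), prob = runif(4) + 0.1)
    x <- dinucleotide_shuffle(s, seed = i)
    expect_identical(count_dinucs(x), count_dinucs(s))
    expect_equal(substr(x, 1, 1), substr(s, 1, 1))
    expect_equal(substr(x, nchar(x), nchar(x)), substr(s, nchar(s), nchar(s)))
    expect_identical(dinucleotide_shuffle(s, seed = i), x)
  }
})

test_that("shuffling actually randomizes higher-order structure", {
  s <- strrep("ACGGT", 200)
  shuffles <- vapply(1:5, function(i) dinucleotide_shuffle(s, seed = i),
                     character(1))
  expect_gt(length(unique(shuffles)), 1L)
  expect_false(any(shuffles == s))
})

test_that("hairpin scorer evaluates the documented formula", {
  cands <- score_terminators("GGGGGAAAACCCCCTTTTTTTT")
  best <- cands[cands$strand == "+" & cands$stem_len == 5 &
                  cands$loop_len == 4, ]
  expect_equal(nrow(best), 1L)
  expect_equal(best$score, 15 - 0.5 + 8)   # stem 15, loop penalty, U-tract
  expect_equal(c(best$hairpin_start, best$hairpin_end), c(0L, 14L))
  # homopolymers form no inverted repeat
  expect_equal(nrow(score_terminators(strrep("A", 80))), 0L)
})

test_that("candidate enumeration equals the brute-force hairpin oracle", {
  set.seed(14)
  for (i in 1:6) {
    s <- rand_seq(300, prob = c(0.2, 0.3, 0.3, 0.2))
    got <- score_terminators(s)
    got <- got[got$strand == "+", c("hairpin_start", "hairpin_end",
                                    "stem_len", "loop_len", "score")]
    got <- got[order(got$hairpin_start, got$hairpin_end, got$loop_len), ]
    want <- oracle_hairpins(s)
    want <- want[order(want$hairpin_start, want$hairpin_end, want$loop_len), ]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("adaptive threshold implements the 5% shuffled-genome rule", {
  # worked example: 100 original hits at >= 90; mean shuffled count 5 is the
  # largest average still permitting threshold 90
  orig <- rep(90, 100)
  five <- lapply(1:10, function(i) rep(90, 5))
  res <- adaptive_threshold(orig, five, fraction = 0.05)
  expect_equal(res$threshold, 90)
  expect_equal(res$n_original_above, 100L)
  expect_equal(res$mean_shuffled_above, 5)
  expect_equal(length(res$accepted), 100L)
  six <- lapply(1:10, function(i) rep(90, 6))
  res2 <- adaptive_threshold(orig, six, fraction = 0.05)
  expect_equal(res2$threshold, Inf)
  expect_equal(length(res2$accepted), 0L)
})

test_that("adaptive threshold picks the smallest qualifying candidate score", {
  # empty shuffles accept everything at the minimum score
  orig <- c(5, 9, 3, 7)
  res <- adaptive_threshold(orig, lapply(1:10, function(i) numeric(0)))
  expect_equal(res$threshold, 3)
  expect_equal(sort(res$accepted), 1:4)
  # two candidate thresholds, only the higher qualifies
  orig2 <- c(rep(10, 20), rep(5, 80))
  shuf <- lapply(1:10, function(i) c(rep(10, ifelse(i <= 5, 1, 0)),
                                     rep(5, 20)))
  # mean count >= 10 is 0.5 <= 0.05*20; at >= 5 it is 20.5 > 0.05*100
  res2 <- adaptive_threshold(orig2, shuf)
  expect_equal(res2$threshold, 10)
  expect_equal(length(res2$accepted), 20L)
  expect_error(adaptive_threshold(orig, list(numeric(0)), fraction = 0),
               "fraction")
  expect_error(adaptive_threshold(orig, list(numeric(0)), fraction = 1.5),
               "fraction")
})

test_that("increasing the fraction never raises the chosen threshold", {
  set.seed(77)
  for (rep in 1:10) {
    orig <- round(runif(40, 0, 30), 1)
    shuf <- lapply(1:10, function(i) round(runif(sample(10:40, 1), 0, 30), 1))
    ths <- vapply(c(0.02, 0.05, 0.1, 0.3, 1), function(f) {
      adaptive_threshold(orig, shuf, fraction = f)$threshold
    }, numeric(1))
    d <- diff(ths)
    expect_true(all(d <= 0 | is.nan(d)))  # NaN: successive +Inf thresholds
  }
})

test_that("overlapping terminator candidates merge to the best representative", {
  mk <- function(start, end, strand, score) {
    data.frame(genome_id = "g", hairpin_start = start, hairpin_end = end,
               strand = strand, stem_len = 5L, loop_len = 4L, score = score,
               stringsAsFactors = FALSE)
  }
  nested <- rbind(mk(10L, 40L, "+", 20), mk(15L, 35L, "+", 25))
  m <- merge_overlapping_terminators(nested)
  expect_equal(nrow(m), 1L)
  expect_equal(m$score, 25)
  expect_equal(m$hairpin_start, 15L)
  disjoint <- rbind(mk(10L, 30L, "+", 20), mk(50L, 70L, "+", 25))
  expect_equal(nrow(merge_overlapping_terminators(disjoint)), 2L)
  chain <- rbind(mk(0L, 20L, "+", 5), mk(15L, 35L, "+", 9),
                 mk(30L, 50L, "+", 7))
  m2 <- merge_overlapping_terminators(chain)
  expect_equal(nrow(m2), 1L)
  expect_equal(m2$score, 9)
  # strands never merge
  strands <- rbind(mk(10L, 40L, "+", 20), mk(15L, 35L, "-", 25))
  expect_equal(nrow(merge_overlapping_terminators(strands)), 2L)
})

test_that("a strong planted terminator with quiet shuffles is accepted", {
  # construct a genome whose only high-scoring hairpin is the planted one
  set.seed(19)
  bg <- generate_background(1500, uniform_dinucleotide_freqs(), seed = 55)
  co <- plant_cohort(1, plant_spec(genome_length = 8000,
                                   n_decoys_outside_window = 0L), seed = 55)
  g <- co[[1]]$genome
  tr <- co[[1]]$truth
  res <- suppressMessages(call_terminators(g, seed = 3))
  term <- tr[tr$kind == "terminator", ]
  if (is.finite(res$threshold)) {
    # if anything is accepted, the planted terminator must be among it
    hit <- any(res$accepted$hairpin_start < term$end &
                 res$accepted$hairpin_end > term$start)
    expect_true(hit)
  }
  # the planted hairpin is always among the raw candidates with its score
  planted <- res$candidates[res$candidates$hairpin_start >= term$start &
                              res$candidates$hairpin_end <= term$end, ]
  expect_gte(max(planted$score), 26 - 0.5 + 8 - 8)  # stem score bound
})
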