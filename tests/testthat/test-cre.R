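uniform_bg <- structure(list(
  initial = stats::setNames(rep(0.25, 4), c("A", "C", "G", "T")),
  transition = matrix(0.25, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                                  c("A", "C", "G", "T")))),
  class = "sixs_markov_bg")

test_that("PWM construction counts, pseudocounts and validation", {
  p0 <- build_pwm(c("AA", "AA"), pseudocount = 0)
  expect_equal(p0$probs["A", ], c(1, 1))
  p1 <- build_pwm(c("A", "C"), pseudocount = 0)
  expect_equal(unname(p1$probs[c("A", "C"), 1]), c(0.5, 0.5))
  p2 <- build_pwm(c("A", "A"), pseudocount = 0.5)
  expect_equal(unname(p2$probs["A", 1]), 2.5 / 4)
  expect_equal(colSums(p2$probs), 1)
  expect_error(build_pwm(c("AA", "AAA")), "equal length")
  rc <- revcomp_pwm(build_pwm(c("AACG", "AACG", "AACT")))
  expect_equal(unname(rc$probs["T", 4]), unname(build_pwm(
    c("AACG", "AACG", "AACT"))$probs["A", 1]))
})

test_that("background fitting yields stochastic rows and degenerate limits", {
  bgA <- fit_background(strrep("A", 50), smoothing = 1e-9)
  expect_equal(unname(bgA$transition["A", "A"]), 1, tolerance = 1e-6)
  set.seed(3)
  bg <- fit_background(rand_seq(20000))
  expect_equal(unname(rowSums(bg$transition)), rep(1, 4))
  expect_true(all(abs(bg$transition - 0.25) < 0.02))
  expect_true(all(bg$transition > 0))
})

test_that("log-odds scoring matches hand expansion", {
  pwm <- build_pwm(c("AG", "AG"), pseudocount = 0)
  # column 1 is all A: +2 bits against a uniform background
  w1 <- build_pwm(c("A", "A", "A"), pseudocount = 0)
  expect_equal(logodds_score(w1, "A", uniform_bg), 2)
  # pwm equal to background everywhere scores 0
  flat <- build_pwm(c("A", "C", "G", "T"), pseudocount = 0)
  for (b in c("A", "C", "G", "T")) {
    expect_equal(logodds_score(flat, b, uniform_bg), 0)
  }
  # width-2 hand expansion with a non-uniform background
  bg <- fit_background(paste(rep("ACGGT", 100), collapse = ""))
  got <- logodds_score(pwm, "AG", bg, preceding_base = "T")
  want <- log2(pwm$probs["A", 1] / bg$transition["T", "A"]) +
    log2(pwm$probs["G", 2] / bg$transition["A", "G"])
  expect_equal(got, unname(want))
  expect_error(logodds_score(pwm, "AGG", bg), "width")
})

test_that("p-value table matches exhaustive enumeration and is conservative", {
  set.seed(8)
  for (w in 4:8) {
    sites <- vapply(1:12, function(i) rand_seq(w), character(1))
    pwm <- build_pwm(sites, pseudocount = 0.5)
    bg <- fit_background(rand_seq(5000, prob = runif(4) + 0.2))
    tab <- score_pvalue_table(pwm, bg, resolution = 1e-3)
    dist <- oracle_pwm_distribution(pwm$probs, bg$initial, bg$transition)
    probe <- quantile(dist$score, c(0.5, 0.9, 0.99, 1))
    for (s in probe) {
      exact <- oracle_pwm_pvalue(dist, s)
      got <- tab$pvalue(s)
      expect_gte(got + 1e-12, exact)                    # conservative
      # within the discretization bound: no more than the extra mass in
      # the (width+1)*resolution band below s
      upper <- oracle_pwm_pvalue(dist, s - (w + 1) * 1e-3 - 1e-9)
      expect_lte(got, upper + 1e-12)
    }
    # monotone non-increasing in score, and total mass at -Inf
    ss <- seq(min(dist$score), max(dist$score), length.out = 25)
    pv <- tab$pvalue(ss)
    expect_true(all(diff(pv) <= 1e-12))
    expect_equal(tab$pvalue(-Inf), 1)
    expect_equal(tab$pvalue(max(dist$score) + 10), 0)
  }
})

test_that("width-1 concentrated PWM has p-value 1/4 at its maximum", {
  w1 <- build_pwm(c("A", "A", "A"), pseudocount = 0)
  tab <- score_pvalue_table(w1, uniform_bg)
  expect_equal(tab$pvalue(2), 0.25)       # only A scores log2(1/0.25)
})

test_that("locus scanning finds planted sites with correct region class", {
  sites <- default_cre_sites()
  pwm <- build_pwm(sites)
  consensus <- "TGAAAGCGCTTTCA"
  set.seed(12)
  g <- generate_background(2000, uniform_dinucleotide_freqs(), seed = 61,
                           id = "g1")
  gene_start <- 900L; gene_end <- 1088L
  s <- g$seq
  plant_at <- function(s, site, pos0) {
    paste0(substr(s, 1, pos0), site, substr(s, pos0 + nchar(site) + 1,
                                            nchar(s)))
  }
  s <- plant_at(s, consensus, gene_start - 60L)         # upstream at -60
  s <- plant_at(s, consensus, gene_start + 40L)         # internal at +40
  g$seq <- s
  bg <- fit_background(g)
  ssrS <- features("g1", gene_start, gene_end, "+", "ssrS")
  hits <- scan_locus(pwm, bg, g, ssrS)
  up <- hits[hits$position == -60, ]
  int <- hits[hits$position == 40, ]
  expect_gte(nrow(up), 1L)
  expect_equal(unique(up$region_class), "upstream")
  expect_gte(nrow(int), 1L)
  expect_equal(unique(int$region_class), "internal")
  expect_true(all(hits$pvalue <= 1e-5))
  expect_equal(up$genome_start[1], gene_start - 60L)
})

test_that("scanning a minus-strand gene mirrors the plus-strand result", {
  sites <- default_cre_sites()
  pwm <- build_pwm(sites)
  consensus <- "TGAAAGCGCTTTCA"
  g <- generate_background(1200, uniform_dinucleotide_freqs(), seed = 71,
                           id = "gp")
  gene_start <- 600L; gene_end <- 788L
  s <- paste0(substr(g$seq, 1, gene_start - 60L), consensus,
              substr(g$seq, gene_start - 60L + nchar(consensus) + 1,
                     nchar(g$seq)))
  gplus <- data.frame(id = "gp", seq = s, description = "")
  gminus <- data.frame(id = "gm", seq = revcomp(s), description = "")
  n <- nchar(s)
  bg <- fit_background(gplus)             # shared background: the score is
  hits_p <- scan_locus(pwm, bg, gplus,    # strand-specific only through bg
                       features("gp", gene_start, gene_end, "+", "ssrS"))
  hits_m <- scan_locus(pwm, bg, gminus,
                       features("gm", n - gene_end, n - gene_start, "-",
                                "ssrS"))
  expect_equal(hits_m$position, hits_p$position)
  expect_equal(hits_m$score, hits_p$score)
  expect_equal(hits_m$region_class, hits_p$region_class)
  # mirrored genome coordinates
  expect_equal(hits_m$genome_start, n - hits_p$genome_end)
})

test_that("background-only loci produce hits at about the nominal rate", {
  sites <- default_cre_sites()
  pwm <- build_pwm(sites)
  p_threshold <- 1e-3                     # liberal threshold: measurable rate
  nrep <- 150
  total_hits <- 0; total_windows <- 0
  bg_fit <- fit_background(generate_background(20000,
                                               uniform_dinucleotide_freqs(),
                                               seed = 1))
  tab_f <- score_pvalue_table(pwm, bg_fit)
  tab_r <- score_pvalue_table(revcomp_pwm(pwm), bg_fit)
  for (i in seq_len(nrep)) {
    g <- generate_background(320, uniform_dinucleotide_freqs(),
                             seed = 5000 + i, id = "bg")
    ssrS <- features("bg", 100L, 300L, "+", "ssrS")
    hits <- scan_locus(pwm, bg_fit, g, ssrS, p_threshold = p_threshold,
                       max_hits = 1000L)
    total_hits <- total_hits + nrow(hits)
    total_windows <- total_windows + 2 * (300 - pwm$width + 1)
  }
  # conservative p-values + overlap reduction: rate must not exceed nominal
  lambda_max <- p_threshold * total_windows
  expect_lte(total_hits, lambda_max + 3 * sqrt(lambda_max))
  expect_gt(total_hits, 0)
})
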