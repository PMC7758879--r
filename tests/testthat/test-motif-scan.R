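test_that("consensus matching reports all occurrences with palindrome dedup", {
  hits <- match_consensus("AACGTACGT", "ACGT")
  expect_equal(hits$offset, c(1L, 5L))
  expect_equal(hits$strand, c("+", "+"))  # ACGT is palindromic

  expect_equal(nrow(match_consensus("ACGTACGT", "N")), 8)
  expect_equal(nrow(match_consensus("CCCC", "ACGT")), 0)
  expect_error(match_consensus("ACGT", "AZGT"), "invalid IUPAC")

  # overlapping occurrences are all reported
  expect_equal(match_consensus("AAAA", "AA", both_strands = FALSE)$offset,
               0:2)

  # non-palindromic consensus picks up reverse-strand matches
  hits2 <- match_consensus("GGGCCACGGGG", "CCACG")
  expect_identical(hits2$strand, "+")
  hits3 <- match_consensus("GGGCGTGGGGG", "CCACG")  # revcomp embedded
  expect_identical(hits3$strand, "-")

  # a sequence N is matched only by a consensus N
  expect_equal(nrow(match_consensus("ANGT", "ACGT")), 0)
  expect_equal(nrow(match_consensus("ANGT", "NN", both_strands = FALSE)), 3)
})

test_that("consensus matching agrees with the brute-force oracle", {
  motifs <- c("ACGT", "CCACG", "GACGTG", "TRCGYA", "NCGN")
  for (i in 1:20) {
    s <- random_seq(80, seed = 1000 + i)
    for (cons in motifs) {
      expect_equal(
        nrow(match_consensus(s, cons)),
        oracle_consensus_count(s, cons),
        info = paste("seed", i, "motif", cons))
    }
  }
})

test_that("PWM threshold admits exactly the intended tail for L = 1", {
  m <- pwm_motif("best_base", matrix(c(1, 0, 0, 0), 4, 1),
                 pvalue_threshold = 0.25)
  # only the best base (A) reaches the threshold; tail is exactly 0.25
  expect_equal(m$threshold$tail_prob, 0.25)
  expect_equal(nrow(scan_motif("A", m, both_strands = FALSE)), 1)
  expect_equal(nrow(scan_motif("C", m, both_strands = FALSE)), 0)
  expect_equal(nrow(scan_motif("G", m, both_strands = FALSE)), 0)
})

test_that("a PWM equal to the background admits no words", {
  m <- pwm_motif("flat", matrix(0.25, 4, 6), pvalue_threshold = 0.5)
  expect_equal(m$threshold$tail_prob, 0)
  expect_true(m$threshold$threshold_bits > 0)
  expect_equal(nrow(scan_motif(random_seq(50, 3), m)), 0)
})

test_that("DP score distribution matches exhaustive enumeration", {
  for (L in c(2, 3, 4)) {
    for (rep in 1:3) {
      mat <- random_pwm(L, seed = 100 * L + rep)
      m <- pwm_motif(paste0("r", L, rep), mat, pvalue_threshold = 1e-3)
      thr <- m$threshold$threshold_bin
      expect_equal(m$threshold$tail_prob, oracle_pwm_tail(m, thr),
                   tolerance = 1e-12)
      # threshold is the smallest qualifying bin
      expect_gt(oracle_pwm_tail(m, thr - 1L), 1e-3)
    }
  }
})

test_that("an indicator PWM reproduces consensus matching", {
  mat <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  mat[cbind(c(1, 2, 3, 4), 1:4)] <- 1  # ACGT
  m <- pwm_motif("acgt_pwm", mat, pvalue_threshold = 1 / 256)
  for (i in 1:10) {
    s <- random_seq(60, seed = 40 + i)
    expect_equal(scan_motif(s, m)$offset, match_consensus(s, "ACGT")$offset)
  }
})

test_that("PWM scanning skips N windows and honors its threshold", {
  mat <- random_pwm(4, seed = 9)
  m <- pwm_motif("r4", mat, pvalue_threshold = 0.05)
  expect_equal(nrow(scan_motif(strrep("N", 30), m)), 0)
  expect_equal(nrow(scan_motif("ACG", m)), 0)  # shorter than the motif
  hits <- scan_motif(random_seq(500, 7), m)
  expect_gt(nrow(hits), 0)
  expect_true(all(hits$score >= m$threshold$threshold_bits - 1e-12))
})

test_that("counting is exact against the oracle and closed under strand flips", {
  promoters <- data.frame(
    gene_id = sprintf("p%03d", 1:50),
    sequence = vapply(1:50, function(i) random_seq(200, 700 + i),
                      character(1)))
  motifs <- list(consensus_motif("acgt_core", "ACGT"),
                 consensus_motif("ccacg_box", "CCACG"))
  counts <- count_occurrences(promoters, motifs)
  expect_identical(rownames(counts), promoters$gene_id)
  for (i in seq_len(nrow(promoters))) {
    expect_equal(counts[i, "acgt_core"],
                 oracle_consensus_count(promoters$sequence[i], "ACGT"))
    expect_equal(counts[i, "ccacg_box"],
                 oracle_consensus_count(promoters$sequence[i], "CCACG"))
  }
  # strand closure: reverse-complementing every promoter keeps totals
  rc <- promoters
  rc$sequence <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(promoters$sequence)))
  expect_equal(unclass(count_occurrences(rc, motifs)), unclass(counts),
               ignore_attr = FALSE)

  dup <- promoters
  dup$gene_id[2] <- dup$gene_id[1]
  expect_error(count_occurrences(dup, motifs), "duplicate")
})

test_that("motif files round-trip through their readers", {
  cons_path <- write_lines_tmp(c("# illustrative motifs",
                                 "acgt_core\tACGT",
                                 "ccacg_box\tCCACG"))
  motifs <- read_motifs_consensus(cons_path)
  expect_named(motifs, c("acgt_core", "ccacg_box"))
  expect_equal(motifs$ccacg_box$consensus, "CCACG")

  meme_path <- write_lines_tmp(c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "Background letter frequencies",
    "A 0.3 C 0.2 G 0.2 T 0.3", "",
    "MOTIF uprea_like",
    "letter-probability matrix: alength= 4 w= 3 nsites= 20",
    " 0.9 0.05 0.03 0.02",
    " 0.1 0.7 0.1 0.1",
    " 0.25 0.25 0.25 0.25"))
  pwms <- read_motifs_meme(meme_path)
  expect_named(pwms, "uprea_like")
  expect_equal(pwms$uprea_like$length, 3)
  expect_equal(pwms$uprea_like$background, c(0.3, 0.2, 0.2, 0.3))
  expect_equal(pwms$uprea_like$matrix[, 1], c(A = 0.9, C = 0.05,
                                              G = 0.03, T = 0.02))
})
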